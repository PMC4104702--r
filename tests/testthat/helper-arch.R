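# Scaled-down architecture for statistically structured but fast tests:
# same head/tail construction and variance bookkeeping as the default trait,
# fewer SNPs. Head count and head total are shrunk proportionally so the
# spectrum shape is preserved.
small_arch <- function(n_snps = 300, fraction = 0, fold = 1, model = 1,
                       seed = NULL, ...) {
  n_head <- round(n_snps * 701 / 2500)
  head_total <- 0.16 * n_head / 701
  # tiny panels: cap the head maximum so the head total stays achievable
  gv_max <- min(0.0028, 0.9 * (head_total - (n_head - 1) * 0.00012))
  trait_architecture(
    n_snps = n_snps, n_head = n_head, gv_max = gv_max,
    head_total = head_total,
    fraction = fraction, fold = fold, model = model, seed = seed, ...
  )
}

# Reference 4-parameter interaction fit via stats::lm, used as the
# independent oracle for the closed-form two-group regression.
lm_interaction <- function(y, x, env) {
  fit <- summary(stats::lm(y ~ x + env + x:env))$coefficients
  list(estimate = fit["x:env", 1], std_error = fit["x:env", 2],
       p_value = fit["x:env", 4])
}
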
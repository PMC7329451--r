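# A hand-assembled fit object with known fitted parameters, for exercising
# the residual formulas without an optimizer in the loop. Only the fields
# the residual/diagnostic code touches are populated.
fake_fit <- function(family, y, lambda, k = NULL, p_zero = NULL) {
  fam <- count_family(family, rep_len(lambda, length(y)), k = k,
                      p_zero = if (!is.null(p_zero))
                        rep_len(p_zero, length(y)))
  structure(list(
    family = family,
    fitted_family = fam,
    mu_hat = count_mean_var(fam)$mean,
    k_hat = k,
    y = as.numeric(y),
    n = length(y),
    converged = TRUE,
    data = data.frame(y = y)
  ), class = "count_fit")
}

# Small simulated Poisson regression dataset + fit, shared across tests.
small_pois_fit <- function(n = 300, seed = 42) {
  set.seed(seed)
  d <- data.frame(x = runif(n, -1, 1))
  d$y <- rpois(n, exp(0.5 + d$x))
  fit_count_model(y ~ x, d, family = "poisson")
}
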
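# Independent population-level oracle for the additive model.
#
# Represents each variable by its coefficients on the orthonormal shocks
# (G, U, eps_E, eps_Y), so every covariance is a plain dot product; the
# OLS plim is then solved from the resulting moment matrix. This shares
# no code with the package's closed forms.
oracle_plim <- function(lambda, delta, kappa, beta = 0.6, gamma = 0.6,
                        sigma = 1) {
  G <- c(1, 0, 0, 0)
  U <- c(0, 1, 0, 0)
  eps_e <- c(0, 0, sqrt(1 - lambda^2 - delta^2), 0)
  eps_y <- c(0, 0, 0, sigma)
  E <- lambda * G + delta * U + eps_e
  Y <- beta * G + gamma * E + kappa * U + eps_y
  cv <- function(a, b) sum(a * b)
  s_xx <- matrix(c(cv(G, G), cv(G, E), cv(G, E), cv(E, E)), 2, 2)
  s_xy <- c(cv(G, Y), cv(E, Y))
  b <- solve(s_xx, s_xy)
  var_y <- cv(Y, Y)
  truth <- beta * G + gamma * E
  list(
    b_g = b[[1]], b_e = b[[2]],
    bias_g = b[[1]] - beta, bias_e = b[[2]] - gamma,
    r2_fitted = sum(b * s_xy) / var_y,
    r2_true_share = cv(truth, truth) / var_y
  )
}

# mean estimates across seeded replicates for one parameter set
replicate_means <- function(p, fitter, n_reps, terms, seed_offset = 0L) {
  est <- vapply(seq_len(n_reps), function(r) {
    p_r <- colliderbias:::modify_params(p, seed = p$seed + seed_offset + r)
    fit <- fitter(generate_cohort(p_r))
    fit$coef[terms]
  }, numeric(length(terms)))
  est <- matrix(est, nrow = length(terms),
                dimnames = list(terms, NULL))
  list(mean = rowMeans(est),
       se_mean = apply(est, 1, stats::sd) / sqrt(n_reps))
}
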
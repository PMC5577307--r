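# Independent oracles used across the suite.

# Direct marginal-likelihood oracle for the crossed random-intercept LMM:
# maximises the Gaussian log-likelihood of y ~ N(X beta, V) with
# V = s2_m Zm Zm' + s2_f Zf Zf' + s2_p Zp Zp' + s2_e I
# by generic optimisation over log-variances, beta profiled out by GLS.
# Shares no code with fit_rtl_lmm()'s lme4 path.
direct_ml_loglik <- function(data) {
  y <- data$rtl
  n <- length(y)
  X <- stats::model.matrix(~ sample_year + age * sex, data)
  Z <- lapply(c("mother_id", "father_id", "plate_id"), function(g) {
    stats::model.matrix(~ 0 + factor(data[[g]]))
  })
  loglik_at <- function(logv) {
    v <- exp(logv)
    V <- v[4] * diag(n)
    for (k in 1:3) V <- V + v[k] * tcrossprod(Z[[k]])
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(-1e10)
    Xi <- backsolve(ch, X, transpose = TRUE)
    yi <- backsolve(ch, y, transpose = TRUE)
    beta <- qr.solve(Xi, yi)
    r <- yi - Xi %*% beta
    -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(r^2))
  }
  v0 <- stats::var(y)
  best <- -Inf
  for (start in list(
    log(c(v0 / 4, v0 / 4, v0 / 4, v0 / 4)),
    log(c(v0 / 10, v0 / 10, v0 / 10, v0)),
    log(c(v0 / 50, v0 / 50, v0 / 50, v0 / 2))
  )) {
    opt <- stats::optim(start, function(p) -loglik_at(p),
      method = "Nelder-Mead",
      control = list(maxit = 5000, reltol = 1e-12)
    )
    opt <- stats::optim(opt$par, function(p) -loglik_at(p),
      method = "Nelder-Mead",
      control = list(maxit = 5000, reltol = 1e-12)
    )
    best <- max(best, -opt$value)
  }
  best
}

# Error propagation of the RTL formula under Gaussian Cq noise:
# Cq means over triplicates on both sample and calibrator sides give
# Var(log RTL) = (2/3) sigma^2 (log E_TEL^2 + log E_B2M^2).
rtl_noise_pass_prob <- function(sigma, e_tel = 1.91, e_b2m = 1.88, rel_tol = 0.1) {
  sd_log <- sqrt(2 / 3) * sigma * sqrt(log(e_tel)^2 + log(e_b2m)^2)
  stats::pnorm(log(1 + rel_tol) / sd_log) - stats::pnorm(log(1 - rel_tol) / sd_log)
}

# Noise-free plate spec for round-trip identities.
noiseless_spec <- function(cq_noise_sd = 0, ...) {
  qpcr_plate_spec(
    cq_noise_sd = cq_noise_sd, fluor_noise_sd = 0,
    baseline_intercept = c(0, 0), baseline_slope = c(0, 0), ...
  )
}

small_structure <- function(...) {
  soay_structure(
    n_obs = 30L, n_animals = 30L, n_mothers = 20L, n_fathers = 15L,
    n_plates = 3L, ...
  )
}
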
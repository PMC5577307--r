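test_that("model specs enforce term hierarchy and lamb mode", {
  expect_error(rtl_model_spec(c("year", "age_sex")), "age_sex requires")
  expect_error(rtl_model_spec(c("year", "age", "sex", "PAC2")), "PAC2 requires PAC")
  expect_error(rtl_model_spec("height"), "unknown fixed terms")
  lamb <- rtl_model_spec(lamb_mode = TRUE)
  expect_false(any(c("age", "age_sex") %in% lamb$fixed_terms))
  expect_true(all(c("year", "sex") %in% lamb$fixed_terms))
})

test_that("with zero random variances the LMM reduces to ordinary least squares", {
  params <- soay_structure(
    n_obs = 8000L, n_animals = 8000L,
    fixed_effects = c(year = 0.05, age = -0.01, sex = 0.03, age_sex = 0.004),
    var_mother = 0, var_father = 0, var_plate = 0, var_resid = 0.02
  )
  pop <- sample_population(params, seed = 17)
  fit <- fit_rtl_lmm(pop, rtl_model_spec())
  ols <- lm(rtl ~ sample_year + age * sex, data = pop)
  expect_lt(sum(fit$varcomps[c("mother_id", "father_id", "plate_id")]), 1e-4)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)), tolerance = 1e-4)
  expect_true(fit$singular) # zero components sit at the boundary, flagged
  expect_true(fit$converged)
})

test_that("ML log-likelihood matches a direct covariance-matrix optimiser", {
  pop <- sample_population(
    soay_structure(
      n_obs = 40L, n_animals = 40L, n_mothers = 12L,
      n_fathers = 10L, n_plates = 3L
    ),
    seed = 40
  )
  fit <- fit_rtl_lmm(pop, rtl_model_spec(estimation = "ML"))
  oracle <- direct_ml_loglik(pop)
  expect_equal(fit$loglik, oracle, tolerance = 1e-3 / abs(oracle))
})

test_that("fits are invariant to row permutation and identifier relabelling", {
  pop <- sample_population(small_structure(var_resid = 0.02), seed = 12)
  fit <- fit_rtl_lmm(pop, rtl_model_spec())
  perm <- pop[sample(nrow(pop)), ]
  fit_p <- fit_rtl_lmm(perm, rtl_model_spec())
  expect_equal(fit_p$loglik, fit$loglik, tolerance = 1e-8)
  expect_equal(fit_p$coefficients$estimate, fit$coefficients$estimate,
    tolerance = 1e-8
  )
  relab <- dplyr::mutate(pop,
    mother_id = paste0("zz_", mother_id),
    father_id = chartr("0123456789", "9876543210", father_id)
  )
  fit_r <- fit_rtl_lmm(relab, rtl_model_spec())
  expect_equal(fit_r$loglik, fit$loglik, tolerance = 1e-8)
  expect_equal(sort(unname(fit_r$varcomps)), sort(unname(fit$varcomps)),
    tolerance = 1e-6
  )
})

test_that("likelihood-ratio tests follow the chi-square definition", {
  pop <- sample_population(soay_structure(), seed = 23)
  full <- fit_rtl_lmm(pop, rtl_model_spec(c("year", "age", "sex", "age_sex", "PAC")))
  red <- fit_rtl_lmm(pop, rtl_model_spec())
  # identical model twice: chisq 0, p 1
  self <- lrt(full, full)
  expect_equal(self$chisq, 0)
  expect_equal(self$p_value, 1)
  r <- lrt(full, red, term = "PAC")
  expect_gte(r$chisq, 0)
  expect_equal(r$df, 1L)
  expect_equal(r$p_value, pchisq(r$chisq, 1, lower.tail = FALSE))
  # chi-square quantile identity at the 5% point
  expect_equal(pchisq(3.841459, 1, lower.tail = FALSE), 0.05, tolerance = 1e-6)
  # usage errors
  expect_error(lrt(red, full), "nested")
  reml <- fit_rtl_lmm(pop, rtl_model_spec(estimation = "REML"))
  expect_error(lrt(reml, red), "require ML")
  other <- fit_rtl_lmm(pop[-1, ], rtl_model_spec())
  expect_error(lrt(full, other), "same data")
})

test_that("parental-age tests use the right base model and degrees of freedom", {
  pop <- sample_population(soay_structure(pac_slope = 0.05), seed = 31)
  lin <- test_parental_age(pop, "PAC", "linear")
  expect_equal(lin$df, 1L)
  expect_equal(lin$term_tested, "PAC_linear")
  expect_lt(lin$p_value, 0.01) # strong injected effect is detected
  quad <- test_parental_age(pop, "PAC", "quadratic")
  expect_equal(quad$df, 2L) # joint 2-df comparison against the base model
  fits <- attr(quad, "fits")
  expect_true("I(pac_c^2)" %in% fits$full$coefficients$term)
  # lamb mode drops age terms from both models
  lamb <- dplyr::filter(pop, age < 1)
  lam <- test_parental_age(lamb, "MAC", "linear", lamb_mode = TRUE)
  expect_equal(lam$df, 1L)
  lam_fits <- attr(lam, "fits")
  expect_false(any(grepl("age", lam_fits$full$coefficients$term)))
})

test_that("parental-age slope is recovered without bias at large n", {
  est <- purrr::map_dbl(1:10, function(s) {
    pop <- sample_population(
      soay_structure(n_obs = 3000L, n_animals = 3000L, pac_slope = 0.05),
      seed = 100 + s
    )
    fit <- fit_rtl_lmm(pop, rtl_model_spec(c("year", "age", "sex", "age_sex", "PAC")))
    fit$coefficients$estimate[fit$coefficients$term == "pac_c"]
  })
  # mean estimate over seeds within Monte-Carlo error of the truth
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.05), 3 * mc_se + 1e-4)
})

test_that("variance proportions normalise the random-intercept components", {
  pop <- sample_population(soay_structure(), seed = 3)
  fit <- fit_rtl_lmm(pop, rtl_model_spec())
  vp <- variance_proportions(fit)
  expect_setequal(vp$term, c("mother_id", "father_id", "plate_id"))
  expect_equal(sum(vp$proportion), 1, tolerance = 1e-12)
  vp_tot <- variance_proportions(fit, include_residual = TRUE)
  expect_true("residual" %in% vp_tot$term)
  expect_equal(sum(vp_tot$proportion), 1, tolerance = 1e-12)
  # direct ratio on hand-set components
  fake <- fit
  fake$varcomps <- c(mother_id = 0.8, father_id = 0.1, plate_id = 0.1, residual = 1)
  expect_equal(variance_proportions(fake)$proportion, c(0.8, 0.1, 0.1))
  # degenerate all-zero case is flagged, not silent
  fake$varcomps <- c(mother_id = 0, father_id = 0, plate_id = 0, residual = 1)
  expect_warning(out <- variance_proportions(fake), "undefined")
  expect_equal(nrow(out), 0)
})

test_that("tidy and glance expose coefficients and fit summaries", {
  pop <- sample_population(small_structure(var_resid = 0.02), seed = 2)
  fit <- fit_rtl_lmm(pop, rtl_model_spec())
  td <- tidy(fit)
  expect_true(all(c("effect", "term", "estimate", "se") %in% names(td)))
  expect_true(all(c("fixed", "ran_pars") %in% td$effect))
  gl <- glance(fit)
  expect_equal(gl$nobs, nrow(pop))
  expect_true(is.finite(gl$logLik))
})
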
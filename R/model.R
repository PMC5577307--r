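# Crossed random-intercept LMMs for RTL and the parental-age LRTs.
#
# Base model: RTL ~ year + age * sex with random intercepts for mother,
# father and plate. Parental-age terms (MAC/PAC, linear or joint quadratic)
# are tested against the base model with likelihood-ratio tests on
# ML-fitted models. The lamb-only variant drops age and age:sex.

fixed_term_map <- c(
  year = "sample_year", age = "age", sex = "sex", age_sex = "age:sex",
  MAC = "mac_c", MAC2 = "I(mac_c^2)", PAC = "pac_c", PAC2 = "I(pac_c^2)"
)

#' Specify an RTL mixed model
#'
#' @param fixed_terms character subset of `year`, `age`, `sex`, `age_sex`,
#'   `MAC`, `MAC2`, `PAC`, `PAC2`. Parental-age covariates are mean-centred
#'   before squaring. `age_sex` requires `age` and `sex`; a quadratic term
#'   requires its linear term.
#' @param random_terms character subset of `mother_id`, `father_id`,
#'   `plate_id` fitted as crossed random intercepts. `animal_id` may be
#'   added to model repeat measurements explicitly (off by default,
#'   matching the reported random-term list).
#' @param estimation `"ML"` (required whenever fits are compared) or
#'   `"REML"`.
#' @param lamb_mode drop `age` and `age_sex` (single-age lamb subset).
#' @return an object of class `rtl_model_spec`.
#' @export
rtl_model_spec <- function(fixed_terms = c("year", "age", "sex", "age_sex"),
                           random_terms = c("mother_id", "father_id", "plate_id"),
                           estimation = c("ML", "REML"),
                           lamb_mode = FALSE) {
  estimation <- match.arg(estimation)
  allowed <- names(fixed_term_map)
  if (!all(fixed_terms %in% allowed)) {
    abort(paste("unknown fixed terms:", paste(setdiff(fixed_terms, allowed), collapse = ", ")))
  }
  allowed_r <- c("mother_id", "father_id", "plate_id", "animal_id")
  if (!all(random_terms %in% allowed_r)) {
    abort(paste("unknown random terms:", paste(setdiff(random_terms, allowed_r), collapse = ", ")))
  }
  if (lamb_mode) fixed_terms <- setdiff(fixed_terms, c("age", "age_sex"))
  if ("age_sex" %in% fixed_terms && !all(c("age", "sex") %in% fixed_terms)) {
    abort("age_sex requires age and sex")
  }
  if ("MAC2" %in% fixed_terms && !"MAC" %in% fixed_terms) abort("MAC2 requires MAC")
  if ("PAC2" %in% fixed_terms && !"PAC" %in% fixed_terms) abort("PAC2 requires PAC")
  structure(
    list(
      fixed_terms = fixed_terms, random_terms = random_terms,
      estimation = estimation, lamb_mode = lamb_mode
    ),
    class = "rtl_model_spec"
  )
}

spec_formula <- function(spec) {
  rhs <- unname(fixed_term_map[spec$fixed_terms])
  re <- sprintf("(1 | %s)", spec$random_terms)
  stats::as.formula(
    paste("rtl ~", paste(c(if (length(rhs)) rhs else "1", re), collapse = " + ")),
    env = globalenv()
  )
}

prepare_model_data <- function(data, spec) {
  col_of <- list(
    year = "sample_year", age = "age", sex = "sex", age_sex = c("age", "sex"),
    MAC = "mac", MAC2 = "mac", PAC = "pac", PAC2 = "pac"
  )
  need <- unique(c("rtl", unlist(col_of[spec$fixed_terms]), spec$random_terms))
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste("data lacks columns:", paste(missing_cols, collapse = ", ")))
  }
  data <- data[complete.cases(data[need]), , drop = FALSE]
  if ("mac" %in% names(data)) data$mac_c <- data$mac - mean(data$mac)
  if ("pac" %in% names(data)) data$pac_c <- data$pac - mean(data$pac)
  data
}

#' Fit a crossed random-intercept linear mixed model for RTL
#'
#' Gaussian LMM maximised by ML (or REML) via lme4, with the spec's crossed
#' random intercepts. Non-convergence is flagged on the result, never
#' silent; a variance component estimated at the 0 boundary is flagged as
#' `singular` and the fit retained.
#'
#' @param data tibble of RTL observations ([sample_population()] schema).
#' @param spec an [rtl_model_spec()].
#' @return an object of class `rtl_fit` with elements `coefficients`
#'   (tibble: term, estimate, se), `varcomps` (named: one per random term
#'   plus `residual`), `loglik`, `n_obs`, `converged`, `singular`, `spec`,
#'   and the underlying `lme4` fit as `model`.
#' @export
fit_rtl_lmm <- function(data, spec = rtl_model_spec()) {
  if (!inherits(spec, "rtl_model_spec")) abort("spec must be an rtl_model_spec")
  data <- prepare_model_data(data, spec)
  for (rt in spec$random_terms) {
    if (length(unique(data[[rt]])) < 2) {
      abort(sprintf("random term %s needs >= 2 levels", rt))
    }
  }
  fml <- spec_formula(spec)
  fit <- suppressMessages(lme4::lmer(
    fml,
    data = data, REML = identical(spec$estimation, "REML"),
    control = lme4::lmerControl(
      calc.derivs = FALSE,
      check.conv.singular = "ignore"
    )
  ))
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomps <- setNames(vc$vcov, ifelse(vc$grp == "Residual", "residual", vc$grp))
  varcomps <- varcomps[c(spec$random_terms, "residual")]
  sfit <- summary(fit)
  cf <- stats::coef(sfit)
  msgs <- fit@optinfo$conv$lme4$messages
  structure(
    list(
      coefficients = tibble(
        term = rownames(cf), estimate = unname(cf[, "Estimate"]),
        se = unname(cf[, "Std. Error"])
      ),
      varcomps = varcomps,
      loglik = as.numeric(logLik(fit)),
      n_obs = nrow(data),
      converged = fit@optinfo$conv$opt == 0 &&
        !any(grepl("failed to converge", unlist(msgs))),
      singular = lme4::isSingular(fit, tol = 1e-6),
      spec = spec,
      model = fit
    ),
    class = "rtl_fit"
  )
}

#' @export
print.rtl_fit <- function(x, ...) {
  cat(sprintf(
    "<rtl_fit> %s, n = %d, logLik = %.3f%s%s\n",
    x$spec$estimation, x$n_obs, x$loglik,
    if (!x$converged) " [NOT CONVERGED]" else "",
    if (x$singular) " [singular]" else ""
  ))
  cat("fixed:", paste(x$spec$fixed_terms, collapse = ", "), "\n")
  print(x$coefficients)
  cat("variance components:\n")
  print(round(x$varcomps, 6))
  invisible(x)
}

#' @rdname fit_rtl_lmm
#' @param x an `rtl_fit`.
#' @param effects `"fixed"`, `"ran_pars"`, or both.
#' @param ... unused.
#' @export
tidy.rtl_fit <- function(x, effects = c("fixed", "ran_pars"), ...) {
  out <- list()
  if ("fixed" %in% effects) {
    out$fixed <- x$coefficients %>% mutate(effect = "fixed", .before = 1)
  }
  if ("ran_pars" %in% effects) {
    out$ran <- tibble(
      effect = "ran_pars", term = names(x$varcomps),
      estimate = unname(x$varcomps), se = NA_real_
    )
  }
  bind_rows(out)
}

#' @rdname fit_rtl_lmm
#' @export
glance.rtl_fit <- function(x, ...) {
  tibble(
    nobs = x$n_obs, logLik = x$loglik,
    AIC = -2 * x$loglik + 2 * (nrow(x$coefficients) + length(x$varcomps)),
    sigma = sqrt(x$varcomps[["residual"]]),
    converged = x$converged, singular = x$singular
  )
}

#' Likelihood-ratio test between nested RTL model fits
#'
#' `chisq = 2 * (loglik_full - loglik_reduced)` (clipped at 0), with
#' degrees of freedom equal to the difference in fixed-effect parameter
#' counts and an upper-tail chi-square p-value. Both fits must be ML fits
#' of nested fixed structures on the same data with the same random terms.
#'
#' @param full,reduced `rtl_fit` objects.
#' @param term label recorded in the output.
#' @return one-row tibble: `term_tested`, `chisq`, `df`, `p_value`.
#' @export
lrt <- function(full, reduced, term = NA_character_) {
  if (!inherits(full, "rtl_fit") || !inherits(reduced, "rtl_fit")) {
    abort("lrt() expects two rtl_fit objects")
  }
  if (full$spec$estimation != "ML" || reduced$spec$estimation != "ML") {
    abort("likelihood-ratio tests require ML fits")
  }
  if (full$n_obs != reduced$n_obs) abort("fits are not on the same data")
  if (!setequal(full$spec$random_terms, reduced$spec$random_terms)) {
    abort("fits must share the same random terms")
  }
  if (!all(reduced$spec$fixed_terms %in% full$spec$fixed_terms)) {
    abort("reduced model's fixed terms must be nested in the full model's")
  }
  df <- nrow(full$coefficients) - nrow(reduced$coefficients)
  if (df < 0) abort("full model has fewer parameters than reduced model")
  chisq <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- if (df == 0) 1 else pchisq(chisq, df, lower.tail = FALSE)
  tibble(term_tested = term, chisq = chisq, df = as.integer(df), p_value = p)
}

#' Likelihood-ratio test for a parental-age effect on RTL
#'
#' Adds MAC or PAC to the base model (year + age * sex, or year + sex in
#' lamb mode) and compares by LRT: the linear test is 1 df; the quadratic
#' test is a joint 2-df comparison of base + term + term^2 against the
#' base model. Parental-age covariates are mean-centred before squaring.
#' Both models are fitted by ML.
#'
#' @param data RTL observations ([sample_population()] schema).
#' @param which `"PAC"` or `"MAC"`.
#' @param order `"linear"` or `"quadratic"`.
#' @param lamb_mode restrict the base model to the single-age form.
#' @param random_terms passed to [rtl_model_spec()].
#' @return one-row tibble: `term_tested`, `chisq`, `df`, `p_value`, plus
#'   the two fits as attribute `"fits"`.
#' @examples
#' pop <- sample_population(soay_structure(pac_slope = 0.05), seed = 1)
#' test_parental_age(pop, "PAC")
#' @export
test_parental_age <- function(data, which = c("PAC", "MAC"),
                              order = c("linear", "quadratic"),
                              lamb_mode = FALSE,
                              random_terms = c("mother_id", "father_id", "plate_id")) {
  which <- match.arg(which)
  order <- match.arg(order)
  base_terms <- c("year", "age", "sex", "age_sex")
  add <- if (order == "linear") which else c(which, paste0(which, "2"))
  base_spec <- rtl_model_spec(base_terms,
    random_terms = random_terms,
    estimation = "ML", lamb_mode = lamb_mode
  )
  full_spec <- rtl_model_spec(c(base_terms, add),
    random_terms = random_terms,
    estimation = "ML", lamb_mode = lamb_mode
  )
  data <- prepare_model_data(data, full_spec)
  reduced <- fit_rtl_lmm(data, base_spec)
  full <- fit_rtl_lmm(data, full_spec)
  out <- lrt(full, reduced, term = paste(which, order, sep = "_"))
  attr(out, "fits") <- list(full = full, reduced = reduced)
  out
}

#' Proportion of random-effect variance per term
#'
#' Each random intercept's variance divided by the sum of the random-term
#' variances. By default the residual is excluded, reading "variance in the
#' random effects component" as shares among the fitted random intercepts;
#' `include_residual = TRUE` reports shares of the total modelled variance
#' instead.
#'
#' @param fit an `rtl_fit`.
#' @param include_residual include the residual variance in the
#'   denominator (and as a row).
#' @return tibble with `term`, `variance`, `proportion` (sums to 1).
#' @export
variance_proportions <- function(fit, include_residual = FALSE) {
  if (!inherits(fit, "rtl_fit")) abort("fit must be an rtl_fit")
  if (!fit$converged) abort("fit did not converge")
  vc <- fit$varcomps
  if (!include_residual) vc <- vc[setdiff(names(vc), "residual")]
  total <- sum(vc)
  if (total <= 0) {
    warn("all random-effect variances are zero; proportions undefined")
    return(tibble(term = character(), variance = double(), proportion = double()))
  }
  tibble(term = names(vc), variance = unname(vc), proportion = unname(vc) / total)
}
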
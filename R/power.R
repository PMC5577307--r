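# Monte-Carlo power for the parental-age LRT under the study design, and
# the slope <-> correlation effect-size conversion.

#' Convert a parental-age slope to an implied correlation
#'
#' `r = slope * sd_x / sd_y`: a regression slope in RTL units per year of
#' parental age, scaled by the SD of the parental age (`sd_x`) over the SD
#' of RTL (`sd_y`), gives the correlation coefficient the effect implies —
#' the unitless scale on which effect sizes are compared across species.
#'
#' @param slope effect in RTL units per year.
#' @param sd_x SD of the parental-age covariate (years); study value 2.121.
#' @param sd_y SD of RTL; study value 0.185.
#' @return implied correlation coefficient.
#' @examples
#' slope_to_r(0.012, 2.121, 0.185) # ~0.138
#' @export
slope_to_r <- function(slope, sd_x = 2.121, sd_y = 0.185) {
  if (any(sd_x <= 0) || any(sd_y <= 0)) abort("SDs must be > 0")
  slope * sd_x / sd_y
}

#' Convert a correlation to the equivalent parental-age slope
#'
#' Exact inverse of [slope_to_r()]: `slope = r * sd_y / sd_x`.
#'
#' @param r correlation coefficient.
#' @inheritParams slope_to_r
#' @return slope in RTL units per year.
#' @examples
#' r_to_slope(0.378, 2.121, 0.185) # chimpanzee-equivalent slope, ~0.033
#' @export
r_to_slope <- function(r, sd_x = 2.121, sd_y = 0.185) {
  if (any(sd_x <= 0) || any(sd_y <= 0)) abort("SDs must be > 0")
  r * sd_y / sd_x
}

#' Monte-Carlo power of the parental-age likelihood-ratio test
#'
#' For each true slope in `effects`, simulates `n_reps` full datasets from
#' `structure` (parents, plates and covariates resampled fresh each
#' replicate), runs the 1-df linear LRT for the chosen parental-age term,
#' and reports the fraction of replicates with p < `alpha`. One master seed
#' spawns independent per-replicate seeds, so results are reproducible and
#' each grid point is independent. Replicates whose fits fail or do not
#' converge are dropped from the denominator with a warning; if more than
#' 2% drop, the run aborts.
#'
#' @param effects numeric vector of true slopes (RTL units per year).
#' @param structure a [population_params()] object; defaults to
#'   [soay_structure()].
#' @param n_reps Monte-Carlo replicates per effect.
#' @param alpha test size.
#' @param which `"PAC"` or `"MAC"`.
#' @param seed master seed.
#' @return a tibble of class `power_curve`: `effect`, `power`, `mc_se`
#'   (binomial SE `sqrt(power * (1 - power) / n_used)`), `n_reps`,
#'   `n_used`, `n_failed`; `alpha`, `which` and `seed` kept as attributes.
#' @examples
#' \donttest{
#' pw <- estimate_power(c(0, 0.03), n_reps = 50, seed = 1)
#' }
#' @export
estimate_power <- function(effects,
                           structure = soay_structure(),
                           n_reps = 500L,
                           alpha = 0.05,
                           which = c("PAC", "MAC"),
                           seed = 1L) {
  which <- match.arg(which)
  if (!inherits(structure, "population_params")) {
    abort("structure must be a population_params object")
  }
  if (n_reps < 1) abort("n_reps must be >= 1")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (any(!is.finite(effects))) abort("effects must be finite")

  set.seed(seed)
  rep_seeds <- matrix(
    sample.int(.Machine$integer.max - 1L, length(effects) * n_reps),
    nrow = n_reps
  )
  slope_field <- if (which == "PAC") "pac_slope" else "mac_slope"

  rows <- purrr::imap(effects, function(effect, j) {
    params <- structure
    params[[slope_field]] <- effect
    p_vals <- purrr::map_dbl(seq_len(n_reps), function(i) {
      tryCatch(
        {
          dat <- sample_population(params, seed = rep_seeds[i, j])
          res <- test_parental_age(dat, which = which, order = "linear")
          fits <- attr(res, "fits")
          if (!fits$full$converged || !fits$reduced$converged) {
            return(NA_real_)
          }
          res$p_value
        },
        error = function(e) NA_real_
      )
    })
    n_failed <- sum(is.na(p_vals))
    if (n_failed > 0) {
      warn(sprintf(
        "effect %.4g: %d of %d replicates failed or did not converge",
        effect, n_failed, n_reps
      ))
    }
    if (n_failed > 0.02 * n_reps) {
      abort(sprintf(
        "effect %.4g: %.1f%% of replicates failed (> 2%% limit)",
        effect, 100 * n_failed / n_reps
      ))
    }
    n_used <- n_reps - n_failed
    pw <- mean(p_vals < alpha, na.rm = TRUE)
    tibble(
      effect = effect, power = pw,
      mc_se = sqrt(pw * (1 - pw) / n_used),
      n_reps = as.integer(n_reps), n_used = as.integer(n_used),
      n_failed = as.integer(n_failed)
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("power_curve", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "which") <- which
  attr(out, "seed") <- seed
  out
}

#' Minimum detectable effect at a target power
#'
#' Monotone (isotonic-regression) interpolation of a simulated power curve
#' at `target_power`. The grid must bracket the target.
#'
#' @param power_curve output of [estimate_power()] (or any tibble with
#'   `effect`, `power`, `mc_se`).
#' @param target_power required power, in (alpha, 1); default 0.80.
#' @return one-row tibble: `target_power`, `effect` (interpolated minimum
#'   detectable slope), bracketing grid points `effect_lo`/`effect_hi`
#'   with their estimated powers, and `mc_se_at_bracket`.
#' @export
minimum_detectable_effect <- function(power_curve, target_power = 0.8) {
  req <- c("effect", "power")
  if (!all(req %in% names(power_curve))) {
    abort("power_curve needs columns effect and power")
  }
  if (target_power <= 0 || target_power >= 1) abort("target_power must be in (0, 1)")
  pc <- power_curve %>% arrange(.data$effect)
  iso <- stats::isoreg(pc$effect, pc$power)
  p_iso <- iso$yf
  if (max(p_iso) < target_power || min(p_iso) > target_power) {
    abort("effect grid does not bracket the target power")
  }
  hi_i <- which(p_iso >= target_power)[1]
  lo_i <- max(which(p_iso[seq_len(hi_i)] <= target_power))
  eff <- if (p_iso[hi_i] == p_iso[lo_i]) {
    pc$effect[hi_i]
  } else {
    pc$effect[lo_i] + (target_power - p_iso[lo_i]) /
      (p_iso[hi_i] - p_iso[lo_i]) * (pc$effect[hi_i] - pc$effect[lo_i])
  }
  tibble(
    target_power = target_power, effect = eff,
    effect_lo = pc$effect[lo_i], power_lo = p_iso[lo_i],
    effect_hi = pc$effect[hi_i], power_hi = p_iso[hi_i],
    mc_se_at_bracket = if ("mc_se" %in% names(pc)) {
      max(pc$mc_se[c(lo_i, hi_i)])
    } else {
      NA_real_
    }
  )
}

#' Plot a simulated power curve
#'
#' @param object a `power_curve` from [estimate_power()].
#' @param target_power horizontal reference line (default 0.80).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.power_curve <- function(object, target_power = 0.8, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  ggplot2::ggplot(object, ggplot2::aes(x = .data$effect, y = .data$power)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = pmax(0, .data$power - 1.96 * .data$mc_se),
        ymax = pmin(1, .data$power + 1.96 * .data$mc_se)
      ),
      fill = "grey80"
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = target_power, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dotted") +
    ggplot2::labs(
      x = "true parental-age slope (RTL / year)",
      y = sprintf("power (rejection fraction at alpha = %.2g)", alpha)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.power_curve
#' @param x a `power_curve`.
#' @param y ignored.
#' @export
plot.power_curve <- function(x, y, ...) print(autoplot(x, ...))
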
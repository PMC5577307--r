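# Raw qPCR plate simulation: invert the calibrator/efficiency-corrected RTL
# formula to per-well Cq targets, then render amplification curves.

#' qPCR plate simulation parameters
#'
#' Plate-level truths for the amplification-curve generator: amplicon
#' efficiencies, fluorescence thresholds, triplicate Cq noise, per-well
#' linear baseline ranges, plateau and cycle count. Each curve is
#' `baseline(c) + min(F0 * E^c, plateau)` with optional multiplicative
#' lognormal noise, where `F0 = threshold * E^(-Cq)` so the curve crosses
#' the threshold exactly at its target Cq.
#'
#' @param e_tel,e_b2m true amplification efficiencies in (1, 2] for the
#'   telomere and B2M amplicon groups (per-cycle fold change).
#' @param threshold_tel,threshold_b2m constant fluorescence thresholds for
#'   Cq determination.
#' @param cq_noise_sd SD (cycles) of independent Gaussian noise added to
#'   each well's target Cq; generates triplicate scatter.
#' @param fluor_noise_sd SD of lognormal multiplicative noise applied
#'   per cycle to the amplification component.
#' @param baseline_intercept,baseline_slope ranges from which each well's
#'   linear baseline intercept and slope are drawn uniformly.
#' @param plateau fluorescence ceiling of the amplification component.
#' @param n_cycles number of PCR cycles (>= 30).
#' @param calibrator_cq_tel,calibrator_cq_b2m true Cqs of the calibrator
#'   sample for each amplicon.
#' @param sample_cq_spread SD (cycles) of between-sample variation in B2M
#'   Cq, reflecting DNA input variation around the calibrator.
#' @param n_triplicate wells per sample per amplicon (3, as run).
#' @return an object of class `qpcr_plate_spec`.
#' @export
qpcr_plate_spec <- function(e_tel = 1.91,
                            e_b2m = 1.88,
                            threshold_tel = 0.222,
                            threshold_b2m = 0.193,
                            cq_noise_sd = 0.05,
                            fluor_noise_sd = 0.01,
                            baseline_intercept = c(0.01, 0.05),
                            baseline_slope = c(0, 5e-4),
                            plateau = 2.5,
                            n_cycles = 50L,
                            calibrator_cq_tel = 20,
                            calibrator_cq_b2m = 26,
                            sample_cq_spread = 0.4,
                            n_triplicate = 3L) {
  if (e_tel <= 1 || e_tel > 2 || e_b2m <= 1 || e_b2m > 2) {
    abort("efficiencies must lie in (1, 2]")
  }
  if (n_cycles < 30) abort("n_cycles must be >= 30")
  if (threshold_tel <= 0 || threshold_b2m <= 0 ||
    plateau <= max(threshold_tel, threshold_b2m)) {
    abort("need plateau > threshold > 0")
  }
  if (cq_noise_sd < 0 || fluor_noise_sd < 0 || sample_cq_spread < 0) {
    abort("noise SDs must be >= 0")
  }
  structure(
    list(
      e_tel = e_tel, e_b2m = e_b2m,
      threshold_tel = threshold_tel, threshold_b2m = threshold_b2m,
      cq_noise_sd = cq_noise_sd, fluor_noise_sd = fluor_noise_sd,
      baseline_intercept = baseline_intercept, baseline_slope = baseline_slope,
      plateau = plateau, n_cycles = as.integer(n_cycles),
      calibrator_cq_tel = calibrator_cq_tel,
      calibrator_cq_b2m = calibrator_cq_b2m,
      sample_cq_spread = sample_cq_spread,
      n_triplicate = as.integer(n_triplicate),
      calibrator_rtl = 1
    ),
    class = "qpcr_plate_spec"
  )
}

# Render one well's curve. Returns fluorescence over cycles 1..n_cycles.
render_curve <- function(cq, efficiency, threshold, spec, amplify = TRUE) {
  cycles <- seq_len(spec$n_cycles)
  a <- runif(1, spec$baseline_intercept[1], spec$baseline_intercept[2])
  b <- runif(1, spec$baseline_slope[1], spec$baseline_slope[2])
  base <- a + b * cycles
  if (!amplify) {
    return(base)
  }
  f0 <- threshold * efficiency^(-cq)
  amp <- pmin(f0 * efficiency^cycles, spec$plateau)
  if (spec$fluor_noise_sd > 0) {
    amp <- amp * exp(rnorm(spec$n_cycles, 0, spec$fluor_noise_sd))
  }
  base + amp
}

well_rows <- function(plate_id, well_id, sample_id, amplicon, role, fluor) {
  tibble(
    plate_id = plate_id, well_id = well_id, sample_id = sample_id,
    amplicon = amplicon, role = role,
    cycle = seq_along(fluor), fluorescence = fluor
  )
}

#' Simulate raw amplification curves for a phenotyped population
#'
#' For each RTL observation, emits triplicate telomere (TEL) and B2M wells
#' whose true Cq values invert the calibrator-normalised RTL formula: with
#' the spec's efficiencies, processing the noiseless curves reproduces each
#' record's `rtl` exactly. Each plate additionally carries calibrator
#' triplicates for both amplicons (the calibrator's RTL is 1 by
#' construction) and no-template-control (NTC) wells containing baseline
#' fluorescence only.
#'
#' @param records tibble of RTL observations as produced by
#'   [sample_population()]; needs columns `sample_id`, `plate_id`, `rtl`
#'   with every `rtl > 0`.
#' @param spec a [qpcr_plate_spec()].
#' @param seed integer seed.
#' @return a long-format tibble, one row per well per cycle, with columns
#'   `plate_id`, `well_id`, `sample_id`, `amplicon` ("TEL"/"B2M"), `role`
#'   ("sample"/"calibrator"/"NTC"), `cycle`, `fluorescence`.
#' @examples
#' pop <- sample_population(soay_structure(n_obs = 4L, n_animals = 4L), seed = 1)
#' curves <- plates_from_phenotypes(pop, qpcr_plate_spec(), seed = 1)
#' dplyr::count(curves, role, amplicon)
#' @export
plates_from_phenotypes <- function(records, spec = qpcr_plate_spec(), seed = 1L) {
  req <- c("sample_id", "plate_id", "rtl")
  if (!all(req %in% names(records))) {
    abort("records must have columns sample_id, plate_id, rtl")
  }
  if (any(!is.finite(records$rtl)) || any(records$rtl <= 0)) {
    abort("all rtl values must be finite and > 0")
  }
  if (anyDuplicated(records$sample_id)) abort("sample_id must be unique")
  set.seed(seed)

  log_et <- log(spec$e_tel)
  log_eb <- log(spec$e_b2m)
  # invert RTL = E_T^(CqT_cal - CqT_s) / E_B^(CqB_cal - CqB_s):
  # draw the sample's B2M Cq (DNA input), solve for its TEL Cq
  cq_b2m_true <- spec$calibrator_cq_b2m +
    rnorm(nrow(records), 0, spec$sample_cq_spread)
  cq_tel_true <- spec$calibrator_cq_tel -
    (log(records$rtl) + (spec$calibrator_cq_b2m - cq_b2m_true) * log_eb) / log_et

  out <- vector("list", nrow(records) + length(unique(records$plate_id)))
  k <- 0L
  for (i in seq_len(nrow(records))) {
    sid <- records$sample_id[i]
    pid <- records$plate_id[i]
    rows <- vector("list", 2L * spec$n_triplicate)
    for (r in seq_len(spec$n_triplicate)) {
      cq_t <- cq_tel_true[i] + rnorm(1, 0, spec$cq_noise_sd)
      rows[[r]] <- well_rows(
        pid, sprintf("%s_%s_TEL_%d", pid, sid, r), sid, "TEL", "sample",
        render_curve(cq_t, spec$e_tel, spec$threshold_tel, spec)
      )
      cq_b <- cq_b2m_true[i] + rnorm(1, 0, spec$cq_noise_sd)
      rows[[spec$n_triplicate + r]] <- well_rows(
        pid, sprintf("%s_%s_B2M_%d", pid, sid, r), sid, "B2M", "sample",
        render_curve(cq_b, spec$e_b2m, spec$threshold_b2m, spec)
      )
    }
    k <- k + 1L
    out[[k]] <- bind_rows(rows)
  }
  for (pid in unique(records$plate_id)) {
    rows <- list()
    for (r in seq_len(spec$n_triplicate)) {
      cq_t <- spec$calibrator_cq_tel + rnorm(1, 0, spec$cq_noise_sd)
      rows[[length(rows) + 1L]] <- well_rows(
        pid, sprintf("%s_CAL_TEL_%d", pid, r), "CAL", "TEL", "calibrator",
        render_curve(cq_t, spec$e_tel, spec$threshold_tel, spec)
      )
      cq_b <- spec$calibrator_cq_b2m + rnorm(1, 0, spec$cq_noise_sd)
      rows[[length(rows) + 1L]] <- well_rows(
        pid, sprintf("%s_CAL_B2M_%d", pid, r), "CAL", "B2M", "calibrator",
        render_curve(cq_b, spec$e_b2m, spec$threshold_b2m, spec)
      )
      rows[[length(rows) + 1L]] <- well_rows(
        pid, sprintf("%s_NTC_TEL_%d", pid, r), "NTC", "TEL", "NTC",
        render_curve(NA, spec$e_tel, spec$threshold_tel, spec, amplify = FALSE)
      )
      rows[[length(rows) + 1L]] <- well_rows(
        pid, sprintf("%s_NTC_B2M_%d", pid, r), "NTC", "B2M", "NTC",
        render_curve(NA, spec$e_b2m, spec$threshold_b2m, spec, amplify = FALSE)
      )
    }
    k <- k + 1L
    out[[k]] <- bind_rows(rows)
  }
  bind_rows(out)
}
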
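# Raw amplification curves -> QC-filtered, calibrator-normalised RTL.
#
# Per-well: linear baseline subtraction, window-of-linearity search on
# log-fluorescence, efficiency E = exp(slope), Cq by log-linear threshold
# interpolation. Per-sample: triplicate CV and efficiency-deviation QC.
# Per-plate: amplicon-mean efficiencies and calibrator Cq means feeding
#   RTL = E_TEL^(CqTEL[Cal] - CqTEL[Sample]) / E_B2M^(CqB2M[Cal] - CqB2M[Sample]).

#' Subtract a linear baseline from amplification curves
#'
#' Fits fluorescence ~ cycle by least squares over the first
#' `n_baseline_cycles` cycles of each well and subtracts the fitted line
#' from the whole curve. Corrected fluorescence may be <= 0 in the baseline
#' region. `n_baseline_cycles = 0` disables the correction (curves already
#' baseline-free).
#'
#' @param curves long-format curve tibble (`plate_id`, `well_id`, `cycle`,
#'   `fluorescence`, plus metadata columns which are passed through).
#' @param n_baseline_cycles early cycles used for the baseline fit.
#' @return the input tibble with `fluorescence` replaced by its
#'   baseline-corrected value.
#' @export
correct_baseline <- function(curves, n_baseline_cycles = 8L) {
  check_curves(curves)
  if (n_baseline_cycles == 0) {
    return(curves)
  }
  n_min <- min(dplyr::count(curves, .data$plate_id, .data$well_id)$n)
  if (n_baseline_cycles < 2 || n_baseline_cycles > n_min) {
    abort("n_baseline_cycles must be >= 2 and <= the shortest curve")
  }
  fits <- curves %>%
    group_by(.data$plate_id, .data$well_id) %>%
    filter(row_number() <= n_baseline_cycles) %>%
    summarise(
      b = stats::cov(.data$cycle, .data$fluorescence) / stats::var(.data$cycle),
      a = mean(.data$fluorescence) - .data$b * mean(.data$cycle),
      .groups = "drop"
    )
  curves %>%
    left_join(fits, by = c("plate_id", "well_id")) %>%
    mutate(fluorescence = .data$fluorescence - .data$a - .data$b * .data$cycle) %>%
    select(-"a", -"b")
}

check_curves <- function(curves) {
  req <- c("plate_id", "well_id", "cycle", "fluorescence")
  if (!all(req %in% names(curves))) {
    abort(paste("curves must have columns:", paste(req, collapse = ", ")))
  }
  if (any(!is.finite(curves$fluorescence))) abort("fluorescence must be finite")
  invisible(curves)
}

# Window-of-linearity fit for one well (baseline-corrected values).
# Candidate windows of min_window..max_window consecutive cycles between the
# noise floor and plateau onset (first cycle within 5% of max) maximise the
# R^2 of log-fluorescence ~ cycle; ties prefer a window spanning the
# threshold, then the later window.
wol_estimate <- function(cycle, fluor, threshold = NULL,
                         min_window = 4L, max_window = 6L) {
  out <- list(
    efficiency = NA_real_, cq = NA_real_,
    window_start = NA_integer_, window_end = NA_integer_,
    qc_pass = FALSE, qc_reason = "ok"
  )
  fmax <- max(fluor)
  floor_val <- if (is.null(threshold)) 1e-3 * fmax else 1e-2 * threshold
  if (fmax <= floor_val || (!is.null(threshold) && fmax < threshold)) {
    out$qc_reason <- "non_amplifying"
    return(out)
  }
  plateau_onset <- which(fluor >= 0.95 * fmax)[1]
  eligible <- which(fluor > floor_val & seq_along(fluor) <= plateau_onset)
  if (length(eligible) < min_window) {
    out$qc_reason <- "window_too_short"
    return(out)
  }
  # contiguous eligible run ending at the plateau onset (the growth phase)
  brk <- which(diff(eligible) > 1)
  run_start <- if (length(brk)) eligible[max(brk) + 1L] else eligible[1]
  run <- run_start:eligible[length(eligible)]
  if (length(run) < min_window) {
    out$qc_reason <- "window_too_short"
    return(out)
  }
  lf <- log(ifelse(fluor > 0, fluor, NA_real_))
  best <- NULL # best window overall
  best_sp <- NULL # best window whose fluorescence span contains the threshold
  for (w in min_window:min(max_window, length(run))) {
    for (s in seq_len(length(run) - w + 1L)) {
      idx <- run[s:(s + w - 1L)]
      x <- cycle[idx]
      y <- lf[idx]
      sxx <- sum((x - mean(x))^2)
      sxy <- sum((x - mean(x)) * (y - mean(y)))
      syy <- sum((y - mean(y))^2)
      r2 <- if (syy > 0) (sxy^2 / sxx) / syy else 0
      spans <- !is.null(threshold) &&
        min(fluor[idx]) <= threshold && threshold <= max(fluor[idx])
      cand <- list(idx = idx, slope = sxy / sxx, r2 = r2, spans = spans)
      better <- function(old) {
        is.null(old) || r2 > old$r2 + 1e-12 ||
          (abs(r2 - old$r2) <= 1e-12 && idx[1] > old$idx[1])
      }
      if (better(best)) best <- cand
      if (spans && better(best_sp)) best_sp <- cand
    }
  }
  # a window containing the constant threshold is preferred: the threshold
  # is set "within the window of linearity", so Cq and E come from the
  # same exponential phase
  if (!is.null(best_sp)) best <- best_sp
  out$window_start <- cycle[best$idx[1]]
  out$window_end <- cycle[best$idx[length(best$idx)]]
  out$efficiency <- exp(best$slope)
  if (!is.finite(out$efficiency) || out$efficiency <= 1) {
    out$qc_reason <- "low_efficiency"
    return(out)
  }
  if (is.null(threshold)) {
    out$qc_pass <- TRUE
    return(out)
  }
  # log-linear interpolation of the first upward threshold crossing
  m <- length(fluor)
  crossings <- which(fluor[-1] >= threshold & fluor[-m] < threshold & fluor[-m] > 0) + 1L
  i <- crossings[1]
  if (is.na(i)) {
    out$qc_reason <- "no_threshold_crossing"
    return(out)
  }
  out$cq <- cycle[i - 1L] +
    (log(threshold) - lf[i - 1L]) / (lf[i] - lf[i - 1L]) *
      (cycle[i] - cycle[i - 1L])
  if (!best$spans) {
    out$qc_reason <- "threshold_outside_window"
    return(out)
  }
  out$qc_pass <- TRUE
  out
}

#' Estimate reaction efficiency and Cq for each well
#'
#' Searches each well's window of linearity (the 4-6 consecutive cycles
#' between noise floor and plateau onset maximising the linearity of
#' log-fluorescence), takes the efficiency as `exp(slope)` of the
#' log-fluorescence regression in that window, and interpolates the Cq at
#' which the corrected curve crosses the constant threshold (log-linear
#' interpolation). A well passes QC only if the threshold lies within the
#' window's fluorescence span; non-amplifying wells (e.g. NTCs) are flagged
#' with no Cq.
#'
#' @param curves baseline-corrected long-format curve tibble.
#' @param threshold constant fluorescence threshold, or a named vector
#'   `c(TEL = ..., B2M = ...)` applied per amplicon.
#' @param min_window,max_window window-of-linearity sizes (cycles).
#' @return one row per well: metadata plus `efficiency`, `cq`,
#'   `window_start`, `window_end`, `qc_pass`, `qc_reason`.
#' @export
estimate_efficiency_and_cq <- function(curves, threshold,
                                       min_window = 4L, max_window = 6L) {
  check_curves(curves)
  meta_cols <- intersect(
    c("plate_id", "well_id", "sample_id", "amplicon", "role"), names(curves)
  )
  split_wells(curves) %>%
    purrr::map(function(w) {
      thr <- if (length(threshold) > 1) threshold[[w$amplicon[1]]] else threshold
      est <- wol_estimate(w$cycle, w$fluorescence, thr, min_window, max_window)
      dplyr::bind_cols(
        w[1, meta_cols],
        tibble(
          threshold = thr, efficiency = est$efficiency, cq = est$cq,
          window_start = est$window_start, window_end = est$window_end,
          qc_pass = est$qc_pass, qc_reason = est$qc_reason
        )
      )
    }) %>%
    bind_rows()
}

split_wells <- function(curves) {
  key <- paste(curves$plate_id, curves$well_id, sep = "\r")
  split(curves, factor(key, levels = unique(key)))
}

#' Set a constant group threshold from the first k plates
#'
#' Reconstructs the thresholding convention in which a constant fluorescence
#' threshold is fixed for an amplicon group using the average Cq across the
#' first `k` plates: each well on those plates gets a provisional Cq at the
#' midpoint of its window of linearity, and the returned threshold is the
#' value (within the group's common window-fluorescence span) at which the
#' mean interpolated Cq equals the mean provisional Cq.
#'
#' @param curves baseline-corrected curve tibble (all plates; NTCs ignored).
#' @param amplicon "TEL" or "B2M".
#' @param k number of leading plates used (default 6).
#' @return a single threshold value.
#' @export
set_group_threshold <- function(curves, amplicon, k = 6L) {
  check_curves(curves)
  plates <- unique(curves$plate_id)
  use <- curves %>%
    filter(
      .data$amplicon == .env$amplicon, .data$role != "NTC",
      .data$plate_id %in% head(plates, k)
    )
  if (nrow(use) == 0) abort("no wells for this amplicon in the first k plates")
  wells <- split_wells(use)
  wins <- purrr::map(wells, function(w) {
    est <- wol_estimate(w$cycle, w$fluorescence, threshold = NULL)
    if (!est$qc_pass) {
      return(NULL)
    }
    idx <- which(w$cycle >= est$window_start & w$cycle <= est$window_end)
    list(
      cycle = w$cycle, lf = log(pmax(w$fluorescence, 1e-300)),
      fluor = w$fluorescence,
      fmin = min(w$fluorescence[idx]), fmax = max(w$fluorescence[idx]),
      prov_cq = mean(w$cycle[idx])
    )
  }) %>% purrr::compact()
  if (length(wins) == 0) abort("no amplifying wells found")
  lo <- max(purrr::map_dbl(wins, "fmin"))
  hi <- min(purrr::map_dbl(wins, "fmax"))
  if (!(lo > 0 && hi > lo)) { # no common span; fall back to central span
    lo <- stats::median(purrr::map_dbl(wins, "fmin"))
    hi <- stats::median(purrr::map_dbl(wins, "fmax"))
  }
  target <- mean(purrr::map_dbl(wins, "prov_cq"))
  mean_cq_at <- function(thr) {
    mean(purrr::map_dbl(wins, function(w) {
      interp_cq(w$cycle, w$fluor, w$lf, thr)
    }))
  }
  f_lo <- mean_cq_at(lo) - target
  f_hi <- mean_cq_at(hi) - target
  if (f_lo * f_hi > 0) {
    return(sqrt(lo * hi))
  } # target outside span: geometric midpoint
  uniroot(function(t) mean_cq_at(t) - target, c(lo, hi), tol = 1e-10)$root
}

interp_cq <- function(cycle, fluor, lf, threshold) {
  m <- length(fluor)
  crossings <- which(fluor[-1] >= threshold & fluor[-m] < threshold & fluor[-m] > 0) + 1L
  i <- crossings[1]
  if (is.na(i)) {
    return(NA_real_)
  }
  cycle[i - 1L] + (log(threshold) - lf[i - 1L]) / (lf[i] - lf[i - 1L]) *
    (cycle[i] - cycle[i - 1L])
}

#' Triplicate coefficient-of-variation QC
#'
#' CV = sample SD / mean of the triplicate Cq values on the cycle scale;
#' a triplicate fails if CV > `cv_limit` (default 5%), and a sample failing
#' on either amplicon is excluded. Fewer than three finite Cqs (e.g. a
#' non-amplifying replicate) fail with the distinct reason
#' `replicate_missing`.
#'
#' @param cqs numeric vector of triplicate Cq values.
#' @param cv_limit maximum allowed CV (proportion).
#' @return one-row tibble with `cv`, `pass`, `reason`.
#' @examples
#' triplicate_cv_qc(c(20, 21, 22)) # CV = 1/21, pass
#' triplicate_cv_qc(c(18, 21, 24)) # CV = 1/7, fail
#' @export
triplicate_cv_qc <- function(cqs, cv_limit = 0.05) {
  cqs <- cqs[is.finite(cqs)]
  if (length(cqs) < 3) {
    return(tibble(cv = NA_real_, pass = FALSE, reason = "replicate_missing"))
  }
  cv <- sd(cqs) / mean(cqs)
  tibble(
    cv = cv, pass = cv <= cv_limit,
    reason = ifelse(cv <= cv_limit, "ok", "cv")
  )
}

#' Per-well efficiency-deviation QC
#'
#' A replicate fails if its well efficiency deviates from the plate's mean
#' efficiency for that amplicon by more than `limit` (default 5%) in either
#' direction; any failing replicate excludes the sample.
#'
#' @param well_eff well efficiency (vectorised).
#' @param plate_amplicon_mean_eff plate-amplicon mean efficiency.
#' @param limit maximum relative deviation.
#' @return logical vector: `TRUE` = pass.
#' @examples
#' well_efficiency_qc(2.00, 1.90) # 5.26% deviation, fail
#' well_efficiency_qc(1.81, 1.90) # 4.74% deviation, pass
#' @export
well_efficiency_qc <- function(well_eff, plate_amplicon_mean_eff, limit = 0.05) {
  if (any(well_eff <= 1, na.rm = TRUE) || any(plate_amplicon_mean_eff <= 1)) {
    abort("efficiencies must be > 1")
  }
  abs(well_eff - plate_amplicon_mean_eff) / plate_amplicon_mean_eff <= limit
}

#' DNA extraction quality control
#'
#' A sample is accepted iff yield >= 20 ng/ul, the 260/280 absorbance ratio
#' lies in \[1.7, 2.0\], the 260/230 ratio lies in \[1.8, 2.2\], and the gel
#' integrity score (1-5) is at most 2. Samples failing on the first
#' extraction attempt are flagged for re-extraction; failure on the second
#' attempt is final exclusion.
#'
#' @param records tibble with columns `sample_id`, `yield_ng_per_ul`,
#'   `a260_280`, `a260_230`, `integrity_score` and optionally `attempt`
#'   (1 or 2, default 1).
#' @param yield_min,r260_280,r260_230,integrity_max QC limits.
#' @return the input with `accepted`, `reason`
#'   (first failing check: `low_yield`, `a260_280`, `a260_230`,
#'   `integrity`), and `status` (`accepted` / `reextract` / `excluded`).
#' @export
dna_sample_qc <- function(records, yield_min = 20, r260_280 = c(1.7, 2.0),
                          r260_230 = c(1.8, 2.2), integrity_max = 2L) {
  req <- c("sample_id", "yield_ng_per_ul", "a260_280", "a260_230", "integrity_score")
  if (!all(req %in% names(records))) {
    abort(paste("records must have columns:", paste(req, collapse = ", ")))
  }
  if (!all(complete.cases(records[req]))) abort("QC fields must not be missing")
  if (!all(records$integrity_score %in% 1:5)) {
    abort("integrity_score must be an integer in 1..5")
  }
  if (!"attempt" %in% names(records)) records$attempt <- 1L
  records %>%
    mutate(
      reason = case_when(
        .data$yield_ng_per_ul < yield_min ~ "low_yield",
        .data$a260_280 < r260_280[1] | .data$a260_280 > r260_280[2] ~ "a260_280",
        .data$a260_230 < r260_230[1] | .data$a260_230 > r260_230[2] ~ "a260_230",
        .data$integrity_score > integrity_max ~ "integrity",
        TRUE ~ "ok"
      ),
      accepted = .data$reason == "ok",
      status = case_when(
        .data$accepted ~ "accepted",
        .data$attempt >= 2L ~ "excluded",
        TRUE ~ "reextract"
      )
    )
}

#' Plate-level summaries: mean efficiencies and calibrator Cqs
#'
#' Mean reaction efficiency per plate and amplicon across QC-passing sample
#' and calibrator wells (NTCs never contribute), and the mean calibrator Cq
#' per plate and amplicon.
#'
#' @param wells per-well estimates from [estimate_efficiency_and_cq()].
#' @param use_all_wells include wells that failed window/threshold QC in
#'   the plate-mean efficiency (default `FALSE`: failed wells are excluded
#'   before averaging).
#' @return tibble with one row per plate: `plate_id`, `mean_eff_tel`,
#'   `mean_eff_b2m`, `calib_cq_tel`, `calib_cq_b2m`, `n_wells_tel`,
#'   `n_wells_b2m`.
#' @export
plate_summary <- function(wells, use_all_wells = FALSE) {
  eligible <- wells %>%
    filter(.data$role != "NTC", is.finite(.data$efficiency)) %>%
    filter(use_all_wells | .data$qc_pass)
  effs <- eligible %>%
    group_by(.data$plate_id, .data$amplicon) %>%
    summarise(mean_eff = mean(.data$efficiency), n_wells = n(), .groups = "drop") %>%
    tidyr::pivot_wider(
      names_from = "amplicon", values_from = c("mean_eff", "n_wells"),
      names_glue = "{.value}_{tolower(amplicon)}"
    )
  cals <- wells %>%
    filter(.data$role == "calibrator", .data$qc_pass, is.finite(.data$cq)) %>%
    group_by(.data$plate_id, .data$amplicon) %>%
    summarise(calib_cq = mean(.data$cq), .groups = "drop") %>%
    tidyr::pivot_wider(
      names_from = "amplicon", values_from = "calib_cq",
      names_glue = "calib_cq_{tolower(amplicon)}"
    )
  out <- left_join(effs, cals, by = "plate_id")
  need <- c("mean_eff_tel", "mean_eff_b2m", "calib_cq_tel", "calib_cq_b2m")
  for (nm in setdiff(need, names(out))) out[[nm]] <- NA_real_
  out %>% select(
    "plate_id", "mean_eff_tel", "mean_eff_b2m",
    "calib_cq_tel", "calib_cq_b2m", dplyr::starts_with("n_wells")
  )
}

#' Calibrator-normalised, efficiency-corrected RTL
#'
#' `RTL = E_TEL^(CqTEL[Calibrator] - CqTEL[Sample]) /
#'        E_B2M^(CqB2M[Calibrator] - CqB2M[Sample])`
#' using each plate's amplicon-mean efficiencies and mean calibrator Cqs.
#' A sample whose Cqs equal the calibrator's has RTL exactly 1.
#'
#' @param samples tibble with `sample_id`, `plate_id`, `cq_tel`, `cq_b2m`
#'   (triplicate-mean Cqs).
#' @param plates [plate_summary()] output.
#' @return `samples` with an `rtl` column.
#' @examples
#' plates <- tibble::tibble(
#'   plate_id = "P1", mean_eff_tel = 2, mean_eff_b2m = 2,
#'   calib_cq_tel = 21, calib_cq_b2m = 24
#' )
#' s <- tibble::tibble(sample_id = "S1", plate_id = "P1", cq_tel = 20, cq_b2m = 24)
#' compute_rtl(s, plates)$rtl # 2^1 / 2^0 = 2
#' @export
compute_rtl <- function(samples, plates) {
  req <- c("sample_id", "plate_id", "cq_tel", "cq_b2m")
  if (!all(req %in% names(samples))) {
    abort(paste("samples must have columns:", paste(req, collapse = ", ")))
  }
  merged <- left_join(samples, plates, by = "plate_id")
  if (any(is.na(merged$calib_cq_tel) | is.na(merged$calib_cq_b2m))) {
    abort("missing calibrator Cq for at least one plate")
  }
  if (any(merged$mean_eff_tel <= 1 | merged$mean_eff_b2m <= 1)) {
    abort("plate mean efficiencies must be > 1")
  }
  merged %>%
    mutate(
      rtl = .data$mean_eff_tel^(.data$calib_cq_tel - .data$cq_tel) /
        .data$mean_eff_b2m^(.data$calib_cq_b2m - .data$cq_b2m)
    ) %>%
    select(dplyr::all_of(names(samples)), "rtl")
}

#' Process raw qPCR plates into QC-filtered RTL values
#'
#' Full measurement pipeline: baseline correction, per-well efficiency and
#' Cq estimation at the per-amplicon thresholds, plate summaries, triplicate
#' CV QC (> `cv_limit` on either amplicon excludes the sample), replicate
#' efficiency QC (any replicate deviating > `eff_limit` from the plate
#' amplicon mean excludes the sample), and RTL computation for surviving
#' samples. QC filters are order-independent; each excluded sample carries
#' one primary reason (`replicate_missing` > `cv` > `efficiency`).
#'
#' @param curves raw long-format curve tibble from
#'   [plates_from_phenotypes()] or [read_plates()].
#' @param threshold_tel,threshold_b2m constant fluorescence thresholds.
#' @param cv_limit,eff_limit QC limits (proportions).
#' @param n_baseline_cycles early cycles for baseline fitting (0 = skip).
#' @param use_all_wells passed to [plate_summary()].
#' @return an object of class `rtl_processing`: a list with tibbles
#'   `rtl` (per sample: Cq means, `rtl`, `excluded`, `reason`), `wells`,
#'   `plates`, and a `counts` summary.
#' @export
process_plates <- function(curves,
                           threshold_tel = 0.222,
                           threshold_b2m = 0.193,
                           cv_limit = 0.05,
                           eff_limit = 0.05,
                           n_baseline_cycles = 8L,
                           use_all_wells = FALSE) {
  corrected <- correct_baseline(curves, n_baseline_cycles)
  wells <- estimate_efficiency_and_cq(
    corrected,
    threshold = c(TEL = threshold_tel, B2M = threshold_b2m)
  )
  plates <- plate_summary(wells, use_all_wells = use_all_wells)

  sw <- wells %>%
    filter(.data$role == "sample") %>%
    left_join(
      plates %>%
        tidyr::pivot_longer(c("mean_eff_tel", "mean_eff_b2m"),
          names_to = "amplicon", values_to = "plate_mean_eff"
        ) %>%
        mutate(amplicon = toupper(sub("mean_eff_", "", .data$amplicon))) %>%
        select("plate_id", "amplicon", "plate_mean_eff"),
      by = c("plate_id", "amplicon")
    ) %>%
    mutate(
      eff_ok = is.finite(.data$efficiency) & .data$efficiency > 1 &
        abs(.data$efficiency - .data$plate_mean_eff) / .data$plate_mean_eff <= eff_limit
    )

  per_amp <- sw %>%
    group_by(.data$sample_id, .data$plate_id, .data$amplicon) %>%
    summarise(
      n_ok = sum(.data$qc_pass & is.finite(.data$cq)),
      cq_mean = mean(.data$cq[.data$qc_pass & is.finite(.data$cq)]),
      cq_sd = sd(.data$cq[.data$qc_pass & is.finite(.data$cq)]),
      any_eff_fail = any(!.data$eff_ok),
      .groups = "drop"
    ) %>%
    mutate(cv = ifelse(.data$n_ok >= 3, .data$cq_sd / .data$cq_mean, NA_real_))

  status <- per_amp %>%
    group_by(.data$sample_id, .data$plate_id) %>%
    summarise(
      missing = any(.data$n_ok < 3),
      cv_fail = any(is.finite(.data$cv) & .data$cv > cv_limit),
      eff_fail = any(.data$any_eff_fail),
      cq_tel = .data$cq_mean[.data$amplicon == "TEL"][1],
      cq_b2m = .data$cq_mean[.data$amplicon == "B2M"][1],
      .groups = "drop"
    ) %>%
    mutate(
      reason = case_when(
        .data$missing ~ "replicate_missing",
        .data$cv_fail ~ "cv",
        .data$eff_fail ~ "efficiency",
        TRUE ~ "ok"
      ),
      excluded = .data$reason != "ok"
    )

  kept <- status %>% filter(!.data$excluded)
  rtl <- if (nrow(kept) > 0) {
    compute_rtl(
      kept %>% select("sample_id", "plate_id", "cq_tel", "cq_b2m"), plates
    )
  } else {
    tibble(
      sample_id = character(), plate_id = character(),
      cq_tel = double(), cq_b2m = double(), rtl = double()
    )
  }
  result <- status %>%
    select("sample_id", "plate_id", "cq_tel", "cq_b2m", "excluded", "reason") %>%
    left_join(rtl %>% select("sample_id", "rtl"), by = "sample_id") %>%
    arrange(.data$sample_id)

  counts <- tibble(
    n_samples = nrow(status),
    n_analyzed = sum(!status$excluded),
    n_excluded = sum(status$excluded),
    n_excluded_replicate = sum(status$reason == "replicate_missing"),
    n_excluded_cv = sum(status$reason == "cv"),
    n_excluded_efficiency = sum(status$reason == "efficiency")
  )
  structure(
    list(
      rtl = result, wells = wells, plates = plates, counts = counts,
      thresholds = c(TEL = threshold_tel, B2M = threshold_b2m)
    ),
    class = "rtl_processing"
  )
}

#' @export
print.rtl_processing <- function(x, ...) {
  cat("<rtl_processing>\n")
  cat(sprintf(
    "  %d samples on %d plates: %d analysed, %d excluded (replicate %d, CV %d, efficiency %d)\n",
    x$counts$n_samples, nrow(x$plates), x$counts$n_analyzed,
    x$counts$n_excluded, x$counts$n_excluded_replicate,
    x$counts$n_excluded_cv, x$counts$n_excluded_efficiency
  ))
  invisible(x)
}

#' @rdname process_plates
#' @param x an `rtl_processing` object.
#' @param ... unused.
#' @export
tidy.rtl_processing <- function(x, ...) x$rtl
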
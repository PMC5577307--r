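make_curve <- function(f0, eff, n_cycles = 50, baseline_a = 0, baseline_b = 0,
                       plateau = Inf, well = "W1", plate = "P1",
                       amplicon = "TEL", role = "sample", sample = "S1") {
  cyc <- seq_len(n_cycles)
  tibble::tibble(
    plate_id = plate, well_id = well, sample_id = sample,
    amplicon = amplicon, role = role, cycle = cyc,
    fluorescence = baseline_a + baseline_b * cyc + pmin(f0 * eff^cyc, plateau)
  )
}

test_that("baseline correction removes a pure linear baseline", {
  cur <- make_curve(0, 2, baseline_a = 0.04, baseline_b = 3e-4)
  out <- correct_baseline(cur, 8)
  expect_lt(max(abs(out$fluorescence)), 1e-12)
  expect_error(correct_baseline(cur, 60), "shortest curve")
  expect_identical(correct_baseline(cur, 0), cur)
})

test_that("log-fluorescence of a corrected exponential is linear with slope log E", {
  eff <- 1.9
  thr <- 0.2
  cur <- make_curve(thr * eff^-25, eff,
    baseline_a = 0.03, baseline_b = 2e-4, plateau = 2.5
  )
  out <- correct_baseline(cur, 8)
  grow <- dplyr::filter(out, cycle >= 20, cycle <= 24)
  slope <- coef(lm(log(fluorescence) ~ cycle, grow))[2]
  expect_equal(unname(slope), log(eff), tolerance = 1e-3)
})

test_that("efficiency and Cq are recovered exactly from a noiseless curve", {
  # F = F0 * 2^c with F0 = threshold * 2^-20: closed form Cq = 20, E = 2
  thr <- 0.2
  cur <- make_curve(thr * 2^-20, 2, plateau = 2.5)
  est <- estimate_efficiency_and_cq(cur, thr)
  expect_equal(est$efficiency, 2, tolerance = 1e-6)
  expect_equal(est$cq, 20, tolerance = 1e-6)
  expect_true(est$qc_pass)

  est19 <- estimate_efficiency_and_cq(
    make_curve(thr * 1.9^-22, 1.9, plateau = 2.5), thr
  )
  expect_equal(est19$efficiency, 1.9, tolerance = 0.02 / 1.9)
  expect_equal(est19$cq, 22, tolerance = 0.05 / 22)
})

test_that("non-amplifying (NTC) wells are flagged and get no Cq", {
  ntc <- make_curve(0, 2, baseline_a = 0.03, baseline_b = 1e-4, role = "NTC")
  est <- estimate_efficiency_and_cq(correct_baseline(ntc, 8), 0.2)
  expect_false(est$qc_pass)
  expect_equal(est$qc_reason, "non_amplifying")
  expect_true(is.na(est$cq))
})

test_that("per-amplicon thresholds are applied and echoed in output", {
  cur <- dplyr::bind_rows(
    make_curve(0.222 * 1.91^-20, 1.91, well = "W1", amplicon = "TEL", plateau = 2.5),
    make_curve(0.193 * 1.88^-24, 1.88, well = "W2", amplicon = "B2M", plateau = 2.5)
  )
  est <- estimate_efficiency_and_cq(cur, c(TEL = 0.222, B2M = 0.193))
  expect_equal(est$threshold[est$amplicon == "TEL"], 0.222)
  expect_equal(est$threshold[est$amplicon == "B2M"], 0.193)
  expect_equal(est$cq, c(20, 24), tolerance = 1e-6)
})

test_that("group threshold lies in every window and is deterministic with k plates", {
  set.seed(42)
  pop <- sample_population(small_structure(), seed = 2)
  cur <- correct_baseline(
    plates_from_phenotypes(pop, qpcr_plate_spec(), seed = 2), 8
  )
  thr <- set_group_threshold(cur, "TEL", k = 6)
  thr2 <- set_group_threshold(cur, "TEL", k = 6)
  expect_identical(thr, thr2)
  wells <- estimate_efficiency_and_cq(
    dplyr::filter(cur, amplicon == "TEL", role != "NTC"), thr
  )
  # the constant threshold sits inside the window of linearity of the wells
  expect_gt(mean(wells$qc_pass), 0.95)
  expect_equal(formals(set_group_threshold)$k, 6L)
})

test_that("triplicate CV follows the sample-SD/mean definition with a 5% limit", {
  expect_equal(triplicate_cv_qc(c(20, 20, 20))$cv, 0)
  expect_true(triplicate_cv_qc(c(20, 20, 20))$pass)
  r <- triplicate_cv_qc(c(20, 21, 22))
  expect_equal(r$cv, 1 / 21)
  expect_true(r$pass)
  r2 <- triplicate_cv_qc(c(18, 21, 24))
  expect_equal(r2$cv, 3 / 21)
  expect_false(r2$pass)
  expect_equal(r2$reason, "cv")
  r3 <- triplicate_cv_qc(c(20, 21, NA))
  expect_false(r3$pass)
  expect_equal(r3$reason, "replicate_missing")
})

test_that("well efficiency QC fails beyond 5% deviation from the plate mean", {
  expect_true(well_efficiency_qc(1.90, 1.90))
  expect_false(well_efficiency_qc(2.00, 1.90)) # 5.26% off
  expect_true(well_efficiency_qc(1.81, 1.90)) # 4.74% off
  expect_error(well_efficiency_qc(0.9, 1.9), "must be > 1")
})

test_that("DNA QC enforces yield, purity ratios, integrity, and one retry", {
  rec <- tibble::tibble(
    sample_id = c("a", "b", "c", "d", "e"),
    yield_ng_per_ul = c(19, 50, 50, 50, 50),
    a260_280 = c(1.85, 1.85, 1.85, 2.1, 1.85),
    a260_230 = c(2.0, 2.0, 2.0, 2.0, 2.0),
    integrity_score = c(1L, 2L, 3L, 1L, 1L),
    attempt = c(1L, 1L, 1L, 2L, 2L)
  )
  out <- dna_sample_qc(rec)
  expect_equal(out$reason, c("low_yield", "ok", "integrity", "a260_280", "ok"))
  expect_equal(out$accepted, c(FALSE, TRUE, FALSE, FALSE, TRUE))
  # failed first attempts are re-extracted; failed second attempts are final
  expect_equal(out$status, c("reextract", "accepted", "reextract", "excluded", "accepted"))
  expect_error(dna_sample_qc(rec[, -2]), "must have columns")
})

test_that("RTL follows the calibrator/efficiency-corrected formula", {
  plates <- tibble::tibble(
    plate_id = "P1", mean_eff_tel = 2, mean_eff_b2m = 2,
    calib_cq_tel = 21, calib_cq_b2m = 24
  )
  # sample Cqs equal to the calibrator's normalise to exactly 1
  s0 <- tibble::tibble(sample_id = "S0", plate_id = "P1", cq_tel = 21, cq_b2m = 24)
  expect_identical(compute_rtl(s0, plates)$rtl, 1)
  # delta-Cq TEL = 1, B2M = 0 at E = 2 doubles RTL
  s1 <- tibble::tibble(sample_id = "S1", plate_id = "P1", cq_tel = 20, cq_b2m = 24)
  expect_equal(compute_rtl(s1, plates)$rtl, 2)
  # printed plate-mean efficiencies: 1.91^0.5 * 1.88^0.25
  p2 <- tibble::tibble(
    plate_id = "P1", mean_eff_tel = 1.91, mean_eff_b2m = 1.88,
    calib_cq_tel = 20.5, calib_cq_b2m = 23.75
  )
  s2 <- tibble::tibble(sample_id = "S2", plate_id = "P1", cq_tel = 20, cq_b2m = 24)
  expect_equal(compute_rtl(s2, p2)$rtl, 1.91^0.5 * 1.88^0.25, tolerance = 1e-12)
  expect_equal(compute_rtl(s2, p2)$rtl, 1.618, tolerance = 1e-3)
  # missing calibrator is a plate error
  p3 <- dplyr::mutate(p2, calib_cq_tel = NA_real_)
  expect_error(compute_rtl(s2, p3), "calibrator")
  p4 <- dplyr::mutate(p2, mean_eff_b2m = 0.99)
  expect_error(compute_rtl(s2, p4), "> 1")
})

test_that("RTL is invariant to a common Cq shift and decreasing in sample TEL Cq", {
  plates <- tibble::tibble(
    plate_id = "P1", mean_eff_tel = 1.91, mean_eff_b2m = 1.88,
    calib_cq_tel = 20, calib_cq_b2m = 26
  )
  s <- tibble::tibble(sample_id = "S1", plate_id = "P1", cq_tel = 19.2, cq_b2m = 25.5)
  base <- compute_rtl(s, plates)$rtl
  # shifting calibrator and sample Cqs of one amplicon together cancels
  shifted <- compute_rtl(
    dplyr::mutate(s, cq_tel = cq_tel + 1.3),
    dplyr::mutate(plates, calib_cq_tel = calib_cq_tel + 1.3)
  )$rtl
  expect_equal(shifted, base, tolerance = 1e-12)
  # monotonicity in CqTEL[Sample] with B2M held fixed
  cqs <- seq(18, 22, by = 0.5)
  rtls <- purrr::map_dbl(cqs, function(cq) {
    compute_rtl(dplyr::mutate(s, cq_tel = cq), plates)$rtl
  })
  expect_true(all(diff(rtls) < 0))
})

test_that("QC exclusion reasons are order-independent and singly attributed", {
  pop <- sample_population(small_structure(), seed = 8)
  cur <- plates_from_phenotypes(pop, qpcr_plate_spec(cq_noise_sd = 0.02), seed = 8)
  # delay one TEL replicate of one sample by 3 cycles (CV failure) and
  # knock out one replicate of another (replicate_missing)
  cv_sample <- pop$sample_id[1]
  miss_sample <- pop$sample_id[2]
  cur <- dplyr::mutate(cur,
    fluorescence = ifelse(
      sample_id == cv_sample & grepl("TEL_1$", well_id),
      fluorescence * 1.91^-3, fluorescence
    )
  )
  cur <- dplyr::filter(cur, !(sample_id == miss_sample & grepl("B2M_1$", well_id)))
  proc <- process_plates(cur)
  r <- proc$rtl
  expect_equal(r$reason[r$sample_id == cv_sample], "cv")
  expect_equal(r$reason[r$sample_id == miss_sample], "replicate_missing")
  expect_true(all(r$reason %in% c("ok", "replicate_missing", "cv", "efficiency")))
  expect_equal(sum(proc$counts[c(
    "n_excluded_replicate", "n_excluded_cv", "n_excluded_efficiency"
  )]), proc$counts$n_excluded)
  expect_equal(proc$counts$n_analyzed + proc$counts$n_excluded, proc$counts$n_samples)
})

test_that("noisy Cq recovery matches direct error propagation of the RTL formula", {
  pop <- sample_population(
    soay_structure(n_obs = 150L, n_animals = 150L, n_plates = 3L),
    seed = 21
  )
  run_sigma <- function(sigma, seed) {
    spec <- noiseless_spec(cq_noise_sd = sigma)
    cur <- plates_from_phenotypes(pop, spec, seed = seed)
    proc <- process_plates(cur, n_baseline_cycles = 0L)
    m <- dplyr::inner_join(
      pop[, c("sample_id", "rtl")],
      dplyr::filter(proc$rtl, !excluded)[, c("sample_id", "rtl")],
      by = "sample_id", suffix = c("_true", "_est")
    )
    mean(abs(m$rtl_est / m$rtl_true - 1) < 0.1)
  }
  # the propagation oracle predicts the fraction recovered within +/-10%
  frac_10 <- run_sigma(0.1, 31)
  pred_10 <- rtl_noise_pass_prob(0.1)
  expect_equal(frac_10, pred_10, tolerance = 3 * sqrt(pred_10 * (1 - pred_10) / 150) / pred_10)
  # at sigma = 0.05 the oracle puts >= 95% of samples within +/-10%
  expect_gt(rtl_noise_pass_prob(0.05), 0.95)
  expect_gt(run_sigma(0.05, 32), 0.95)
})
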
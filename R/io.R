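# Delimited-text I/O with schema validation, run configuration, and the
# end-to-end pipeline driver with its manifest.

PHENOTYPE_SCHEMA <- c(
  sample_id = "c", animal_id = "c", sample_year = "c", age = "d", sex = "c",
  mother_id = "c", father_id = "c", plate_id = "c", mac = "i", pac = "i",
  rtl = "d"
)
PLATE_SCHEMA <- c(
  plate_id = "c", well_id = "c", sample_id = "c", amplicon = "c", role = "c",
  cycle = "i", fluorescence = "d"
)
RTL_SCHEMA <- c(
  sample_id = "c", plate_id = "c", cq_tel = "d", cq_b2m = "d",
  excluded = "l", reason = "c", rtl = "d"
)

read_table_schema <- function(path, schema, name) {
  df <- readr::read_tsv(
    path,
    col_types = paste(unname(schema), collapse = ""), na = "NA",
    progress = FALSE, show_col_types = FALSE
  )
  missing_cols <- setdiff(names(schema), names(df))
  if (length(missing_cols)) {
    abort(sprintf(
      "%s file %s lacks columns: %s", name, path,
      paste(missing_cols, collapse = ", ")
    ))
  }
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    abort(sprintf(
      "%s file %s: parse problem at row %d, column %d (%s)",
      name, path, prob$row[1], prob$col[1], prob$expected[1]
    ))
  }
  df[names(schema)]
}

#' Read and write the phenotype, plate and RTL tables
#'
#' All tables are tab-separated text with a header row and `NA` as the
#' missing-value marker; `read_*(write_*(x))` is the identity. Schemas:
#' phenotypes — `sample_id, animal_id, sample_year, age, sex, mother_id,
#' father_id, plate_id, mac, pac, rtl`; plates (long format, one row per
#' well per cycle) — `plate_id, well_id, sample_id, amplicon, role, cycle,
#' fluorescence`; RTL — `sample_id, plate_id, cq_tel, cq_b2m, excluded,
#' reason, rtl`. Schema violations are reported with the offending row and
#' column.
#'
#' @param x table to write.
#' @param path file path.
#' @return readers return a validated tibble; writers return `path`
#'   invisibly.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_phenotypes <- function(x, path) {
  validate_phenotypes(x)
  readr::write_tsv(x[names(PHENOTYPE_SCHEMA)], path, na = "NA")
  invisible(path)
}

#' @rdname table_io
#' @export
read_phenotypes <- function(path) {
  df <- read_table_schema(path, PHENOTYPE_SCHEMA, "phenotype")
  validate_phenotypes(df)
  df$sample_year <- factor(df$sample_year, levels = sort(unique(df$sample_year)))
  df$sex <- factor(df$sex, levels = c("F", "M"))
  df
}

validate_phenotypes <- function(df) {
  missing_cols <- setdiff(names(PHENOTYPE_SCHEMA), names(df))
  if (length(missing_cols)) {
    abort(paste("phenotypes lack columns:", paste(missing_cols, collapse = ", ")))
  }
  bad_sex <- which(!as.character(df$sex) %in% c("F", "M"))
  if (length(bad_sex)) {
    abort(sprintf(
      "unknown sex code %s at row %d",
      as.character(df$sex)[bad_sex[1]], bad_sex[1]
    ))
  }
  bad_age <- which(!is.na(df$mac) & (df$mac < 1 | df$mac != round(df$mac)) |
    !is.na(df$pac) & (df$pac < 1 | df$pac != round(df$pac)))
  if (length(bad_age)) {
    abort(sprintf("mac/pac must be integers >= 1 (row %d)", bad_age[1]))
  }
  invisible(df)
}

#' @rdname table_io
#' @export
write_plates <- function(x, path) {
  check_curves(x)
  readr::write_tsv(x[names(PLATE_SCHEMA)], path, na = "NA")
  invisible(path)
}

#' @rdname table_io
#' @export
read_plates <- function(path) {
  df <- read_table_schema(path, PLATE_SCHEMA, "plate")
  bad <- which(!df$amplicon %in% c("TEL", "B2M"))
  if (length(bad)) {
    abort(sprintf("unknown amplicon %s at row %d", df$amplicon[bad[1]], bad[1]))
  }
  bad <- which(!df$role %in% c("sample", "calibrator", "NTC"))
  if (length(bad)) {
    abort(sprintf("unknown role %s at row %d", df$role[bad[1]], bad[1]))
  }
  df
}

#' @rdname table_io
#' @export
write_rtl <- function(x, path) {
  readr::write_tsv(x[names(RTL_SCHEMA)], path, na = "NA")
  invisible(path)
}

#' @rdname table_io
#' @export
read_rtl <- function(path) {
  read_table_schema(path, RTL_SCHEMA, "RTL")
}

#' Map an externally formatted phenotype table onto the package schema
#'
#' Column names of external datasets are not hard-coded anywhere: a named
#' character mapping (package column = external column) adapts any
#' delimited table to the [read_phenotypes()] schema. Unmapped optional
#' columns are filled with `NA`.
#'
#' @param df external data frame.
#' @param mapping named character vector, e.g.
#'   `c(rtl = "RelTL", mac = "MumAgeConc", ...)`.
#' @return a tibble in the package phenotype schema.
#' @export
map_phenotypes <- function(df, mapping) {
  unknown <- setdiff(names(mapping), names(PHENOTYPE_SCHEMA))
  if (length(unknown)) {
    abort(paste("mapping targets unknown columns:", paste(unknown, collapse = ", ")))
  }
  absent <- setdiff(unname(mapping), names(df))
  if (length(absent)) {
    abort(paste("external table lacks columns:", paste(absent, collapse = ", ")))
  }
  out <- tibble(.rows = nrow(df))
  for (col in names(PHENOTYPE_SCHEMA)) {
    out[[col]] <- if (col %in% names(mapping)) df[[mapping[[col]]]] else NA
  }
  out$sample_year <- factor(as.character(out$sample_year))
  out$sex <- factor(as.character(out$sex), levels = c("F", "M"))
  if (all(is.na(out$sample_id))) out$sample_id <- sprintf("S%04d", seq_len(nrow(out)))
  validate_phenotypes(out)
  out
}

#' Pipeline run configuration
#'
#' All tunable thresholds and defaults in one validated list, with the
#' published measurement-protocol values as defaults: qPCR thresholds
#' 0.222 (TEL) / 0.193 (B2M), triplicate CV limit 5%, replicate efficiency
#' deviation limit 5%, DNA QC limits (yield >= 20 ng/ul, 260/280 in
#' 1.7-2.0, 260/230 in 1.8-2.2, integrity <= 2), test size 0.05, ML
#' estimation. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults (see Details in the vignette).
#' @return an object of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1L,
    threshold_tel = 0.222,
    threshold_b2m = 0.193,
    cv_limit = 0.05,
    eff_limit = 0.05,
    n_baseline_cycles = 8L,
    use_all_wells = FALSE,
    dna_yield_min = 20,
    dna_r260_280 = c(1.7, 2.0),
    dna_r260_230 = c(1.8, 2.2),
    dna_integrity_max = 2L,
    alpha = 0.05,
    estimation = "ML",
    cq_noise_sd = 0.05,
    run_power = FALSE,
    power_effects = c(0, 0.012, 0.033),
    power_n_reps = 100L,
    structure = list()
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    abort(paste("unknown config keys:", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, overrides)
  if (cfg$alpha <= 0 || cfg$alpha >= 1) abort("alpha must be in (0, 1)")
  if (!cfg$estimation %in% c("ML", "REML")) abort("estimation must be ML or REML")
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Run the full pipeline: simulate, process, fit, power
#'
#' Executes simulate (phenotypes + raw plates) -> qPCR processing ->
#' merge of measured RTL onto phenotypes -> parental-age LRTs -> optional
#' power analysis, writing every stage's outputs under `out_dir` together
#' with a manifest recording the configuration snapshot, package version,
#' seeds, input file digests, and per-stage record counts (generated /
#' QC-excluded / analysed). Idempotent given the seed.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest, an object of class `run_manifest`, invisibly
#'   written to `manifest.json`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("telopac_run_")) {
  if (!inherits(config, "run_config")) abort("config must be a run_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  manifest <- list(
    package_version = as.character(packageVersion("telopac")),
    config = unclass(config),
    out_dir = out_dir,
    stages = list()
  )
  result <- tryCatch(
    {
      params <- do.call(soay_structure, c(config$structure, list(seed = config$seed)))
      pheno <- sample_population(params)
      pheno_path <- file.path(out_dir, "phenotypes.tsv")
      write_phenotypes(pheno, pheno_path)
      spec <- qpcr_plate_spec(
        threshold_tel = config$threshold_tel,
        threshold_b2m = config$threshold_b2m,
        cq_noise_sd = config$cq_noise_sd
      )
      curves <- plates_from_phenotypes(pheno, spec, seed = config$seed + 1L)
      plates_path <- file.path(out_dir, "plates.tsv")
      write_plates(curves, plates_path)
      manifest$stages$simulate <- list(
        n_phenotypes = nrow(pheno), n_wells = length(unique(curves$well_id)),
        files = list(phenotypes = pheno_path, plates = plates_path)
      )

      stage <- "process_qpcr"
      proc <- process_plates(
        curves,
        threshold_tel = config$threshold_tel,
        threshold_b2m = config$threshold_b2m,
        cv_limit = config$cv_limit,
        eff_limit = config$eff_limit,
        n_baseline_cycles = config$n_baseline_cycles,
        use_all_wells = config$use_all_wells
      )
      rtl_path <- file.path(out_dir, "rtl.tsv")
      write_rtl(proc$rtl, rtl_path)
      manifest$stages$process_qpcr <- c(
        as.list(proc$counts),
        list(files = list(rtl = rtl_path))
      )

      stage <- "merge"
      analysed <- pheno %>%
        select(-"rtl") %>%
        dplyr::inner_join(
          proc$rtl %>% filter(!.data$excluded) %>% select("sample_id", "rtl"),
          by = "sample_id"
        )
      merged_path <- file.path(out_dir, "analysed_phenotypes.tsv")
      write_phenotypes(analysed, merged_path)
      manifest$stages$merge <- list(
        n_analyzed = nrow(analysed),
        n_excluded = nrow(pheno) - nrow(analysed),
        files = list(analysed = merged_path)
      )

      stage <- "fit"
      tests <- bind_rows(
        test_parental_age(analysed, "MAC", "linear"),
        test_parental_age(analysed, "MAC", "quadratic"),
        test_parental_age(analysed, "PAC", "linear"),
        test_parental_age(analysed, "PAC", "quadratic")
      )
      base_fit <- fit_rtl_lmm(analysed, rtl_model_spec(estimation = config$estimation))
      summary_tbl <- bind_rows(
        tidy(base_fit) %>%
          mutate(chisq = NA_real_, df = NA_integer_, p_value = NA_real_) %>%
          rename(term_tested = "term") %>%
          select("term_tested", "estimate", "se", "chisq", "df", "p_value"),
        tests %>% mutate(estimate = NA_real_, se = NA_real_) %>%
          select("term_tested", "estimate", "se", "chisq", "df", "p_value")
      )
      model_path <- file.path(out_dir, "model_summary.tsv")
      readr::write_tsv(summary_tbl, model_path, na = "NA")
      manifest$stages$fit <- list(
        n_obs = base_fit$n_obs, loglik = base_fit$loglik,
        converged = base_fit$converged,
        tests = purrr::transpose(as.list(tests)),
        files = list(model_summary = model_path)
      )

      if (isTRUE(config$run_power)) {
        stage <- "power"
        pw <- estimate_power(
          config$power_effects,
          structure = params,
          n_reps = config$power_n_reps, alpha = config$alpha,
          seed = config$seed + 2L
        )
        power_path <- file.path(out_dir, "power_curve.tsv")
        readr::write_tsv(as_tibble(pw), power_path, na = "NA")
        manifest$stages$power <- list(
          n_reps = config$power_n_reps, files = list(power_curve = power_path)
        )
      }
      manifest$status <- "ok"
      manifest
    },
    error = function(e) {
      manifest$status <- "failed"
      manifest$failed_stage <- stage
      manifest$error <- conditionMessage(e)
      manifest
    }
  )
  files <- unlist(purrr::map(result$stages, function(s) unlist(s$files)))
  if (length(files)) {
    result$input_digests <- as.list(tools::md5sum(unname(files)))
  }
  class(result) <- "run_manifest"
  jsonlite::write_json(
    unclass(result), file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE
  )
  if (identical(result$status, "failed")) {
    abort(sprintf(
      "pipeline failed at stage %s: %s", result$failed_stage, result$error
    ))
  }
  invisible(result)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>", x$status, "\n")
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    counts <- s[vapply(s, is.numeric, logical(1))]
    cat(sprintf(
      "  %s: %s\n", nm,
      paste(sprintf("%s=%s", names(counts), counts), collapse = ", ")
    ))
  }
  invisible(x)
}
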
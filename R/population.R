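# Synthetic sheep population: phenotypes, pedigree links, and true RTL values
# with crossed mother/father/plate random intercepts.

#' Truncated geometric probabilities over an integer range
#'
#' Integer ages at conception are modelled with a geometric-like decay over a
#' closed range: P(k) is proportional to (1 - p)^(k - min). Small p approaches
#' a discrete uniform; large p concentrates mass at the youngest age.
#'
#' @param p decay parameter in (0, 1).
#' @param range integer vector `c(min, max)`, min >= 1.
#' @return numeric vector of probabilities over `range[1]:range[2]`.
#' @keywords internal
tgeom_probs <- function(p, range) {
  stopifnot(p > 0, p < 1, length(range) == 2, range[1] >= 1, range[2] >= range[1])
  k <- range[1]:range[2]
  w <- (1 - p)^(k - range[1])
  w / sum(w)
}

tgeom_moments <- function(p, range) {
  pr <- tgeom_probs(p, range)
  k <- range[1]:range[2]
  mu <- sum(pr * k)
  list(mean = mu, sd = sqrt(sum(pr * (k - mu)^2)))
}

#' Solve the truncated-geometric decay for a target standard deviation
#'
#' @param target_sd target SD of the distribution (years).
#' @param range inclusive integer range.
#' @return decay parameter `p`.
#' @keywords internal
tgeom_shape_for_sd <- function(target_sd, range) {
  if (range[1] == range[2]) abort("degenerate range has SD 0")
  sd_max <- tgeom_moments(1e-9, range)$sd
  if (target_sd >= sd_max || target_sd <= 0) {
    abort(sprintf(
      "target SD %.3f not attainable on [%d, %d] (max %.3f)",
      target_sd, range[1], range[2], sd_max
    ))
  }
  uniroot(
    function(p) tgeom_moments(p, range)$sd - target_sd,
    interval = c(1e-8, 1 - 1e-8), tol = 1e-10
  )$root
}

rtgeom <- function(n, p, range) {
  sample(range[1]:range[2], n, replace = TRUE, prob = tgeom_probs(p, range))
}

#' Population parameters for the synthetic-data generator
#'
#' Bundles the design (observation, parent, plate counts), the parental-age
#' distributions, the fixed effects, the true parental-age slopes, and the
#' random-effect variances that together define a simulated population.
#' RTL is generated as
#' `rtl_mean + fixed effects + mac_slope * (MAC - mean MAC) +
#'  pac_slope * (PAC - mean PAC) + mother + father + plate + residual`,
#' with all random terms Gaussian.
#'
#' @param n_obs number of RTL observations.
#' @param n_animals number of distinct animals; `n_obs - n_animals` animals
#'   are measured in both sample years (repeated measures).
#' @param n_mothers,n_fathers,n_plates numbers of distinct mothers, fathers
#'   and qPCR plates.
#' @param mac_range,pac_range inclusive integer ranges (years) for maternal
#'   and paternal age at conception; ages are >= 1.
#' @param mac_sd,pac_sd target marginal standard deviations (years) of the
#'   truncated-geometric age distributions.
#' @param fixed_effects named numeric vector with elements `year`, `age`,
#'   `sex`, `age_sex`: coefficients for the second sample year, age in years,
#'   male sex, and the age-by-male interaction (RTL units).
#' @param mac_slope,pac_slope true linear parental-age effects on RTL
#'   (RTL units per year).
#' @param var_mother,var_father,var_plate,var_resid variances (RTL^2 units)
#'   of the mother, father and plate random intercepts and the residual.
#' @param rtl_mean grand mean RTL.
#' @param prop_female probability an animal is female.
#' @param prop_lamb probability an observation is of a four-month-old lamb.
#' @param lamb_age age (years) assigned to lambs.
#' @param adult_age_range inclusive integer range of adult ages at first
#'   capture.
#' @param adult_age_sd target SD of the adult age distribution.
#' @param same_plate_repeats logical; if `TRUE` a repeat measurement of an
#'   animal stays on its first plate, otherwise plates are drawn
#'   independently each year (whether the real repeats changed plates is
#'   unknown; this is the switch).
#' @param seed integer seed used by [sample_population()] unless overridden.
#'
#' @return an object of class `population_params` (a validated list).
#' @seealso [soay_structure()] for the study-matched default,
#'   [sample_population()] to draw a population.
#' @export
population_params <- function(n_obs = 389L,
                              n_animals = 318L,
                              n_mothers = 208L,
                              n_fathers = 138L,
                              n_plates = 9L,
                              mac_range = c(1L, 14L),
                              pac_range = c(1L, 10L),
                              mac_sd = 2.5,
                              pac_sd = 2.121,
                              fixed_effects = c(year = 0, age = 0, sex = 0, age_sex = 0),
                              mac_slope = 0,
                              pac_slope = 0,
                              var_mother = 0,
                              var_father = 0,
                              var_plate = 0,
                              var_resid = 0,
                              rtl_mean = 1,
                              prop_female = 274 / 389,
                              prop_lamb = 164 / 389,
                              lamb_age = 4 / 12,
                              adult_age_range = c(1L, 10L),
                              adult_age_sd = 2.2,
                              same_plate_repeats = FALSE,
                              seed = 1L) {
  counts <- c(
    n_obs = n_obs, n_animals = n_animals, n_mothers = n_mothers,
    n_fathers = n_fathers, n_plates = n_plates
  )
  if (any(counts < 1) || any(counts != round(counts))) {
    abort("counts (n_obs, n_animals, n_mothers, n_fathers, n_plates) must be positive integers")
  }
  if (n_animals > n_obs) abort("n_animals cannot exceed n_obs")
  if (n_obs - n_animals > n_animals) abort("at most one repeat measurement per animal is supported")
  vars <- c(
    var_mother = var_mother, var_father = var_father,
    var_plate = var_plate, var_resid = var_resid
  )
  if (any(!is.finite(vars)) || any(vars < 0)) abort("variances must be finite and >= 0")
  for (rg in list(mac_range, pac_range, adult_age_range)) {
    if (length(rg) != 2 || any(rg < 1) || rg[2] < rg[1] || any(rg != round(rg))) {
      abort("ranges must be inclusive integer ranges with min >= 1")
    }
  }
  need <- c("year", "age", "sex", "age_sex")
  if (!all(need %in% names(fixed_effects))) {
    abort("fixed_effects must name year, age, sex, age_sex")
  }
  if (prop_female <= 0 || prop_female >= 1) abort("prop_female must be in (0, 1)")

  params <- list(
    n_obs = as.integer(n_obs), n_animals = as.integer(n_animals),
    n_mothers = as.integer(n_mothers), n_fathers = as.integer(n_fathers),
    n_plates = as.integer(n_plates),
    mac_range = as.integer(mac_range), pac_range = as.integer(pac_range),
    mac_sd = mac_sd, pac_sd = pac_sd,
    mac_p = tgeom_shape_for_sd(mac_sd, mac_range),
    pac_p = tgeom_shape_for_sd(pac_sd, pac_range),
    fixed_effects = fixed_effects[need],
    mac_slope = mac_slope, pac_slope = pac_slope,
    var_mother = var_mother, var_father = var_father,
    var_plate = var_plate, var_resid = var_resid,
    rtl_mean = rtl_mean,
    prop_female = prop_female, prop_lamb = prop_lamb, lamb_age = lamb_age,
    adult_age_range = as.integer(adult_age_range),
    adult_age_p = tgeom_shape_for_sd(adult_age_sd, adult_age_range),
    same_plate_repeats = isTRUE(same_plate_repeats),
    seed = as.integer(seed)
  )
  structure(params, class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat("<population_params>\n")
  cat(sprintf(
    "  %d obs / %d animals; %d mothers, %d fathers, %d plates\n",
    x$n_obs, x$n_animals, x$n_mothers, x$n_fathers, x$n_plates
  ))
  cat(sprintf(
    "  MAC on [%d,%d] (SD %.3f), PAC on [%d,%d] (SD %.3f)\n",
    x$mac_range[1], x$mac_range[2], x$mac_sd,
    x$pac_range[1], x$pac_range[2], x$pac_sd
  ))
  cat(sprintf("  slopes: MAC %.4g, PAC %.4g; mean RTL %.3f\n", x$mac_slope, x$pac_slope, x$rtl_mean))
  cat(sprintf(
    "  variances: mother %.5f, father %.5f, plate %.5f, residual %.5f\n",
    x$var_mother, x$var_father, x$var_plate, x$var_resid
  ))
  invisible(x)
}

#' Study-matched population structure
#'
#' Default parameters mirroring the Soay sheep RTL dataset: 389 observations
#' of 318 animals from 208 mothers and 138 fathers run on 9 qPCR plates, PAC
#' marginal SD 2.121 years, total RTL SD 0.185. The total RTL variance
#' (0.185^2) is partitioned as mother 16%, father 2%, plate 5%, residual 77%:
#' the mother and father shares are the reported shares of explained random
#' variation, the plate and residual split is this package's default (the
#' absolute component sizes are not identifiable from the published
#' summaries and plate effects were small).
#'
#' @param ... overrides passed on to [population_params()].
#' @return a `population_params` object.
#' @examples
#' soay_structure()$n_obs # 389
#' @export
soay_structure <- function(...) {
  total_var <- 0.185^2
  defaults <- list(
    n_obs = 389L, n_animals = 318L, n_mothers = 208L, n_fathers = 138L,
    n_plates = 9L,
    var_mother = 0.16 * total_var,
    var_father = 0.02 * total_var,
    var_plate = 0.05 * total_var,
    var_resid = 0.77 * total_var,
    rtl_mean = 1
  )
  do.call(population_params, modifyList(defaults, list(...)))
}

#' Simulate a sheep population with RTL phenotypes
#'
#' Draws animals with sex, ages, pedigree links (mother and father
#' identities), independent integer maternal and paternal ages at conception,
#' plate assignments, and RTL values generated under the crossed
#' random-intercept model of [population_params()]. Animals beyond
#' `n_animals` observations are re-measured in the second sample year with
#' the same parents and parental ages, age advanced by one year, and a fresh
#' residual.
#'
#' @param params a [population_params()] object.
#' @param seed integer seed; defaults to `params$seed`. Identical
#'   params + seed give identical output.
#' @return a tibble with one row per RTL observation and columns
#'   `animal_id`, `sample_year` (factor, "2014"/"2015"), `age` (years),
#'   `sex` (factor, "F"/"M"), `mother_id`, `father_id`, `plate_id`,
#'   `mac`, `pac` (integer years), `rtl`.
#' @examples
#' pop <- sample_population(soay_structure(), seed = 42)
#' nrow(pop)
#' cor(pop$mac, pop$pac) # ~0: MAC and PAC are independent
#' @export
sample_population <- function(params, seed = params$seed) {
  if (!inherits(params, "population_params")) {
    abort("params must be created by population_params() or soay_structure()")
  }
  set.seed(seed)
  n_a <- params$n_animals
  n_rep <- params$n_obs - n_a

  animal <- tibble(
    animal_id = sprintf("A%04d", seq_len(n_a)),
    sex = factor(ifelse(runif(n_a) < params$prop_female, "F", "M"), levels = c("F", "M")),
    mother_id = sprintf("M%03d", sample.int(params$n_mothers, n_a, replace = TRUE)),
    father_id = sprintf("F%03d", sample.int(params$n_fathers, n_a, replace = TRUE)),
    mac = rtgeom(n_a, params$mac_p, params$mac_range),
    pac = rtgeom(n_a, params$pac_p, params$pac_range),
    is_lamb = runif(n_a) < params$prop_lamb
  )
  animal$age1 <- ifelse(
    animal$is_lamb, params$lamb_age,
    rtgeom(n_a, params$adult_age_p, params$adult_age_range)
  )
  # animals measured twice: one obs in each of the two years
  repeated <- sample.int(n_a, n_rep)
  animal$year1 <- factor(
    ifelse(seq_len(n_a) %in% repeated, "2014",
      ifelse(runif(n_a) < 0.5, "2014", "2015")
    ),
    levels = c("2014", "2015")
  )

  obs <- animal %>%
    select("animal_id", "sex", "mother_id", "father_id", "mac", "pac") %>%
    mutate(sample_year = animal$year1, age = animal$age1)
  if (n_rep > 0) {
    second <- obs[repeated, , drop = FALSE] %>%
      mutate(
        sample_year = factor("2015", levels = c("2014", "2015")),
        age = .data$age + 1
      )
    obs <- bind_rows(obs, second)
  }
  obs$plate_id <- sprintf("P%d", sample.int(params$n_plates, nrow(obs), replace = TRUE))
  if (params$same_plate_repeats && n_rep > 0) {
    first_plate <- obs$plate_id[seq_len(n_a)]
    idx2 <- n_a + seq_len(n_rep)
    obs$plate_id[idx2] <- first_plate[repeated]
  }

  b_mother <- setNames(
    rnorm(params$n_mothers, 0, sqrt(params$var_mother)),
    sprintf("M%03d", seq_len(params$n_mothers))
  )
  b_father <- setNames(
    rnorm(params$n_fathers, 0, sqrt(params$var_father)),
    sprintf("F%03d", seq_len(params$n_fathers))
  )
  b_plate <- setNames(
    rnorm(params$n_plates, 0, sqrt(params$var_plate)),
    sprintf("P%d", seq_len(params$n_plates))
  )

  fe <- params$fixed_effects
  male <- as.numeric(obs$sex == "M")
  obs$rtl <- params$rtl_mean +
    fe[["year"]] * as.numeric(obs$sample_year == "2015") +
    fe[["age"]] * obs$age +
    fe[["sex"]] * male +
    fe[["age_sex"]] * obs$age * male +
    params$mac_slope * (obs$mac - mean(obs$mac)) +
    params$pac_slope * (obs$pac - mean(obs$pac)) +
    unname(b_mother[obs$mother_id]) +
    unname(b_father[obs$father_id]) +
    unname(b_plate[obs$plate_id]) +
    rnorm(nrow(obs), 0, sqrt(params$var_resid))

  obs %>%
    arrange(.data$animal_id, .data$sample_year) %>%
    mutate(sample_id = sprintf("S%04d", row_number())) %>%
    select(
      "sample_id", "animal_id", "sample_year", "age", "sex",
      "mother_id", "father_id", "plate_id", "mac", "pac", "rtl"
    )
}
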
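test_that("degenerate noiseless population has constant RTL", {
  params <- population_params(
    n_obs = 50L, n_animals = 40L, n_mothers = 10L, n_fathers = 10L,
    n_plates = 2L, rtl_mean = 1
  )
  pop <- sample_population(params, seed = 1)
  expect_equal(nrow(pop), 50L)
  expect_equal(pop$rtl, rep(1, 50))
})

test_that("invalid parameters are rejected", {
  expect_error(population_params(n_obs = 0L), "positive integers")
  expect_error(population_params(var_mother = -0.1), "variances")
  expect_error(population_params(mac_range = c(0L, 10L)), "min >= 1")
  expect_error(population_params(n_obs = 10L, n_animals = 20L), "n_animals")
})

test_that("identical params and seed give identical populations", {
  params <- soay_structure()
  a <- sample_population(params, seed = 99)
  b <- sample_population(params, seed = 99)
  expect_identical(a, b)
  c <- sample_population(params, seed = 100)
  expect_false(identical(a$rtl, c$rtl))
})

test_that("study-matched structure carries the reported design", {
  s <- soay_structure()
  expect_equal(s$n_obs, 389L)
  expect_equal(s$n_animals, 318L)
  expect_equal(s$n_mothers, 208L)
  expect_equal(s$n_fathers, 138L)
  expect_equal(s$n_plates, 9L)
  expect_equal(s$pac_sd, 2.121)
  # total generated RTL variance sums to SD 0.185
  total <- s$var_mother + s$var_father + s$var_plate + s$var_resid
  expect_equal(sqrt(total), 0.185, tolerance = 1e-12)
})

test_that("MAC and PAC are independent and match target dispersions", {
  params <- soay_structure(n_obs = 5000L, n_animals = 5000L)
  pop <- sample_population(params, seed = 7)
  expect_lt(abs(cor(pop$mac, pop$pac)), 0.05)
  expect_equal(sd(pop$pac), 2.121, tolerance = 0.1 / 2.121)
  expect_true(all(pop$pac >= 1 & pop$pac <= 10))
  expect_true(all(pop$mac >= 1 & pop$mac <= 14))
  expect_true(all(pop$mac == round(pop$mac)))
  # independence holds across seeds at the 3/sqrt(n) level
  for (s in 1:3) {
    p2 <- sample_population(params, seed = s)
    expect_lt(abs(cor(p2$mac, p2$pac)), 3 / sqrt(nrow(p2)))
  }
})

test_that("repeat measurements share parents and parental ages", {
  pop <- sample_population(soay_structure(), seed = 5)
  expect_equal(nrow(pop), 389L)
  expect_equal(length(unique(pop$animal_id)), 318L)
  per_animal <- dplyr::summarise(
    dplyr::group_by(pop, animal_id),
    n = dplyr::n(),
    one_mother = dplyr::n_distinct(mother_id) == 1,
    one_father = dplyr::n_distinct(father_id) == 1,
    one_mac = dplyr::n_distinct(mac) == 1,
    one_pac = dplyr::n_distinct(pac) == 1,
    years = dplyr::n_distinct(sample_year)
  )
  expect_true(all(per_animal$n <= 2))
  expect_true(all(per_animal$one_mother & per_animal$one_father))
  expect_true(all(per_animal$one_mac & per_animal$one_pac))
  # an animal measured twice is measured once in each year
  expect_true(all(per_animal$years[per_animal$n == 2] == 2))
})

test_that("generated RTL dispersion matches the target total SD at large n", {
  params <- soay_structure(n_obs = 20000L, n_animals = 20000L,
    n_mothers = 4000L, n_fathers = 3000L, n_plates = 100L)
  pop <- sample_population(params, seed = 13)
  # 3 Monte-Carlo standard errors of an SD: sd/sqrt(2 n)
  mc3 <- 3 * 0.185 / sqrt(2 * nrow(pop))
  expect_equal(sd(pop$rtl), 0.185, tolerance = (mc3 + 0.003) / 0.185)
  expect_equal(mean(pop$rtl), 1, tolerance = 0.01)
  expect_true(all(pop$rtl > 0))
})

test_that("injected parental-age slopes shift RTL as specified", {
  params <- soay_structure(
    n_obs = 5000L, n_animals = 5000L, pac_slope = 0.05,
    var_mother = 0, var_father = 0, var_plate = 0, var_resid = 0
  )
  pop <- sample_population(params, seed = 3)
  # noiseless: rtl is exactly linear in centred pac
  fit <- lm(rtl ~ I(pac - mean(pac)), data = pop)
  expect_equal(unname(coef(fit)[2]), 0.05, tolerance = 1e-10)
  expect_equal(unname(coef(fit)[1]), 1, tolerance = 1e-10)
})
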
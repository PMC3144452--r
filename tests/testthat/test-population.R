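test_that("population_spec validates its fields", {
  expect_s3_class(population_spec(), "population_spec")
  expect_error(population_spec(strata_proportions = c(0.5, 0.3, 0.3)), "sum to 1")
  expect_error(population_spec(stratum_hr = c(1.2, 1.5, 3)), "reference")
  expect_error(population_spec(weibull_shape = -1), "> 0")
  expect_error(population_spec(smoking_prevalence = c(0.1, 1.2, 0.2)), "\\[0, 1\\]")
  expect_error(population_spec(population_size = 2), "at least the number of strata")
})

test_that("weibull_ph_time matches the inverse-transform closed form", {
  # -log(u) = 1 makes T equal the scale exactly
  expect_equal(weibull_ph_time(exp(-1), 0, shape = 1, scale = 40), 40)
  # closed-form evaluation at shape 2: 40 * sqrt(log 2)
  expect_equal(weibull_ph_time(0.5, 0, shape = 2, scale = 40),
               40 * sqrt(log(2)), tolerance = 1e-12)
  # hazard ratio 2 halves the time scale in the exponential case
  expect_equal(weibull_ph_time(0.5, log(2), shape = 1, scale = 40),
               weibull_ph_time(0.5, 0, shape = 1, scale = 40) / 2)
  expect_equal(weibull_ph_time(0.5, log(2), shape = 1, scale = 40),
               40 * log(2) / 2)
})

test_that("weibull_ph_time is monotone in eta and scale, and validates input", {
  u <- 0.37
  etas <- seq(-2, 2, by = 0.5)
  times <- weibull_ph_time(rep(u, length(etas)), etas, shape = 1.7, scale = 80)
  expect_true(all(diff(times) < 0))            # decreasing in eta
  scales <- seq(20, 120, by = 20)
  t2 <- vapply(scales, function(s) weibull_ph_time(u, 0.3, 2, s), numeric(1))
  expect_true(all(diff(t2) > 0))               # increasing in scale
  expect_true(all(times > 0))
  expect_error(weibull_ph_time(0, 0, 1, 1), "strictly in")
  expect_error(weibull_ph_time(1, 0, 1, 1), "strictly in")
  expect_error(weibull_ph_time(0.5, 0, -1, 1), "positive")
  expect_error(weibull_ph_time(0.5, 0, 1, 0), "positive")
})

test_that("largest-remainder allocation reproduces the study stratum counts", {
  counts <- allocate_counts(52750, c(prof = 0.505, tech = 0.28, admin = 0.215))
  expect_identical(unname(counts), c(26639L, 14770L, 11341L))
  expect_identical(sum(counts), 52750L)
  # always sums to the total across a grid of awkward cases
  for (tot in c(7, 100, 1234)) {
    p <- c(a = 1 / 3, b = 1 / 3, c = 1 / 3)
    expect_identical(sum(allocate_counts(tot, p)), as.integer(tot))
  }
})

test_that("generate_population has the specified structure and is deterministic", {
  spec <- population_spec()
  pop <- generate_population(spec, seed = 11)
  expect_identical(nrow(pop), 52750L)
  expect_identical(unname(table(pop$stratum)[spec$strata]),
                   table(factor(rep(spec$strata, c(26639, 14770, 11341)),
                                levels = spec$strata)) |> unname())
  # censoring invariants
  expect_equal(pop$time, pmin(pop$latent_time, 40))
  expect_identical(pop$event, as.integer(pop$latent_time <= 40))
  expect_true(all(pop$time > 0))
  # smoking prevalence within binomial Monte-Carlo error per stratum
  prev <- tapply(pop$smoker, pop$stratum, mean)
  for (h in spec$strata) {
    p0 <- spec$smoking_prevalence[[h]]
    nh <- sum(pop$stratum == h)
    expect_lt(abs(prev[[h]] - p0), 4 * sqrt(p0 * (1 - p0) / nh))
  }
  # determinism and seed sensitivity
  expect_identical(pop, generate_population(spec, seed = 11))
  expect_false(identical(pop$smoker, generate_population(spec, seed = 12)$smoker))
})

test_that("homogeneous population matches its Weibull survival law (KS)", {
  spec <- population_spec(
    population_size = 52750,
    smoking_prevalence = c(0, 0, 0),
    stratum_hr = c(1, 1, 1), smoking_hr = c(1, 1, 1),
    weibull_shape = 2, weibull_scale = 99, censor_horizon = 1e9
  )
  pop <- generate_population(spec, seed = 3)
  ks <- suppressWarnings(
    stats::ks.test(pop$time, function(q) 1 - exp(-(q / 99)^2))
  )
  expect_gt(ks$p.value, 0.01)
})

test_that("event fraction is monotone in inverse scale and in each log-HR", {
  base <- function(...) population_spec(population_size = 8000, ...)
  ev_frac <- function(spec) mean(generate_population(spec, seed = 5)$event)
  fr_scale <- vapply(c(160, 120, 90, 60), function(s)
    ev_frac(base(weibull_scale = s)), numeric(1))
  expect_true(all(diff(fr_scale) > 0))
  fr_str <- vapply(c(1, 2, 4), function(h)
    ev_frac(base(stratum_hr = c(1, 1.5, h))), numeric(1))
  expect_true(all(diff(fr_str) > 0))
  fr_smk <- vapply(c(1, 2.5, 6), function(h)
    ev_frac(base(smoking_hr = c(h, h, h))), numeric(1))
  expect_true(all(diff(fr_smk) > 0))
})

test_that("cohort tables round-trip through CSV", {
  pop <- generate_population(population_spec(population_size = 100), seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(pop, path)
  back <- read_cohort(path, strata = levels(pop$stratum))
  expect_equal(back$time, pop$time)
  expect_identical(back$event, pop$event)
  expect_identical(as.character(back$stratum), as.character(pop$stratum))
  expect_false("latent_time" %in% names(back))
  expect_error(read_cohort(withr::local_tempfile(lines = "a,b\n1,2")), "columns")
})
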
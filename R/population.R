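#' Specify the synthetic target population
#'
#' Bundles every parameter of the data-generating process: an occupational
#' cohort split into three strata, a binary smoking exposure whose prevalence
#' varies by stratum, and myocardial-infarction times drawn from a Weibull
#' proportional-hazards model with stratum main effects and stratum-specific
#' smoking effects, administratively censored at a fixed horizon.
#'
#' The default parameters describe a workforce of 52,750 people:
#' professionals (50.5%), technicians (28%) and administrative staff (21.5%);
#' smoking prevalence 15.9% / 20.9% / 25.3%; stratum hazard ratios 1 / 1.5 / 3
#' relative to professionals; within-stratum smoking hazard ratios
#' 1.5 / 2.0 / 3.0; administrative censoring at 40 years. The Weibull baseline
#' uses shape 2 (hazard increasing with age, plausible for MI) and a scale
#' calibrated so that about 15% of professional non-smokers experience the
#' event within the 40-year horizon: `scale = 40 / sqrt(-log(0.85))`.
#'
#' @param population_size Number of individuals, an integer >= number of strata.
#' @param strata Ordered character vector of three stratum labels; the first
#'   is the reference category.
#' @param strata_proportions Numeric fractions, one per stratum, each in
#'   (0, 1) and summing to 1 (tolerance 1e-12).
#' @param smoking_prevalence Smoking probability per stratum, each in \[0, 1\].
#' @param stratum_hr Hazard ratio of each stratum relative to the first
#'   (reference) stratum; the first element must be exactly 1.
#' @param smoking_hr Hazard ratio of smoking within each stratum.
#' @param weibull_shape Weibull shape parameter, dimensionless, > 0.
#' @param weibull_scale Weibull scale parameter in years, > 0.
#' @param censor_horizon Administrative censoring time in years, > 0.
#'
#' @return An object of class `population_spec`: a named list with the
#'   validated fields plus `stratum_log_hr` and `smoking_log_hr` (log scale).
#' @examples
#' spec <- population_spec()
#' spec$stratum_log_hr
#' @export
population_spec <- function(population_size = 52750,
                            strata = c("professionals", "technicians", "administrative"),
                            strata_proportions = c(0.505, 0.28, 0.215),
                            smoking_prevalence = c(0.159, 0.209, 0.253),
                            stratum_hr = c(1, 1.5, 3),
                            smoking_hr = c(1.5, 2, 3),
                            weibull_shape = 2,
                            weibull_scale = 40 / sqrt(-log(0.85)),
                            censor_horizon = 40) {
  if (!is.character(strata) || anyDuplicated(strata) > 0) {
    stop("`strata` must be a character vector of distinct labels.", call. = FALSE)
  }
  k <- length(strata)
  for (nm in c("strata_proportions", "smoking_prevalence", "stratum_hr", "smoking_hr")) {
    v <- get(nm)
    if (length(v) != k || !is.numeric(v)) {
      stop(sprintf("`%s` must be numeric of length %d (one per stratum).", nm, k),
           call. = FALSE)
    }
  }
  if (any(strata_proportions <= 0) || any(strata_proportions >= 1)) {
    stop("`strata_proportions` must each lie strictly in (0, 1).", call. = FALSE)
  }
  if (abs(sum(strata_proportions) - 1) > 1e-12) {
    stop("`strata_proportions` must sum to 1 (tolerance 1e-12).", call. = FALSE)
  }
  if (any(smoking_prevalence < 0) || any(smoking_prevalence > 1)) {
    stop("`smoking_prevalence` values must lie in [0, 1].", call. = FALSE)
  }
  if (stratum_hr[1] != 1) {
    stop("The first stratum is the reference: `stratum_hr[1]` must be exactly 1.",
         call. = FALSE)
  }
  if (any(stratum_hr <= 0) || any(smoking_hr <= 0)) {
    stop("Hazard ratios must be positive.", call. = FALSE)
  }
  if (!is.numeric(weibull_shape) || weibull_shape <= 0 ||
      !is.numeric(weibull_scale) || weibull_scale <= 0 ||
      !is.numeric(censor_horizon) || censor_horizon <= 0) {
    stop("`weibull_shape`, `weibull_scale` and `censor_horizon` must be > 0.",
         call. = FALSE)
  }
  population_size <- as.integer(population_size)
  if (is.na(population_size) || population_size < k) {
    stop("`population_size` must be at least the number of strata.", call. = FALSE)
  }
  structure(
    list(
      population_size = population_size,
      strata = strata,
      strata_proportions = stats::setNames(strata_proportions, strata),
      smoking_prevalence = stats::setNames(smoking_prevalence, strata),
      stratum_log_hr = stats::setNames(log(stratum_hr), strata),
      smoking_log_hr = stats::setNames(log(smoking_hr), strata),
      weibull_shape = weibull_shape,
      weibull_scale = weibull_scale,
      censor_horizon = censor_horizon
    ),
    class = "population_spec"
  )
}

#' @export
print.population_spec <- function(x, ...) {
  cat("<population_spec>\n")
  cat("  N =", x$population_size, "in", length(x$strata), "strata\n")
  df <- tibble::tibble(
    stratum = x$strata,
    proportion = unname(x$strata_proportions),
    smoking_prev = unname(x$smoking_prevalence),
    stratum_hr = exp(unname(x$stratum_log_hr)),
    smoking_hr = exp(unname(x$smoking_log_hr))
  )
  print(df)
  cat(sprintf("  Weibull(shape = %g, scale = %.3f yr); censoring at %g yr\n",
              x$weibull_shape, x$weibull_scale, x$censor_horizon))
  invisible(x)
}

#' Inverse-transform Weibull proportional-hazards event times
#'
#' Converts uniform deviates into event times under a Weibull baseline hazard
#' scaled by a proportional-hazards linear predictor:
#' `T = scale * (-log(u) / exp(eta))^(1/shape)`. With `eta = 0` this is a
#' plain Weibull(shape, scale) draw; raising `eta` accelerates events.
#'
#' @param u Uniform(0, 1) deviates, strictly inside the open interval.
#' @param eta Linear predictor on the log-hazard scale (recycled against `u`).
#' @param shape Weibull shape, > 0.
#' @param scale Weibull scale in years, > 0.
#' @return Event times in years, same length as `u`.
#' @examples
#' weibull_ph_time(exp(-1), eta = 0, shape = 1, scale = 40) # exactly 40
#' @export
weibull_ph_time <- function(u, eta = 0, shape, scale) {
  if (!is.numeric(u) || any(u <= 0) || any(u >= 1)) {
    stop("`u` must lie strictly in (0, 1).", call. = FALSE)
  }
  if (!is.numeric(shape) || length(shape) != 1 || shape <= 0 ||
      !is.numeric(scale) || length(scale) != 1 || scale <= 0) {
    stop("`shape` and `scale` must be positive scalars.", call. = FALSE)
  }
  scale * (-log(u) / exp(eta))^(1 / shape)
}

#' Largest-remainder apportionment of a total across groups
#'
#' Allocates an integer `total` across groups in proportion to `proportions`,
#' giving each group the floor of its exact share and distributing the
#' remaining units to the groups with the largest fractional remainders
#' (ties broken by group order). The result always sums to `total` exactly.
#'
#' @param total Integer total to allocate.
#' @param proportions Named numeric fractions summing to 1.
#' @return Named integer vector of counts summing to `total`.
#' @examples
#' allocate_counts(52750, c(prof = 0.505, tech = 0.28, admin = 0.215))
#' @export
allocate_counts <- function(total, proportions) {
  exact <- total * proportions
  counts <- floor(exact)
  short <- as.integer(round(total - sum(counts)))
  if (short > 0) {
    extra <- order(exact - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  stats::setNames(as.integer(counts), names(proportions))
}

#' Generate a synthetic occupational cohort
#'
#' Draws the full target population described by a [population_spec()]:
#' stratum membership by largest-remainder apportionment (deterministic given
#' the spec), smoking as independent Bernoulli draws within stratum, latent
#' event times from the Weibull proportional-hazards model via
#' [weibull_ph_time()], and administrative censoring at the horizon. The same
#' `(spec, seed)` pair always reproduces the identical table; the global RNG
#' state is left untouched.
#'
#' @param spec A [population_spec()].
#' @param seed Integer seed; required, no hidden global state.
#' @return A tibble with one row per individual and columns `id`, `stratum`
#'   (factor with the spec's level order), `smoker` (0/1), `latent_time`,
#'   `time` (observed, years) and `event` (1 = myocardial infarction
#'   observed before the horizon).
#' @examples
#' cohort <- generate_population(population_spec(population_size = 2000), seed = 1)
#' dplyr::count(cohort, stratum, event)
#' @export
generate_population <- function(spec, seed) {
  stopifnot(inherits(spec, "population_spec"))
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("An explicit integer `seed` is required.", call. = FALSE)
  }
  counts <- allocate_counts(spec$population_size, spec$strata_proportions)
  if (any(counts == 0)) {
    stop("Every stratum must receive at least one individual; increase ",
         "`population_size` or the stratum's proportion.", call. = FALSE)
  }
  stratum <- factor(rep(spec$strata, counts), levels = spec$strata)
  n <- spec$population_size

  withr::with_seed(as.integer(seed), {
    smoker <- stats::rbinom(n, 1, spec$smoking_prevalence[as.integer(stratum)])
    eta <- spec$stratum_log_hr[as.integer(stratum)] +
      smoker * spec$smoking_log_hr[as.integer(stratum)]
    u <- stats::runif(n)
    latent <- weibull_ph_time(u, eta, spec$weibull_shape, spec$weibull_scale)
  })

  tibble::tibble(
    id = seq_len(n),
    stratum = stratum,
    smoker = as.integer(smoker),
    latent_time = unname(latent),
    time = pmin(latent_time, spec$censor_horizon),
    event = as.integer(latent_time <= spec$censor_horizon)
  )
}

#' Read or write a cohort table as CSV
#'
#' The on-disk format is a comma-separated table with a header row, UTF-8
#' encoding and `.` as decimal separator; columns `id`, `stratum`, `smoker`,
#' `time`, `event` (the latent time is an internal simulation detail and is
#' not serialised). Sample tables add `weight` and `design_kind`.
#'
#' @param cohort A cohort or sample tibble.
#' @param path File path.
#' @param strata Optional character vector fixing the stratum factor levels
#'   on read; defaults to order of first appearance.
#' @return `write_cohort()` returns `cohort` invisibly; `read_cohort()`
#'   returns a tibble.
#' @export
write_cohort <- function(cohort, path) {
  keep <- intersect(c("id", "stratum", "smoker", "time", "event",
                      "weight", "design_kind"), names(cohort))
  readr::write_csv(cohort[keep], path)
  invisible(cohort)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, strata = NULL) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("id", "stratum", "smoker", "time", "event")
  if (!all(need %in% names(tab))) {
    stop("Cohort file must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lev <- if (is.null(strata)) unique(tab$stratum) else strata
  dplyr::mutate(
    tab,
    stratum = factor(.data$stratum, levels = lev),
    smoker = as.integer(.data$smoker),
    event = as.integer(.data$event)
  )
}
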
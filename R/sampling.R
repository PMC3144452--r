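#' Draw a simple random sample with design weights
#'
#' Samples `n` individuals from the cohort without replacement and attaches
#' the common design weight `N / n` (inverse selection probability). The draw
#' is reproducible from `seed` and leaves the global RNG state untouched.
#'
#' @param cohort A cohort tibble from [generate_population()] or
#'   [read_cohort()].
#' @param n Sample size, `1 <= n <= nrow(cohort)`.
#' @param seed Integer seed.
#' @return A tibble with the cohort's columns plus `weight` and
#'   `design_kind = "srs"`.
#' @examples
#' cohort <- generate_population(population_spec(population_size = 1000), seed = 1)
#' s <- draw_srs(cohort, 100, seed = 2)
#' sum(s$weight) # equals 1000
#' @export
draw_srs <- function(cohort, n, seed) {
  N <- nrow(cohort)
  n <- as.integer(n)
  if (is.na(n) || n < 1 || n > N) {
    stop("`n` must lie between 1 and the population size (", N, ").",
         call. = FALSE)
  }
  idx <- withr::with_seed(as.integer(seed), sample.int(N, n))
  dplyr::mutate(cohort[sort(idx), ], weight = N / n, design_kind = "srs")
}

#' Draw a stratified sample with non-proportional allocation
#'
#' Performs independent simple random sampling without replacement within each
#' stratum, taking `allocation[h]` individuals from stratum `h`, and attaches
#' the per-stratum design weight `N_h / n_h`. Weights are computed from the
#' realised stratum counts in `cohort`, so the Horvitz-Thompson identity
#' `sum(weight) == nrow(cohort)` holds exactly (to floating tolerance).
#'
#' @param cohort A cohort tibble.
#' @param allocation Named integer vector of per-stratum sample sizes; names
#'   must match the cohort's strata exactly and every `n_h` must satisfy
#'   `1 <= n_h <= N_h`.
#' @param seed Integer seed.
#' @return A tibble with the cohort's columns plus `weight` and
#'   `design_kind = "stratified"`.
#' @examples
#' cohort <- generate_population(population_spec(), seed = 1)
#' s <- draw_stratified(
#'   cohort,
#'   c(professionals = 3000, technicians = 4500, administrative = 7500),
#'   seed = 2
#' )
#' unique(s[, c("stratum", "weight")])
#' @export
draw_stratified <- function(cohort, allocation, seed) {
  strata <- levels(factor(cohort$stratum))
  if (is.null(names(allocation)) || !setequal(names(allocation), strata)) {
    stop("`allocation` must be named with exactly the cohort's strata: ",
         paste(strata, collapse = ", "), call. = FALSE)
  }
  allocation <- allocation[strata]
  Nh <- table(cohort$stratum)[strata]
  if (any(allocation < 1)) {
    stop("Every stratum allocation must be at least 1.", call. = FALSE)
  }
  if (any(allocation > Nh)) {
    bad <- strata[allocation > Nh]
    stop("Allocation exceeds the stratum population for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  rows_by_stratum <- split(seq_len(nrow(cohort)), cohort$stratum)[strata]
  idx <- withr::with_seed(as.integer(seed), {
    unlist(lapply(strata, function(h) {
      pool <- rows_by_stratum[[h]]
      pool[sample.int(length(pool), allocation[[h]])]
    }), use.names = FALSE)
  })
  wt <- as.numeric(Nh / allocation)
  out <- cohort[sort(idx), ]
  dplyr::mutate(
    out,
    weight = wt[match(as.character(.data$stratum), strata)],
    design_kind = "stratified"
  )
}

#' Describe a sampling design
#'
#' A small constructor used by scenario configuration: either a simple random
#' design of a given total size or a stratified design with a named
#' per-stratum allocation.
#'
#' @param kind `"srs"` or `"stratified"`.
#' @param n Total sample size (srs only).
#' @param allocation Named per-stratum sample sizes (stratified only).
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(kind = c("srs", "stratified"), n = NULL, allocation = NULL) {
  kind <- match.arg(kind)
  if (kind == "srs") {
    if (is.null(n) || n < 1) stop("srs design requires `n` >= 1.", call. = FALSE)
    allocation <- NULL
  } else {
    if (is.null(allocation) || is.null(names(allocation)) ||
        any(allocation < 1)) {
      stop("stratified design requires a named `allocation` with every n_h >= 1.",
           call. = FALSE)
    }
    n <- sum(allocation)
  }
  structure(list(kind = kind, n = as.integer(n), allocation = allocation),
            class = "design_spec")
}

#' Draw a sample according to a design specification
#'
#' Dispatches to [draw_srs()] or [draw_stratified()].
#'
#' @param cohort A cohort tibble.
#' @param design A [design_spec()].
#' @param seed Integer seed.
#' @return A sample tibble with `weight` and `design_kind`.
#' @export
draw_sample <- function(cohort, design, seed) {
  stopifnot(inherits(design, "design_spec"))
  switch(design$kind,
    srs = draw_srs(cohort, design$n, seed),
    stratified = draw_stratified(cohort, design$allocation, seed)
  )
}
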
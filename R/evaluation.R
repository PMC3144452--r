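#' Specify one Monte-Carlo scenario
#'
#' A scenario is one cell of the experimental grid: a sampling design, a
#' loss-to-follow-up mechanism, a model specification, whether design weights
#' enter the fit, and a replicate count.
#'
#' @param design A [design_spec()].
#' @param loss A [loss_spec()] (default: no loss).
#' @param model A [model_spec()] or model name.
#' @param weighted Logical; use design weights in the fit?
#' @param replicates Number of Monte-Carlo replicates, >= 1.
#' @param name Optional label; a descriptive default is built from the parts.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(design, loss = loss_spec("none"), model,
                          weighted = TRUE, replicates = 200, name = NULL) {
  stopifnot(inherits(design, "design_spec"), inherits(loss, "loss_spec"))
  if (is.character(model)) model <- model_spec(model)
  stopifnot(inherits(model, "model_spec"))
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1) {
    stop("`replicates` must be >= 1.", call. = FALSE)
  }
  if (is.null(name)) {
    name <- paste(design$kind, model$name,
                  if (weighted) "weighted" else "unweighted",
                  paste0("loss_", loss$mode), sep = "-")
  }
  structure(list(design = design, loss = loss, model = model,
                 weighted = isTRUE(weighted), replicates = replicates,
                 name = name),
            class = "scenario_spec")
}

# Deterministic sub-seed rule: replicate r of a run rooted at `seed` draws
# its sample with seed + r and its loss indicators with seed + 1e6 + r.
replicate_seeds <- function(seed, r) {
  list(sample = as.integer(seed + r), loss = as.integer(seed + 1e6 + r))
}

#' Run the Monte-Carlo replication experiment for one scenario
#'
#' For each replicate: draw a sample from the population under the scenario's
#' design, impose loss to follow-up, and fit the scenario's Cox model
#' (weighted or unweighted). Per-replicate seeds are derived deterministically
#' from `seed` (sampling seed `seed + r`, loss seed `seed + 1e6 + r`), so any
#' single replicate can be reproduced in isolation and results do not depend
#' on execution order. Replicates whose fit fails to converge are dropped
#' from the output and counted; more than 5% non-convergence aborts the run,
#' since it signals a mis-specified scenario rather than bad luck.
#'
#' @param population The full cohort tibble.
#' @param scenario A [scenario_spec()].
#' @param seed Integer root seed.
#' @return A tibble with one row per converged replicate and columns
#'   `replicate`, `term`, `estimate` (log-HR), `hr`, `se`, `robust_se`,
#'   `est_var` (the per-replicate estimated variance used for averaging:
#'   robust for weighted fits, model-based for unweighted fits). The number
#'   of dropped replicates is attached as attribute `n_nonconverged`.
#' @examples
#' cohort <- generate_population(population_spec(population_size = 3000), seed = 1)
#' sc <- scenario_spec(design_spec("srs", n = 800), model = "smoke_only",
#'                     replicates = 5)
#' run_replications(cohort, sc, seed = 42)
#' @export
run_replications <- function(population, scenario, seed) {
  stopifnot(inherits(scenario, "scenario_spec"))
  R <- scenario$replicates
  rows <- vector("list", R)
  failed <- 0L
  for (r in seq_len(R)) {
    seeds <- replicate_seeds(seed, r)
    samp <- draw_sample(population, scenario$design, seeds$sample)
    samp <- apply_loss(samp, scenario$loss, seeds$loss)
    fit <- tryCatch(
      fit_cox(samp, scenario$model, weighted = scenario$weighted),
      error = function(e) NULL   # non-convergence, separation, deficient rank
    )
    if (is.null(fit)) {
      failed <- failed + 1L
      next
    }
    td <- tidy(fit)
    rows[[r]] <- dplyr::mutate(
      td[, c("term", "estimate", "hr", "se", "robust_se")],
      replicate = r,
      est_var = (if (scenario$weighted) .data$robust_se else .data$se)^2
    )
  }
  if (failed > 0.05 * R) {
    stop(failed, " of ", R, " replicates failed to converge (> 5%); ",
         "the scenario is likely mis-specified.", call. = FALSE)
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::relocate(out, "replicate")
  attr(out, "n_nonconverged") <- failed
  out
}

#' Summarise replicate estimates against a census reference
#'
#' Computes, per coefficient: the mean hazard ratio and mean log-HR across
#' replicates, the bias of the mean log-HR relative to the census reference
#' fit of the same model, the empirical variance of the log-HR estimates
#' (divisor R - 1), the average of the per-replicate estimated variances, the
#' mean squared error `MSE = variance + bias^2` (an exact identity as
#' computed), the Monte-Carlo standard error of the mean, and the central 95%
#' range of replicate estimates together with a flag raised when the
#' reference value falls outside it — the signature of an estimator whose
#' sampling distribution excludes the truth.
#'
#' @param estimates Replicate tibble from [run_replications()] (>= 2
#'   replicates).
#' @param reference An `svycox_fit` from [population_reference_fit()] for the
#'   same model specification.
#' @return A tibble with one row per coefficient: `term`, `mean_hr`,
#'   `mean_loghr`, `ref_loghr`, `bias`, `emp_var`, `avg_est_var`, `mse`,
#'   `mc_se`, `q025`, `q975` (log-HR scale), `excludes_ref`, `n_replicates`.
#' @export
summarize_replicates <- function(estimates, reference) {
  stopifnot(inherits(reference, "svycox_fit"))
  if (length(unique(estimates$replicate)) < 2) {
    stop("At least 2 replicates are required.", call. = FALSE)
  }
  ref <- coef(reference)
  terms <- unique(estimates$term)
  if (!setequal(terms, names(ref))) {
    stop("Coefficient names in `estimates` do not match the reference fit: ",
         paste(terms, collapse = ", "), " vs ",
         paste(names(ref), collapse = ", "), call. = FALSE)
  }
  ref_tab <- tibble::tibble(term = names(ref), ref_loghr = unname(ref))
  estimates |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      mean_hr = mean(.data$hr),
      mean_loghr = mean(.data$estimate),
      emp_var = stats::var(.data$estimate),
      avg_est_var = mean(.data$est_var),
      q025 = stats::quantile(.data$estimate, 0.025, names = FALSE),
      q975 = stats::quantile(.data$estimate, 0.975, names = FALSE),
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::left_join(ref_tab, by = "term") |>
    dplyr::mutate(
      bias = .data$mean_loghr - .data$ref_loghr,
      mse = .data$emp_var + .data$bias^2,
      mc_se = sqrt(.data$emp_var / .data$n_replicates),
      excludes_ref = .data$ref_loghr < .data$q025 | .data$ref_loghr > .data$q975
    ) |>
    dplyr::select("term", "mean_hr", "mean_loghr", "ref_loghr", "bias",
                  "emp_var", "avg_est_var", "mse", "mc_se", "q025", "q975",
                  "excludes_ref", "n_replicates")
}

#' Gaussian kernel density of replicate hazard-ratio estimates
#'
#' Presents the sampling distribution of estimates as a Gaussian kernel
#' density, the display used throughout the replication study. The default
#' bandwidth is Silverman's rule of thumb
#' (`0.9 * min(sd, IQR/1.34) * n^(-1/5)`, [stats::bw.nrd0()]).
#'
#' @param estimates Numeric vector of (hazard-ratio) estimates, length >= 2,
#'   with positive spread.
#' @param bandwidth Optional kernel bandwidth; defaults to Silverman's rule.
#' @param n_grid Number of abscissae (default 512).
#' @return A tibble with columns `x` (abscissae) and `density`; the curve is
#'   nonnegative and integrates to 1 (within 1e-3 by trapezoidal quadrature).
#' @examples
#' hr_density(c(0, 1), bandwidth = 1) |> head()
#' @export
hr_density <- function(estimates, bandwidth = NULL, n_grid = 512) {
  if (length(estimates) < 2) {
    stop("At least 2 estimates are required.", call. = FALSE)
  }
  if (stats::var(estimates) == 0) {
    stop("Estimates have zero variance; report the point mass at ",
         estimates[1], " directly instead of a density.", call. = FALSE)
  }
  # cut = 4 bandwidths beyond the data range keeps the truncated tail mass
  # below ~1e-4 so the emitted curve integrates to 1 within 1e-3
  d <- if (is.null(bandwidth)) {
    stats::density(estimates, kernel = "gaussian", n = n_grid, cut = 4)
  } else {
    stats::density(estimates, bw = bandwidth, kernel = "gaussian",
                   n = n_grid, cut = 4)
  }
  tibble::tibble(x = d$x, density = d$y)
}

#' Compare scenario summaries
#'
#' Collates per-scenario summaries into a comparison report: per coefficient,
#' scenarios are ranked by mean squared error, and every scenario whose
#' census reference value lies outside the central 95% of its replicate
#' estimates is flagged.
#'
#' @param summaries A named list of summary tibbles from
#'   [summarize_replicates()] (names label the scenarios), or a single
#'   tibble carrying a `scenario` column.
#' @return A tibble with columns `scenario`, `term`, `bias`, `emp_var`,
#'   `avg_est_var`, `mse`, `mse_rank` (1 = smallest MSE within the term),
#'   `excludes_ref`.
#' @export
compare_scenarios <- function(summaries) {
  if (is.data.frame(summaries)) {
    if (!"scenario" %in% names(summaries)) {
      stop("A single tibble input must carry a `scenario` column.", call. = FALSE)
    }
    tab <- summaries
  } else {
    if (length(summaries) == 0) stop("No summaries supplied.", call. = FALSE)
    if (is.null(names(summaries)) || any(names(summaries) == "")) {
      stop("`summaries` must be a named list.", call. = FALSE)
    }
    tab <- dplyr::bind_rows(summaries, .id = "scenario")
  }
  shared <- tab |>
    dplyr::count(.data$term) |>
    dplyr::filter(.data$n >= 2)
  if (nrow(shared) == 0) {
    stop("At least two scenarios must share a coefficient.", call. = FALSE)
  }
  tab |>
    dplyr::group_by(.data$term) |>
    dplyr::mutate(mse_rank = rank(.data$mse, ties.method = "first")) |>
    dplyr::ungroup() |>
    dplyr::select("scenario", "term", "bias", "emp_var", "avg_est_var",
                  "mse", "mse_rank", "excludes_ref") |>
    dplyr::arrange(.data$term, .data$mse_rank)
}
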
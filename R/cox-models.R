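#' The three Cox model specifications
#'
#' Three nested specifications of the proportional-hazards model for the
#' simulated cohort, mirroring how an analyst might (mis)specify the model:
#'
#' * `"full"` — the data-generating structure: indicator columns for the two
#'   non-reference strata plus three stratum-by-smoking interaction columns
#'   (one smoking effect per stratum; no common smoking main effect).
#'   5 coefficients.
#' * `"marginal"` — strata as main effects plus a single common smoking
#'   effect; ignores the effect heterogeneity across strata. 3 coefficients.
#' * `"smoke_only"` — smoking alone, ignoring the design factor entirely.
#'   1 coefficient.
#'
#' The first stratum (professionals) is always the reference: a professional
#' non-smoker maps to an all-zero covariate row in every model.
#'
#' @param name `"full"`, `"marginal"` or `"smoke_only"`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(name = c("full", "marginal", "smoke_only")) {
  name <- match.arg(name)
  structure(list(name = name), class = "model_spec")
}

#' Build the covariate matrix and response vectors for a model specification
#'
#' Encodes a sample tibble into the fixed-order covariate matrix of one of
#' the three model specifications, together with the observed time, event
#' indicator and design weight vectors used by [fit_weighted_cox()].
#'
#' Column order is fixed: `full` gives
#' `(tech, admin, prof_smoking, tech_smoking, admin_smoking)`, `marginal`
#' gives `(tech, admin, smoking)`, `smoke_only` gives `(smoking)`, where
#' `tech`/`admin` are indicators of the second and third stratum and the
#' `*_smoking` columns are stratum-by-smoking products.
#'
#' @param sample_tab A non-empty cohort or sample tibble; if it has no
#'   `weight` column, unit weights are attached.
#' @param model A [model_spec()] or a model name string.
#' @return A list with `X` (numeric matrix), `time`, `event`, `weights`.
#' @examples
#' cohort <- generate_population(population_spec(population_size = 500), seed = 1)
#' d <- build_design_matrix(cohort, "marginal")
#' colnames(d$X)
#' @export
build_design_matrix <- function(sample_tab, model) {
  if (is.character(model)) model <- model_spec(model)
  stopifnot(inherits(model, "model_spec"))
  if (nrow(sample_tab) == 0) stop("`sample_tab` is empty.", call. = FALSE)
  strata <- levels(factor(sample_tab$stratum))
  if (length(strata) != 3) {
    stop("The model specifications expect exactly three strata; got ",
         length(strata), ".", call. = FALSE)
  }
  g <- as.integer(factor(sample_tab$stratum, levels = strata))
  smk <- as.numeric(sample_tab$smoker)
  tech <- as.numeric(g == 2L)
  admin <- as.numeric(g == 3L)
  prof <- as.numeric(g == 1L)
  X <- switch(model$name,
    full = cbind(
      tech = tech, admin = admin,
      prof_smoking = prof * smk,
      tech_smoking = tech * smk,
      admin_smoking = admin * smk
    ),
    marginal = cbind(tech = tech, admin = admin, smoking = smk),
    smoke_only = cbind(smoking = smk)
  )
  w <- if ("weight" %in% names(sample_tab)) sample_tab$weight else rep(1, nrow(sample_tab))
  list(X = X, time = as.numeric(sample_tab$time),
       event = as.integer(sample_tab$event), weights = as.numeric(w))
}

#' Generating log hazard ratios for a model's coefficients
#'
#' For the `full` model the generating values are known exactly from the
#' population specification; for the other models no generating value exists
#' (they are misspecified) and `NA` is returned.
#'
#' @param spec A [population_spec()].
#' @param model A [model_spec()] or name.
#' @return Named numeric vector of generating log-HRs (NA where undefined).
#' @export
generating_loghr <- function(spec, model) {
  if (is.character(model)) model <- model_spec(model)
  switch(model$name,
    full = c(
      tech = unname(spec$stratum_log_hr[2]),
      admin = unname(spec$stratum_log_hr[3]),
      prof_smoking = unname(spec$smoking_log_hr[1]),
      tech_smoking = unname(spec$smoking_log_hr[2]),
      admin_smoking = unname(spec$smoking_log_hr[3])
    ),
    marginal = c(tech = NA_real_, admin = NA_real_, smoking = NA_real_),
    smoke_only = c(smoking = NA_real_)
  )
}
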
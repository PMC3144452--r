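#' Specify a loss-to-follow-up scenario
#'
#' Three modes are supported: `"none"` (no attrition), `"random"` (every
#' individual who experienced the event is lost with a common probability,
#' a non-informative mechanism) and `"differential"` (the loss probability
#' depends on the sampling stratum, an informative mechanism because the
#' strata carry different hazards). Rates are interpreted as applying to
#' event-individuals: loss converts an observed event into a censored
#' observation.
#'
#' @param mode `"none"`, `"random"` or `"differential"`.
#' @param rate Loss probability in \[0, 1\] (random mode).
#' @param rates_by_stratum Named loss probabilities, one per stratum
#'   (differential mode).
#' @return An object of class `loss_spec`.
#' @examples
#' loss_spec("random", rate = 0.15)
#' loss_spec("differential", rates_by_stratum = c(
#'   professionals = 0.08, technicians = 0.12, administrative = 0.20
#' ))
#' @export
loss_spec <- function(mode = c("none", "random", "differential"),
                      rate = NULL, rates_by_stratum = NULL) {
  mode <- match.arg(mode)
  if (mode == "random") {
    if (is.null(rate) || !is.numeric(rate) || rate < 0 || rate > 1) {
      stop("random loss requires `rate` in [0, 1].", call. = FALSE)
    }
    rates_by_stratum <- NULL
  } else if (mode == "differential") {
    if (is.null(rates_by_stratum) || is.null(names(rates_by_stratum)) ||
        any(rates_by_stratum < 0) || any(rates_by_stratum > 1)) {
      stop("differential loss requires named `rates_by_stratum` in [0, 1].",
           call. = FALSE)
    }
    rate <- NULL
  } else {
    rate <- NULL
    rates_by_stratum <- NULL
  }
  structure(list(mode = mode, rate = rate, rates_by_stratum = rates_by_stratum),
            class = "loss_spec")
}

#' Impose loss to follow-up on a drawn sample
#'
#' Only records with an observed event are eligible; each is independently
#' selected for loss with its applicable rate. Under the default mechanism a
#' lost record keeps its observed time but has its event indicator flipped to
#' censored, mimicking a participant who drops out and whose event is never
#' recorded. Record count, weights, strata and observed times are never
#' modified, and already-censored records are untouched.
#'
#' An alternative `"uniform_dropout"` mechanism instead replaces the lost
#' record's follow-up time with a uniform draw on (0, time): the participant
#' leaves at a random point before the event. It is provided for sensitivity
#' analysis and is not the default.
#'
#' @param sample_tab A sample tibble with `event` set (and `stratum` for
#'   differential loss).
#' @param loss A [loss_spec()].
#' @param seed Integer seed.
#' @param mechanism `"censor_at_event"` (default) or `"uniform_dropout"`.
#' @return The sample tibble with loss applied.
#' @examples
#' cohort <- generate_population(population_spec(population_size = 1000), seed = 1)
#' s <- draw_srs(cohort, 500, seed = 2)
#' lost <- apply_loss(s, loss_spec("random", rate = 0.15), seed = 3)
#' c(before = sum(s$event), after = sum(lost$event))
#' @export
apply_loss <- function(sample_tab, loss, seed,
                       mechanism = c("censor_at_event", "uniform_dropout")) {
  stopifnot(inherits(loss, "loss_spec"))
  mechanism <- match.arg(mechanism)
  if (loss$mode == "none") {
    return(sample_tab)
  }
  eligible <- which(sample_tab$event == 1L)
  if (loss$mode == "random") {
    p <- rep(loss$rate, length(eligible))
  } else {
    strata <- as.character(unique(sample_tab$stratum))
    missing_rates <- setdiff(strata, names(loss$rates_by_stratum))
    if (length(missing_rates) > 0) {
      stop("`rates_by_stratum` lacks strata: ",
           paste(missing_rates, collapse = ", "), call. = FALSE)
    }
    p <- loss$rates_by_stratum[as.character(sample_tab$stratum[eligible])]
  }
  withr::with_seed(as.integer(seed), {
    lost <- eligible[stats::runif(length(eligible)) < p]
    if (mechanism == "uniform_dropout" && length(lost) > 0) {
      dropout_time <- stats::runif(length(lost)) * sample_tab$time[lost]
    }
  })
  sample_tab$event[lost] <- 0L
  if (mechanism == "uniform_dropout" && length(lost) > 0) {
    sample_tab$time[lost] <- dropout_time
  }
  sample_tab
}
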
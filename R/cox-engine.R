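#' @keywords internal
#' Reverse cumulative sum down each column (risk-set accumulation).
rev_cumsum_mat <- function(m) {
  n <- nrow(m)
  apply(m[n:1, , drop = FALSE], 2, cumsum)[n:1, , drop = FALSE]
}

# Weighted partial-likelihood quantities at a given beta, on data already
# sorted by increasing time. Risk sets follow the Breslow convention: the
# set at an event time t is {j : t_j >= t}, shared by tied times.
cox_quantities <- function(Xs, ts, ds, ws, fi, beta, XX) {
  p <- ncol(Xs)
  eta <- drop(Xs %*% beta)
  r <- ws * exp(eta)
  S0 <- rev(cumsum(rev(r)))[fi]
  S1 <- rev_cumsum_mat(r * Xs)[fi, , drop = FALSE]
  ev <- which(ds == 1L)
  xbar <- S1[ev, , drop = FALSE] / S0[ev]
  we <- ws[ev]
  loglik <- sum(we * (eta[ev] - log(S0[ev])))
  U <- colSums(we * (Xs[ev, , drop = FALSE] - xbar))
  S2 <- rev_cumsum_mat(r * XX)[fi, , drop = FALSE]
  xbar2 <- xbar[, rep(seq_len(p), times = p), drop = FALSE] *
    xbar[, rep(seq_len(p), each = p), drop = FALSE]
  info <- matrix(colSums(we * (S2[ev, , drop = FALSE] / S0[ev] - xbar2)), p, p)
  list(loglik = loglik, U = U, info = info, eta = eta, S0 = S0, S1 = S1)
}

#' Fit a Cox model by weighted partial likelihood
#'
#' Solves the design-weighted Cox score equation
#' \deqn{U(\beta) = \sum_i w_i \delta_i \left\{ x_i -
#'   S^{(1)}(t_i;\beta)/S^{(0)}(t_i;\beta) \right\} = 0,}
#' with \eqn{S^{(r)}(t;\beta) = \sum_{j: t_j \ge t} w_j e^{x_j'\beta}
#' x_j^{\otimes r}}, by Newton-Raphson with step-halving, using the Breslow
#' convention for tied times. Design weights enter the estimating function as
#' inverse selection probabilities, so the estimate targets the population
#' parameter under an informative sampling design. Setting all weights to a
#' common constant reproduces the classical unweighted partial-likelihood
#' estimate, and rescaling all weights by any positive constant changes
#' neither the estimate nor the robust variance.
#'
#' Two variance estimates accompany the fit: the model-based inverse
#' information, and the design-based sandwich
#' \eqn{I^{-1} M I^{-1}} with \eqn{M = \sum_i (w_i u_i)(w_i u_i)'} the sum of
#' outer products of per-individual weighted score residuals, appropriate
#' under weighting and model misspecification.
#'
#' @param X Numeric covariate matrix (rows = subjects); a numeric vector is
#'   treated as a single-column matrix.
#' @param time Observed times, positive.
#' @param event Event indicators (1 = event, 0 = censored); at least one
#'   event is required.
#' @param weights Positive design weights; defaults to unit weights.
#' @param init Starting value for the coefficient vector (default zeros).
#' @param tol Convergence tolerance on the relative change in the log partial
#'   likelihood (default 1e-11, comfortably below reporting precision).
#' @param max_iter Maximum Newton steps (default 50).
#' @return An object of class `svycox_fit`; see [tidy.svycox_fit()].
#' @examples
#' fit <- fit_weighted_cox(
#'   X = c(1, 0, 1), time = c(1, 2, 3), event = c(1, 1, 0)
#' )
#' coef(fit) # -log(2)/2
#' @export
fit_weighted_cox <- function(X, time, event, weights = NULL, init = NULL,
                             tol = 1e-11, max_iter = 50L) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1, dimnames = list(NULL, "x"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  p <- ncol(X)
  event <- as.integer(event)
  if (length(time) != n || length(event) != n) {
    stop("`time` and `event` must match the rows of `X`.", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights <= 0) || anyNA(weights)) {
    stop("`weights` must be positive and non-missing.", call. = FALSE)
  }
  if (anyNA(X) || anyNA(time)) stop("Missing values are not supported.", call. = FALSE)
  if (sum(event) == 0) stop("At least one event is required.", call. = FALSE)

  ord <- order(time)
  Xs <- X[ord, , drop = FALSE]
  ts <- time[ord]
  ds <- event[ord]
  ws <- weights[ord]
  fi <- match(ts, ts)            # first index of each tie group (risk-set key)

  qr_rank <- qr(Xs * sqrt(ws))$rank
  if (qr_rank < p) {
    stop("Covariate matrix is rank-deficient; check columns: ",
         paste(colnames(X), collapse = ", "), call. = FALSE)
  }

  beta <- if (is.null(init)) rep(0, p) else as.numeric(init)
  XX <- Xs[, rep(seq_len(p), times = p), drop = FALSE] *
    Xs[, rep(seq_len(p), each = p), drop = FALSE]
  q <- cox_quantities(Xs, ts, ds, ws, fi, beta, XX)
  trace <- q$loglik
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(q$info, q$U), error = function(e) {
      stop("Singular information matrix at iteration ", iter,
           "; columns: ", paste(colnames(X), collapse = ", "), call. = FALSE)
    })
    halves <- 0L
    repeat {
      beta_new <- beta + step
      q_new <- tryCatch(cox_quantities(Xs, ts, ds, ws, fi, beta_new, XX),
                        error = function(e) NULL)
      ok <- !is.null(q_new) && is.finite(q_new$loglik)
      if (ok && q_new$loglik >= q$loglik - 1e-12 * abs(q$loglik)) break
      halves <- halves + 1L
      if (halves > 30L) break
      step <- step / 2
    }
    if (is.null(q_new) || !is.finite(q_new$loglik)) {
      cond <- structure(
        class = c("svycoxsim_convergence_error", "error", "condition"),
        list(message = paste0(
          "Step-halving failed to find an uphill step at iteration ", iter,
          ". Log-likelihood trace: ",
          paste(signif(trace, 8), collapse = " -> ")),
          call = NULL, trace = trace)
      )
      stop(cond)
    }
    if (max(abs(beta_new)) > 25) {
      cond <- structure(
        class = c("svycoxsim_convergence_error", "error", "condition"),
        list(message = paste0(
          "Coefficients diverging (|beta| > 25): likely monotone partial ",
          "likelihood / perfect separation. Log-likelihood trace: ",
          paste(signif(c(trace, q_new$loglik), 8), collapse = " -> ")),
          call = NULL, trace = c(trace, q_new$loglik))
      )
      stop(cond)
    }
    delta_ll <- abs(q_new$loglik - q$loglik)
    beta <- beta_new
    q <- q_new
    trace <- c(trace, q$loglik)
    if (delta_ll < tol * (abs(q$loglik) + tol)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    cond <- structure(
      class = c("svycoxsim_convergence_error", "error", "condition"),
      list(message = paste0(
        "Newton-Raphson failed to converge in ", max_iter,
        " iterations. Log-likelihood trace: ",
        paste(signif(trace, 8), collapse = " -> ")),
        call = NULL, trace = trace)
    )
    stop(cond)
  }

  info_inv <- solve(q$info)
  robust <- cox_sandwich(Xs, ts, ds, ws, fi, beta, q, info_inv)
  cn <- colnames(X)
  dimnames(info_inv) <- dimnames(robust) <- list(cn, cn)
  structure(
    list(
      coefficients = stats::setNames(beta, cn),
      var = info_inv,
      robust_var = robust,
      loglik = q$loglik,
      score = q$U,
      iter = iter,
      converged = TRUE,
      trace = trace,
      n = n,
      n_events = sum(ds)
    ),
    class = "svycox_fit"
  )
}

# Design-based (sandwich) covariance I^{-1} M I^{-1}. Per-subject score
# residuals u_i = d_i (x_i - xbar(t_i)) -
#   e^{eta_i} sum_{events k: t_k <= t_i} (w_k / S0(t_k)) (x_i - xbar(t_k)),
# accumulated with forward cumulative sums; M = sum_i (w_i u_i)(w_i u_i)'.
cox_sandwich <- function(Xs, ts, ds, ws, fi, beta, q, info_inv) {
  n <- nrow(Xs)
  p <- ncol(Xs)
  li <- findInterval(ts, ts)     # last index of each tie group
  xbar_all <- q$S1 / q$S0        # n x p, row i = risk-set mean at t_i
  ev_h <- ifelse(ds == 1L, ws / q$S0, 0)
  G0 <- cumsum(ev_h)[li]
  G1 <- apply(ev_h * xbar_all, 2, cumsum)[li, , drop = FALSE]
  expeta <- exp(q$eta)
  u <- ds * (Xs - xbar_all) - expeta * (Xs * G0 - G1)
  M <- crossprod(ws * u)
  info_inv %*% M %*% info_inv
}

#' Fit one of the three model specifications to a sample
#'
#' Data-frame-first wrapper around [build_design_matrix()] and
#' [fit_weighted_cox()]. With `weighted = TRUE` the sample's design weights
#' are used; with `weighted = FALSE` all weights are set to 1, which is the
#' conventional analysis that ignores the sampling design.
#'
#' @param sample_tab A cohort or sample tibble.
#' @param model A [model_spec()] or model name.
#' @param weighted Use the `weight` column as design weights? Default `TRUE`
#'   (a table without a weight column gets unit weights either way).
#' @param ... Passed to [fit_weighted_cox()].
#' @return An `svycox_fit`.
#' @examples
#' cohort <- generate_population(population_spec(population_size = 2000), seed = 1)
#' fit_cox(cohort, "marginal") |> tidy()
#' @export
fit_cox <- function(sample_tab, model, weighted = TRUE, ...) {
  d <- build_design_matrix(sample_tab, model)
  w <- if (weighted) d$weights else rep(1, length(d$weights))
  fit <- fit_weighted_cox(d$X, d$time, d$event, w, ...)
  fit$model <- if (is.character(model)) model else model$name
  fit
}

#' Census reference fit of a model specification
#'
#' Fits a model to the entire generated population with unit weights. The
#' resulting hazard ratios are the finite-population reference ("true")
#' values against which sample-based estimates are judged — exact generating
#' values for the full model, and the population-level projections for the
#' misspecified marginal and smoke-only models.
#'
#' @param cohort The full cohort tibble.
#' @param model A [model_spec()] or model name.
#' @param ... Passed to [fit_weighted_cox()].
#' @return An `svycox_fit`.
#' @export
population_reference_fit <- function(cohort, model, ...) {
  d <- build_design_matrix(cohort, model)
  if (sum(d$event) < 1) stop("Cohort contains no events.", call. = FALSE)
  fit <- fit_weighted_cox(d$X, d$time, d$event, rep(1, nrow(cohort)), ...)
  fit$model <- if (is.character(model)) model else model$name
  fit
}

#' @export
coef.svycox_fit <- function(object, ...) object$coefficients

#' @export
vcov.svycox_fit <- function(object, robust = FALSE, ...) {
  if (robust) object$robust_var else object$var
}

#' @export
print.svycox_fit <- function(x, ...) {
  cat("<svycox_fit>", if (!is.null(x$model)) paste0("model = ", x$model),
      sprintf("n = %d, events = %d, loglik = %.4f (%d iterations)\n",
              x$n, x$n_events, x$loglik, x$iter))
  print(tidy(x))
  invisible(x)
}

#' Tidy a weighted Cox fit
#'
#' @param x An `svycox_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`
#'   (log hazard ratio), `hr` (`exp(estimate)`, exactly), `se` (model-based,
#'   inverse information), `robust_se` (design-based sandwich), `statistic`
#'   (robust Wald z) and `p.value`.
#' @export
tidy.svycox_fit <- function(x, ...) {
  est <- x$coefficients
  se <- sqrt(diag(x$var))
  rse <- sqrt(diag(x$robust_var))
  z <- est / rse
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    hr = exp(unname(est)),
    se = unname(se),
    robust_se = unname(rse),
    statistic = unname(z),
    p.value = 2 * stats::pnorm(-abs(unname(z)))
  )
}

#' Glance at a weighted Cox fit
#'
#' @param x An `svycox_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `n_events`, `loglik`, `iter`, `converged`.
#' @export
glance.svycox_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_events = x$n_events, loglik = x$loglik,
    iter = x$iter, converged = x$converged
  )
}

#' Write a fitted model's coefficient table
#'
#' Serialises a fit as a delimited table (`coefficient, loghr, hr, se,
#' robust_se`) or as JSON carrying the same fields plus fit metadata.
#'
#' @param fit An `svycox_fit`.
#' @param path Output path; the `format` defaults from its extension.
#' @param format `"csv"` or `"json"`.
#' @return `fit`, invisibly.
#' @export
write_fit <- function(fit, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  td <- tidy(fit)
  tab <- tibble::tibble(
    coefficient = td$term, loghr = td$estimate, hr = td$hr,
    se = td$se, robust_se = td$robust_se
  )
  if (format == "csv") {
    readr::write_csv(tab, path)
  } else {
    jsonlite::write_json(
      list(coefficients = tab, n = fit$n, n_events = fit$n_events,
           loglik = fit$loglik, iterations = fit$iter,
           converged = fit$converged, model = fit$model),
      path, auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
  }
  invisible(fit)
}
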
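test_that("design matrices encode the three model specifications", {
  tab <- tibble::tibble(
    id = 1:4,
    stratum = factor(c("professionals", "professionals", "technicians",
                       "administrative"),
                     levels = c("professionals", "technicians", "administrative")),
    smoker = c(0L, 1L, 1L, 1L),
    time = c(1, 2, 3, 4),
    event = c(1L, 1L, 1L, 0L)
  )
  full <- build_design_matrix(tab, "full")
  expect_identical(colnames(full$X),
                   c("tech", "admin", "prof_smoking", "tech_smoking",
                     "admin_smoking"))
  # professional non-smoker is the all-zero reference row in every model
  expect_equal(unname(full$X[1, ]), rep(0, 5))
  # administrative smoker
  expect_equal(unname(full$X[4, ]), c(0, 1, 0, 0, 1))
  # technician smoker
  expect_equal(unname(full$X[3, ]), c(1, 0, 0, 1, 0))
  marg <- build_design_matrix(tab, "marginal")
  expect_identical(colnames(marg$X), c("tech", "admin", "smoking"))
  expect_equal(unname(marg$X[2, ]), c(0, 0, 1))   # professional smoker
  smk <- build_design_matrix(tab, "smoke_only")
  expect_identical(colnames(smk$X), "smoking")
  expect_equal(unname(smk$X[, 1]), as.numeric(tab$smoker))
  # unit weights attached when no weight column exists
  expect_equal(full$weights, rep(1, 4))
  expect_error(build_design_matrix(tab, "bogus"))
  expect_error(build_design_matrix(tab[0, ], "full"), "empty")
})

test_that("toy instance recovers the closed-form estimate and matches the grid oracle", {
  toy <- toy_cox_instance()
  fit <- fit_weighted_cox(toy$X, toy$time, toy$event)
  expect_equal(unname(coef(fit)), -log(2) / 2, tolerance = 1e-10)
  b_grid <- oracle_grid_fit_1d(toy$X, toy$time, toy$event)
  expect_equal(unname(coef(fit)), b_grid, tolerance = 1e-4)
})

test_that("solver matches the brute-force partial-likelihood oracle on small instances", {
  for (seed in c(101, 102, 103)) {
    inst <- random_instance(n = 6, p = 2, seed = seed)
    fit <- fit_weighted_cox(inst$X, inst$time, inst$event, inst$w)
    b_oracle <- oracle_optim_fit(inst$X, inst$time, inst$event, inst$w)
    expect_equal(unname(coef(fit)), b_oracle, tolerance = 1e-4)
    # solved point also beats every oracle grid neighbour in likelihood
    ll_hat <- oracle_logpl(coef(fit), inst$X, inst$time, inst$event, inst$w)
    ll_near <- oracle_logpl(coef(fit) + c(0.01, -0.01),
                            inst$X, inst$time, inst$event, inst$w)
    expect_gt(ll_hat, ll_near)
  }
})

test_that("unit weights reproduce the reference unweighted implementation to 1e-8", {
  skip_if_not_installed("survival")
  for (seed in c(201, 202, 203, 204)) {
    inst <- random_instance(n = 80, p = 3, seed = seed)
    fit <- fit_weighted_cox(inst$X, inst$time, inst$event)
    cf <- survival::coxph(survival::Surv(inst$time, inst$event) ~ inst$X,
                          ties = "breslow")
    expect_equal(unname(coef(fit)), unname(coef(cf)), tolerance = 1e-8)
    expect_equal(unname(fit$var), unname(cf$var), tolerance = 1e-8)
  }
})

test_that("weighted fit and robust variance match the reference survey-weighted fit", {
  skip_if_not_installed("survival")
  inst <- random_instance(n = 120, p = 2, seed = 301)
  fit <- fit_weighted_cox(inst$X, inst$time, inst$event, inst$w)
  cf <- survival::coxph(survival::Surv(inst$time, inst$event) ~ inst$X,
                        weights = inst$w, robust = TRUE, ties = "breslow")
  expect_equal(unname(coef(fit)), unname(coef(cf)), tolerance = 1e-8)
  expect_equal(unname(fit$robust_var), unname(cf$var), tolerance = 1e-8)
  expect_equal(unname(fit$var), unname(cf$naive.var), tolerance = 1e-8)
})

test_that("estimates and robust variance are invariant to rescaling all weights", {
  inst <- random_instance(n = 60, p = 2, seed = 401)
  f1 <- fit_weighted_cox(inst$X, inst$time, inst$event, inst$w)
  f7 <- fit_weighted_cox(inst$X, inst$time, inst$event, inst$w * 7)
  expect_equal(coef(f1), coef(f7), tolerance = 1e-9)
  expect_equal(f1$robust_var, f7$robust_var, tolerance = 1e-9)
  # constant weights equal the unweighted fit
  fu <- fit_weighted_cox(inst$X, inst$time, inst$event)
  fc <- fit_weighted_cox(inst$X, inst$time, inst$event, rep(7, nrow(inst$X)))
  expect_equal(coef(fu), coef(fc), tolerance = 1e-9)
})

test_that("weight 2 equals record duplication for the point estimate", {
  inst <- random_instance(n = 20, p = 2, seed = 501)
  w <- rep(1, 20); w[5] <- 2
  f_w <- fit_weighted_cox(inst$X, inst$time, inst$event, w)
  X2 <- rbind(inst$X, inst$X[5, , drop = FALSE])
  f_dup <- fit_weighted_cox(X2, c(inst$time, inst$time[5]),
                            c(inst$event, inst$event[5]))
  expect_equal(coef(f_w), coef(f_dup), tolerance = 1e-8)
})

test_that("robust SE approaches model-based SE under correct specification", {
  withr::with_seed(601, {
    n <- 4000
    x <- stats::rbinom(n, 1, 0.4)
    tm <- stats::rexp(n, 0.05 * exp(0.5 * x))
    ev <- as.integer(tm <= 20)
    tm <- pmin(tm, 20)
  })
  fit <- fit_weighted_cox(matrix(x, ncol = 1), tm, ev)
  ratio <- sqrt(diag(fit$robust_var)) / sqrt(diag(fit$var))
  expect_lt(abs(ratio - 1), 0.1)
})

test_that("sandwich covariance tracks a delete-one jackknife on a small instance", {
  inst <- random_instance(n = 25, p = 1, seed = 701)
  fit <- fit_weighted_cox(inst$X, inst$time, inst$event)
  beta_hat <- coef(fit)
  jack <- vapply(seq_len(25), function(i) {
    f <- fit_weighted_cox(inst$X[-i, , drop = FALSE], inst$time[-i],
                          inst$event[-i])
    unname(coef(f))
  }, numeric(1))
  v_jack <- sum((jack - beta_hat)^2)   # jackknife-style sum of squared shifts
  v_sand <- fit$robust_var[1, 1]
  # the sandwich is the infinitesimal-jackknife variance; at n = 25 it agrees
  # with the delete-one jackknife within a factor of 4 on this instance
  expect_gt(v_sand / v_jack, 0.25)
  expect_lt(v_sand / v_jack, 4)
})

test_that("degenerate inputs raise informative errors", {
  inst <- random_instance(n = 10, p = 1, seed = 801)
  expect_error(fit_weighted_cox(inst$X, inst$time, rep(0L, 10)),
               "At least one event")
  expect_error(fit_weighted_cox(inst$X, inst$time, inst$event, rep(-1, 10)),
               "positive")
  # perfectly collinear columns
  X2 <- cbind(inst$X, inst$X)
  expect_error(fit_weighted_cox(X2, inst$time, inst$event), "rank-deficient")
  # monotone likelihood: the only event has the extreme covariate value
  expect_error(
    fit_weighted_cox(matrix(c(0, 1, 1, 1), ncol = 1), c(1, 2, 3, 4),
                     c(1L, 0L, 0L, 0L)),
    class = "svycoxsim_convergence_error"
  )
})

test_that("tidy and glance expose the fit in broom style", {
  toy <- toy_cox_instance()
  fit <- fit_weighted_cox(toy$X, toy$time, toy$event)
  td <- tidy(fit)
  expect_identical(names(td), c("term", "estimate", "hr", "se", "robust_se",
                                "statistic", "p.value"))
  expect_equal(td$hr, exp(td$estimate))   # exact identity
  expect_true(all(td$se > 0) && all(td$robust_se > 0))
  gl <- glance(fit)
  expect_identical(gl$n, 3L)
  expect_identical(gl$n_events, 2L)
  expect_true(gl$converged)
})

test_that("fit results serialise as delimited table and JSON", {
  toy <- toy_cox_instance()
  fit <- fit_weighted_cox(toy$X, toy$time, toy$event)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_fit(fit, csv)
  write_fit(fit, js)
  tab <- readr::read_csv(csv, show_col_types = FALSE)
  expect_identical(names(tab),
                   c("coefficient", "loghr", "hr", "se", "robust_se"))
  expect_equal(tab$loghr, unname(coef(fit)))
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$coefficients$loghr, unname(coef(fit)))
  expect_identical(parsed$n, 3L)
})
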
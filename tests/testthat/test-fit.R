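# Mixed-effects fitting: self-consistency, methods, model comparison.

# a modest study used by several blocks; fitted once
fit_cache <- local({
  cfg <- sim_config(design = scale_design(study_design(), 0.25))
  data <- simulate_study(cfg, seed = 23)
  list(cfg = cfg, data = data, fit = NULL)
})
get_fit <- function() {
  if (is.null(fit_cache$fit))
    fit_cache$fit <<- pk_fit(fit_cache$data, control = pk_control(restarts = 1))
  fit_cache$fit
}

test_that("noiseless dense data recover the generating parameters within
           one percent", {
  # nearly the full sampling menu per animal, so the terminal phase
  # (which carries the peripheral-volume information) is well covered
  des <- data.frame(group = rep(c("control", "irradiated"), each = 2),
                    route = rep(c("gavage", "iv"), 2),
                    dose_ug = rep(c(300, 60), 2),
                    n_plasma = c(12, 3, 12, 3),
                    urine = TRUE,
                    n = c(8, 5, 8, 5), stringsAsFactors = FALSE)
  # dense, almost noise-free data with no between-animal variability:
  # initializing the random-effect SDs below their activation
  # threshold keeps them pinned at zero (the likelihood is then exact,
  # carrying no mode-approximation bias), so the optimum must sit at
  # the generating values
  cfg <- sim_config(design = des, omega = c(V2 = 0, V3 = 0),
                    sigma = c(plasma = 1e-4, urine = 1e-5))
  d <- simulate_study(cfg, seed = 31)
  init <- pk_init(d)
  init$omega <- c(V2 = 1e-9, V3 = 1e-9)
  fit <- pk_fit(d, init = init,
                control = pk_control(restarts = 1, hessian = FALSE,
                                     polish = FALSE))
  est <- coef(fit)
  truth <- c(unlist(cfg$theta),
             setNames(unlist(cfg$ratios), paste0("ratio.", names(cfg$ratios))))
  for (nm in names(truth))
    expect_lt(abs(est[[nm]] / truth[[nm]] - 1), 0.01, label = nm)
})

test_that("degenerate datasets are rejected or flagged", {
  d <- toy_records()
  expect_error(pk_fit(d[d$ID == "A1", ]), "two animals")
  cfg <- sim_config(design = data.frame(
    group = "control", route = "gavage", dose_ug = 300,
    n_plasma = 2, urine = FALSE, n = 8), omega = c(V2 = 0.1, V3 = 0.1))
  d2 <- simulate_study(cfg, seed = 1)
  w <- testthat::capture_warnings(
    try(pk_fit(d2, control = pk_control(hessian = FALSE, polish = FALSE,
                                        restarts = 0, iter_max = 5)),
        silent = TRUE))
  expect_match(w, "weakly identifiable", all = FALSE)
})

test_that("a converged fit exposes the standard modelling methods", {
  fit <- get_fit()
  cfg <- fit_cache$cfg
  expect_s3_class(fit, "pkfit")
  expect_equal(fit$convergence, 0)

  co <- coef(fit)
  expect_named(co, c("ka", "F", "Cl", "Q", "V2", "V3",
                     "ratio.ka", "ratio.Cl", "ratio.Q", "ratio.F",
                     "omega.V2", "omega.V3",
                     "sigma.plasma", "sigma.urine"))
  expect_true(all(co > 0))
  expect_lt(co[["F"]], 1)

  ll <- logLik(fit)
  expect_s3_class(ll, "logLik")
  expect_equal(attr(ll, "df"), 14)

  ci <- confint(fit)
  est <- co[rownames(ci)]
  expect_true(all(ci[, "lwr"] <= est & est <= ci[, "upr"]))

  s <- summary(fit)
  expect_true(all(s$ratios$p_value >= 0 & s$ratios$p_value <= 1))
  expect_equal(s$base$estimate, unname(co[s$base$parameter]))
  expect_output(print(s), "Radiation-group")

  # predictions: individual conditioning should fit at least as well
  obs <- correct_extraction(fit$data$DV, fit$data$EFF)
  keep <- fit$predictions$in_likelihood
  rss_ind <- sum((obs - predict(fit))[keep]^2)
  rss_pop <- sum((obs - predict(fit, level = "population"))[keep]^2)
  expect_lte(rss_ind, rss_pop)
  expect_equal(residuals(fit), obs - fitted(fit))

  # predictions on new data equal population predictions on same data
  expect_equal(predict(fit, newdata = fit$data, level = "population"),
               predict(fit, level = "population"))

  # simulate() round-trips the design
  sims <- simulate(fit, nsim = 2, seed = 99)
  expect_length(sims, 2)
  expect_equal(dim(sims[[1]]), dim(fit$data))
  expect_length(validate_pk_dataset(sims[[1]]), 0)
  expect_false(identical(sims[[1]]$DV, sims[[2]]$DV))
  expect_identical(simulate(fit, seed = 99)[[1]], sims[[1]])
})

test_that("estimates are invariant to animal relabeling", {
  fit <- get_fit()
  d2 <- fit_cache$data
  d2$ID <- paste0("x", match(d2$ID, unique(d2$ID)))
  fit2 <- pk_fit(d2, control = pk_control(restarts = 1))
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-4)
  expect_equal(fit2$logLik, fit$logLik, tolerance = 1e-6)
})

test_that("pooled R-squared behaves as a coefficient of determination", {
  fit <- get_fit()
  r2 <- r_squared(fit)
  expect_gt(r2, 0.8)  # simulated data with 5% noise fit closely
  expect_lte(r2, 1)

  # hand toy: obs (1,2,3) against preds (1,2,4) in one compartment
  obs <- c(1, 2, 3); pred <- c(1, 2, 4)
  expect_equal(1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2), 0.5)
})

test_that("likelihood-ratio comparison of one- and two-compartment
           models is chi-square based", {
  fit <- get_fit()
  fit1 <- pk_fit(fit_cache$data, model = "one_cpt",
                 control = pk_control(restarts = 1, hessian = FALSE,
                                      polish = FALSE))
  cmp <- anova(fit, fit1)
  expect_equal(cmp$df_diff[2], 4)
  expect_gte(cmp$LRT[2], 0)
  expect_equal(cmp$p_value[2],
               pchisq(cmp$LRT[2], 4, lower.tail = FALSE))
  # the data come from a two-compartment model: decisive rejection
  expect_lt(cmp$p_value[2], 1e-3)
  # chi-square tail oracle on a fixed statistic
  expect_equal(pchisq(10, 2, lower.tail = FALSE), 0.006737947,
               tolerance = 1e-6)
})

test_that("initialization heuristics return a valid parameter set", {
  init <- pk_init(fit_cache$data)
  expect_s3_class(init$theta, "pk_params")
  expect_true(all(init$sigma > 0))
  # order-of-magnitude sanity for this design
  expect_lt(init$theta$V2, 1)
  expect_gt(init$theta$ka, 0.01)
})
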
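# Non-compartmental AUC estimation and bootstrap-t inference.

test_that("dose normalization rescales to the reference dose", {
  d <- toy_records()
  nn <- nca_normalize(d, 300)
  expect_equal(nn$DV[1], (1.25 / 0.85) * 300 / 300)
  expect_equal(nn$DV[3], (0.5 / 0.85) * 300 / 60)
  expect_true(all(nn$EFF == 1))
  d0 <- d; d0$DOSE_UG[1] <- 0
  expect_error(nca_normalize(d0), "positive dose")
})

test_that("normalized profiles of different dose arms coincide under
           linear kinetics", {
  des <- data.frame(group = "control", route = "gavage",
                    dose_ug = c(300, 600), n_plasma = 4,
                    urine = FALSE, n = 60, stringsAsFactors = FALSE)
  cfg <- sim_config(design = des, omega = c(V2 = 0, V3 = 0),
                    sigma = c(plasma = 0, urine = 0))
  d <- nca_normalize(simulate_study(cfg, seed = 13))
  d <- d[d$TIME > 0, ]
  m <- tapply(d$DV, list(d$TIME, d$DOSE_UG), mean)
  shared <- stats::complete.cases(m)
  expect_equal(unname(m[shared, 1]), unname(m[shared, 2]),
               tolerance = 1e-10)
})

test_that("trapezoidal AUC is exact arithmetic", {
  expect_equal(auc_tlast(c(0, 1, 2), c(0, 2, 1)), 2.5)
  # exact for any piecewise-linear curve
  tt <- c(0, 0.5, 2, 3, 7)
  f <- function(t) 2 + 0.5 * t
  expect_equal(auc_tlast(tt, f(tt)), 2 * 7 + 0.25 * 49)
  expect_error(auc_tlast(1, 1), "two time points")
  expect_error(auc_tlast(c(1, 1), c(1, 2)), "strictly increasing")
  # inserting a point on the chord changes nothing
  t0 <- c(0, 2, 6); v0 <- c(1, 5, 3)
  t1 <- c(0, 2, 4, 6); v1 <- c(1, 5, 4, 3)
  expect_equal(auc_tlast(t0, v0), auc_tlast(t1, v1))
})

test_that("dense trapezoid converges to the model quadrature", {
  p <- table2_params()
  tt <- seq(0, 24, by = 0.01)
  conc <- pk_solve(p, dose_to_umol(300), "gavage", tt)$conc
  auc_dense <- auc_tlast(tt, conc)
  # independent fine quadrature of the same curve
  tt2 <- seq(0, 24, by = 0.0025)
  conc2 <- pk_solve(p, dose_to_umol(300), "gavage", tt2)$conc
  expect_equal(auc_dense, auc_tlast(tt2, conc2), tolerance = 1e-5)
})

test_that("bootstrap-t intervals are reproducible and bracket the
           estimate", {
  cfg <- sim_config(design = scale_design(study_design(), 0.3))
  d <- simulate_study(cfg, seed = 17)
  a1 <- suppressWarnings(nca_auc(d, "control", B = 500, seed = 42))
  a2 <- suppressWarnings(nca_auc(d, "control", B = 500, seed = 42))
  expect_identical(a1$ci, a2$ci)
  a3 <- suppressWarnings(nca_auc(d, "control", B = 500, seed = 43))
  expect_false(identical(a1$ci, a3$ci))
  expect_lte(a1$ci[1], a1$auc)
  expect_gte(a1$ci[2], a1$auc)
  expect_error(nca_auc(d, "control", B = 50), "199")
})

test_that("zero-variance data give a degenerate interval of width zero", {
  d <- data.frame(ID = sprintf("A%d", 1:12),
                  GROUP = "control", ROUTE = "gavage", DOSE_UG = 300,
                  TIME = rep(c(1, 2, 4), each = 4), CMT = "plasma",
                  DV = rep(c(1, 0.8, 0.5), each = 4), EFF = 1,
                  stringsAsFactors = FALSE)
  a <- nca_auc(d, "control", B = 199, seed = 1)
  expect_equal(a$ci[1], a$auc)
  expect_equal(a$ci[2], a$auc)
})

test_that("the AUC ratio matches the analytic bioavailability/clearance
           ratio on noiseless model profiles", {
  # dense noiseless profiles over a long window: AUC(0-T) approaches
  # F*D/Cl per group, so the ratio approaches r_F / r_Cl
  p <- table2_params()
  r <- table3_ratios()
  pirr <- apply_radiation(p, r)
  tt <- seq(0, 2000, by = 0.5)
  rows <- function(pp, group, ids) {
    conc <- pk_solve(pp, dose_to_umol(300), "gavage", tt)$conc
    do.call(rbind, lapply(ids, function(id)
      data.frame(ID = id, GROUP = group, ROUTE = "gavage", DOSE_UG = 300,
                 TIME = tt, CMT = "plasma", DV = conc, EFF = 1,
                 stringsAsFactors = FALSE)))
  }
  d <- rbind(rows(p, "control", c("c1", "c2")),
             rows(pirr, "irradiated", c("i1", "i2")))
  rat <- suppressWarnings(nca_ratio(d, tlast = 2000, B = 199, seed = 1))
  expect_equal(rat$ratio, r$F / r$Cl, tolerance = 1e-3)  # 1.406

  # swapping the group labels inverts the ratio
  dsw <- d
  dsw$GROUP <- ifelse(d$GROUP == "control", "irradiated", "control")
  rsw <- suppressWarnings(nca_ratio(dsw, tlast = 2000, B = 199, seed = 1))
  expect_equal(rsw$ratio, 1 / rat$ratio, tolerance = 1e-6)
})

test_that("identical groups give a ratio of one and the ratio is
           invariant to common rescaling", {
  cfg <- sim_config(ratios = radiation_effect(),
                    design = scale_design(study_design(), 0.3))
  d <- simulate_study(cfg, seed = 19)
  r1 <- suppressWarnings(nca_ratio(d, B = 400, seed = 7))
  expect_lt(abs(log(r1$ratio)), 3 * sqrt((r1$irradiated$se /
    r1$irradiated$auc)^2 + (r1$control$se / r1$control$auc)^2))
  expect_gt(r1$p_value, 0.01)
  d2 <- d
  d2$DV <- d$DV * 7  # common rescaling of both groups
  r2 <- suppressWarnings(nca_ratio(d2, B = 400, seed = 7))
  expect_equal(r2$ratio, r1$ratio, tolerance = 1e-10)
})
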
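# Synthetic-study generator: schedules, stochastic structure, design.

test_that("sampling menus match the study's scheduled times", {
  set.seed(1)
  # gavage menu has 13 candidate times, IV has 3
  expect_error(sampling_schedule("gavage", 14), "menu")
  expect_error(sampling_schedule("iv", 4), "menu")
  g <- sampling_schedule("gavage", 13)
  expect_equal(g, c(0, 0.5, 1, 1.5, 2, 2.5, 3, 4, 5, 6, 8, 24, 48))
  for (i in 1:20) {
    t4 <- sampling_schedule("gavage", 4)
    expect_length(t4, 4)
    expect_true(all(t4 %in% g))
    expect_false(any(duplicated(t4)))
    tiv <- sampling_schedule("iv", 2)
    expect_true(all(tiv %in% c(5 / 60, 1.5, 24)))
  }
  set.seed(7); a <- sampling_schedule("gavage", 1)
  set.seed(7); b <- sampling_schedule("gavage", 1)
  expect_identical(a, b)
})

test_that("simulated studies honour the design cell by cell", {
  cfg <- sim_config()
  d <- simulate_study(cfg, seed = 5)
  expect_length(validate_pk_dataset(d), 0)
  expect_equal(length(unique(d$ID)), 219)

  # the largest control gavage cell: 55 animals, one plasma draw each
  per_animal <- table(d$ID[d$CMT == "plasma"])
  des <- study_design()
  counts <- stats::aggregate(
    cbind(nplas = d$CMT == "plasma", nurine = d$CMT == "urine"),
    by = d[c("ID", "GROUP", "ROUTE", "DOSE_UG")], FUN = sum)
  for (i in seq_len(nrow(des))) {
    cell <- des[i, ]
    sel <- counts$GROUP == cell$group & counts$ROUTE == cell$route &
      counts$DOSE_UG == cell$dose_ug & counts$nplas == cell$n_plasma &
      counts$nurine == as.integer(cell$urine)
    expect_gte(sum(sel), cell$n)  # cells differing only in draws can merge
  }
  expect_true(all(d$TIME[d$CMT == "urine"] == 24))

  # same seed reproduces the dataset exactly
  expect_identical(simulate_study(cfg, seed = 5), d)
})

test_that("noise-free simulation reproduces the exact solution after the
           efficiency round-trip", {
  cfg <- sim_config(omega = c(V2 = 0, V3 = 0),
                    sigma = c(plasma = 0, urine = 0),
                    design = scale_design(study_design(), 0.1))
  d <- simulate_study(cfg, seed = 2)
  for (i in seq_len(nrow(d))) {
    if (d$DOSE_UG[i] == 0 || (d$CMT[i] == "plasma" && d$TIME[i] == 0)) {
      expect_equal(d$DV[i] / d$EFF[i], 0)
      next
    }
    p <- if (d$GROUP[i] == "irradiated")
      apply_radiation(cfg$theta, cfg$ratios) else cfg$theta
    tr <- pk_solve(p, dose_to_umol(d$DOSE_UG[i]), d$ROUTE[i], d$TIME[i])
    truth <- if (d$CMT[i] == "urine") tr$urine else tr$conc
    expect_equal(d$DV[i] / d$EFF[i], truth, tolerance = 1e-12)
  }
})

test_that("residual noise converges to the configured sigma", {
  des <- data.frame(group = "control", route = "gavage", dose_ug = 300,
                    n_plasma = 1, urine = FALSE, n = 10000)
  cfg <- sim_config(omega = c(V2 = 0, V3 = 0), design = des)
  d <- simulate_study(cfg, seed = 9)
  d <- d[d$TIME > 0, ]
  truth <- vapply(seq_len(nrow(d)), function(i)
    pk_solve(cfg$theta, dose_to_umol(300), "gavage", d$TIME[i])$conc, 0)
  res <- d$DV / d$EFF - truth
  expect_equal(sd(res), cfg$sigma[["plasma"]], tolerance = 0.05)
  expect_lt(abs(mean(res)), 3 * cfg$sigma[["plasma"]] / sqrt(nrow(d)))
})

test_that("individual volumes are log-normal with the configured spread", {
  des <- data.frame(group = "control", route = "iv", dose_ug = 60,
                    n_plasma = 1, urine = FALSE, n = 1000)
  # no elimination or exchange: the IV concentration is exactly D/V2
  # at every time, so each animal's volume can be read off directly
  theta0 <- pk_params(ka = 0.279, F = 0.192, Cl = 0, Q = 0,
                      V2 = 0.008, V3 = 0.513)
  cfg <- sim_config(theta = theta0, omega = c(V2 = 0.3, V3 = 0.3),
                    sigma = c(plasma = 0, urine = 0), design = des)
  d <- simulate_study(cfg, seed = 11)
  d <- d[d$TIME > 0, ]
  lv <- log(dose_to_umol(60) / (d$DV / d$EFF))
  expect_equal(sd(lv), 0.3, tolerance = 0.1)
  expect_equal(mean(lv), log(theta0$V2), tolerance = 0.05)
  expect_gt(shapiro.test(sample(lv, 500))$p.value, 0.001)
})

test_that("default residual scales derive from the model, not the data", {
  cfg <- sim_config()
  grid <- seq(0, 48, by = 0.05)
  cmax <- max(pk_solve(cfg$theta, dose_to_umol(300), "gavage", grid)$conc)
  expect_equal(cfg$sigma[["plasma"]], 0.05 * cmax)
  expect_gt(cfg$sigma[["urine"]], 0)
  expect_lt(cfg$sigma[["urine"]], cfg$sigma[["plasma"]])
})
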
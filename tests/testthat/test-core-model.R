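# Exact solution of the compartmental system and derived parameters.

test_that("micro-constants are exact ratios of clearances and volumes", {
  p <- table2_params()
  mc <- micro_constants(p)
  expect_equal(mc[["k10"]], 0.009 / 0.008)
  expect_equal(mc[["k12"]], 0.014 / 0.008)
  expect_equal(mc[["k21"]], 0.014 / 0.513)

  # no exchange path: both transfer constants vanish
  q0 <- pk_params(ka = 1, F = 0.5, Cl = 0.01, Q = 0, V2 = 0.01, V3 = 1)
  expect_equal(unname(micro_constants(q0)[c("k12", "k21")]), c(0, 0))

  # equal volumes give symmetric transfer
  ve <- pk_params(ka = 1, F = 0.5, Cl = 0.01, Q = 0.02, V2 = 0.3, V3 = 0.3)
  mce <- micro_constants(ve)
  expect_equal(mce[["k12"]], mce[["k21"]])
})

test_that("disposition rates are the eigenvalues of the disposition matrix", {
  for (p in random_params(25, seed = 11)) {
    mc <- micro_constants(p)
    ab <- disposition_rates(p)
    A <- matrix(c(-(mc[["k10"]] + mc[["k12"]]), mc[["k21"]],
                  mc[["k12"]], -mc[["k21"]]), 2, 2, byrow = TRUE)
    ev <- sort(-eigen(A, only.values = TRUE)$values)
    expect_equal(unname(ab[c("beta", "alpha")]), ev, tolerance = 1e-10)
    # root identities of the characteristic quadratic
    expect_equal(ab[["alpha"]] * ab[["beta"]], mc[["k10"]] * mc[["k21"]])
    expect_equal(ab[["alpha"]] + ab[["beta"]], sum(mc))
    expect_gte(ab[["alpha"]], ab[["beta"]])
  }
})

test_that("degenerate exchange decouples the compartments", {
  q0 <- pk_params(ka = 1, F = 0.5, Cl = 0.02, Q = 0, V2 = 0.01, V3 = 1)
  ab <- disposition_rates(q0)
  expect_equal(unname(ab), c(2, 0))  # (k10, 0)
  cl0 <- pk_params(ka = 1, F = 0.5, Cl = 0, Q = 0.02, V2 = 0.01, V3 = 1)
  expect_equal(disposition_rates(cl0)[["beta"]], 0)
  expect_error(terminal_half_life(cl0), "no terminal elimination")
})

test_that("terminal half-life reproduces the published 65 h and 83 h", {
  ctrl <- table2_params()
  expect_equal(round(terminal_half_life(ctrl)), 65)
  irr <- apply_radiation(ctrl, table3_ratios())
  expect_lt(abs(terminal_half_life(irr) - 83), 1)
  # one-compartment limit as the peripheral volume vanishes
  small <- pk_params(ka = 0.279, F = 0.192, Cl = 0.009, Q = 0.014,
                     V2 = 0.008, V3 = 1e-9)
  expect_equal(terminal_half_life(small), log(2) * 0.008 / 0.009,
               tolerance = 1e-4)
})

test_that("radiation ratios act multiplicatively on ka, Cl, Q, F only", {
  p <- table2_params()
  r <- table3_ratios()
  pi <- apply_radiation(p, r)
  expect_equal(pi$ka, 0.279 * 0.883)
  expect_equal(pi$Cl, 0.009 * 0.943)
  expect_equal(pi$Q, 0.014 * 0.615)
  expect_equal(pi$F, 0.192 * 1.326)
  expect_equal(pi$V2, p$V2)
  expect_equal(pi$V3, p$V3)
  expect_equal(unlist(apply_radiation(p, radiation_effect())), unlist(p))
  expect_error(apply_radiation(p, radiation_effect(F = 6)),
               "bioavailability")
})

test_that("analytic AUC to infinity matches F*D/Cl and quadrature", {
  p <- table2_params()
  d300 <- dose_to_umol(300)
  expect_equal(auc_infinity(p, d300, "gavage"), 0.192 * d300 / 0.009)
  # IV is independent of F
  p2 <- pk_params(ka = p$ka, F = 0.5, Cl = p$Cl, Q = p$Q, V2 = p$V2,
                  V3 = p$V3)
  expect_equal(auc_infinity(p, 1, "iv"), auc_infinity(p2, 1, "iv"))
  expect_error(auc_infinity(pk_params(ka = 1, F = 0.5, Cl = 0, Q = 0.01,
                                      V2 = 0.01, V3 = 1), 1, "gavage"),
               "diverges")
  # quadrature of the solved concentration curve over a long horizon,
  # with a fine grid over the steep absorption/distribution phase
  tt <- unique(c(seq(0, 50, by = 0.005), seq(50, 3000, by = 0.25)))
  conc <- pk_solve(p, d300, "gavage", tt)$conc
  auc_num <- sum(diff(tt) * (head(conc, -1) + conc[-1]) / 2)
  expect_equal(auc_num, auc_infinity(p, d300, "gavage"), tolerance = 1e-4)
})

test_that("IV solution starts at dose/V2 and conserves mass", {
  p <- table2_params()
  d <- dose_to_umol(60)
  tr <- pk_solve(p, d, "iv", c(0, 0.0833, 1.5, 24, 100))
  expect_equal(tr$conc[1], d / p$V2)  # 18.50 umol/L
  expect_equal(tr$plasma + tr$peripheral + tr$urine, rep(d, 5),
               tolerance = 1e-10)
})

test_that("urinary recovery approaches F*dose (gavage) and dose (IV)", {
  p <- table2_params()
  d <- dose_to_umol(300)
  expect_equal(pk_solve(p, d, "gavage", 5e4)$urine, p$F * d,
               tolerance = 1e-6)
  expect_equal(pk_solve(p, d, "iv", 5e4)$urine, d, tolerance = 1e-6)
})

test_that("closed form matches adaptive ODE integration on random draws", {
  skip_if_not_installed("deSolve")
  times <- c(0.5, 2, 8, 24)
  for (p in random_params(30, seed = 21)) {
    for (route in c("gavage", "iv")) {
      tr <- pk_solve(p, 1, route, times)
      orc <- ode_oracle(p, 1, route, times)
      got <- as.matrix(tr[, c("depot", "plasma", "peripheral", "urine")])
      # relative where the state is appreciable; states many orders
      # below the dose are checked absolutely at the oracle's accuracy
      scale <- pmax(abs(orc), 1e-4)
      expect_lt(max(abs(got - orc) / scale), 1e-8)
    }
  }
})

test_that("confluent and degenerate rate constants use the exact fallback", {
  skip_if_not_installed("deSolve")
  times <- c(0.5, 2, 8, 24)
  # ka coinciding with alpha, Q = 0, Cl = 0
  p1 <- pk_params(ka = 2, F = 0.5, Cl = 0.02, Q = 0, V2 = 0.01, V3 = 1)
  p1$ka <- disposition_rates(p1)[["alpha"]]
  p2 <- pk_params(ka = 1, F = 0.5, Cl = 0, Q = 0.02, V2 = 0.01, V3 = 1)
  p3 <- pk_params(ka = 1, F = 0.5, Cl = 0.02, Q = 0, V2 = 0.01, V3 = 1)
  for (p in list(p1, p2, p3)) {
    tr <- pk_solve(p, 1, "gavage", times)
    orc <- ode_oracle(p, 1, "gavage", times)
    got <- as.matrix(tr[, c("depot", "plasma", "peripheral", "urine")])
    expect_lt(max(abs(got - orc) / pmax(abs(orc), 1e-4)), 1e-7)
  }
})

test_that("solutions are linear in dose and monotone where required", {
  p <- table2_params()
  tt <- c(0.5, 1, 2, 4, 8, 24, 48, 96)
  for (route in c("gavage", "iv")) {
    tr1 <- pk_solve(p, 1, route, tt)
    tr3 <- pk_solve(p, 3, route, tt)
    for (col in c("depot", "plasma", "peripheral", "urine"))
      expect_equal(tr3[[col]], 3 * tr1[[col]], tolerance = 1e-12)
    expect_true(all(diff(tr1$urine) >= 0))
    expect_true(all(diff(tr1$depot) <= 0))
    expect_true(all(as.matrix(tr1[, -1]) >= 0))
  }
})

test_that("gavage mass balance includes the depot scaled by F", {
  for (p in random_params(10, seed = 31)) {
    tr <- pk_solve(p, 2, "gavage", c(0, 0.5, 3, 12, 48, 200))
    lhs <- tr$plasma + tr$peripheral + tr$urine + p$F * tr$depot
    expect_equal(lhs, rep(p$F * 2, 6), tolerance = 1e-8 * p$F * 2)
  }
})

test_that("late log-concentration decline has slope -beta", {
  p <- table2_params()
  beta <- disposition_rates(p)[["beta"]]
  tt <- seq(200, 400, by = 5)
  lc <- log(pk_solve(p, 1, "gavage", tt)$conc)
  slope <- coef(lm(lc ~ tt))[["tt"]]
  expect_equal(slope, -beta, tolerance = 0.01)
})

test_that("solver rejects malformed time vectors and doses", {
  p <- table2_params()
  expect_error(pk_solve(p, 1, "gavage", c(2, 1)), "non-decreasing")
  expect_error(pk_solve(p, 1, "gavage", c(-1, 1)), "negative")
  expect_error(pk_solve(p, -1, "gavage", 1), "positive")
})

test_that("parameter containers enforce their invariants", {
  expect_error(pk_params(ka = -1, F = 0.5, Cl = 0.01, Q = 0.01,
                         V2 = 0.01, V3 = 1), "'ka'")
  expect_error(pk_params(ka = 1, F = 1.2, Cl = 0.01, Q = 0.01,
                         V2 = 0.01, V3 = 1), "'F'")
  expect_error(pk_params(ka = 1, F = 0.5, Cl = 0.01, Q = 0.01,
                         V2 = 0, V3 = 1), "volumes")
  expect_error(radiation_effect(ka = 0), "positive")
})

test_that("individual parameters apply log-normal effects to volumes", {
  p <- table2_params()
  expect_equal(unlist(individual_parameters(p, c(0, 0))), unlist(p))
  pi <- individual_parameters(p, c(log(2), 0))
  expect_equal(pi$V2, 2 * p$V2)
  expect_equal(pi$V3, p$V3)
  expect_equal(pi$ka, p$ka)
})
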
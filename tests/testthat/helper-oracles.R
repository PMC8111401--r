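# Independent numerical oracles used to check the closed-form solver
# and the Laplace marginal likelihood.

# Adaptive ODE integration of the compartmental system (deSolve), the
# reference for the closed-form solution.
ode_oracle <- function(p, dose_umol, route, times, one_cpt = FALSE) {
  k10 <- p$Cl / p$V2
  k12 <- if (one_cpt) 0 else p$Q / p$V2
  k21 <- if (one_cpt) 0 else p$Q / p$V3
  deriv <- function(t, y, parms) {
    list(c(-p$ka * y[1],
           p$F * p$ka * y[1] - (k10 + k12) * y[2] + k21 * y[3],
           k12 * y[2] - k21 * y[3],
           k10 * y[2]))
  }
  y0 <- if (route == "iv") c(0, dose_umol, 0, 0) else c(dose_umol, 0, 0, 0)
  tt <- sort(unique(c(0, times)))
  out <- deSolve::lsoda(y0, tt, deriv, parms = NULL,
                        rtol = 1e-12, atol = 1e-14)
  out <- out[match(times, out[, 1]), -1, drop = FALSE]
  colnames(out) <- c("depot", "plasma", "peripheral", "urine")
  out
}

# log-density of one animal's records at given random effects
animal_joint <- function(records, theta, ratios, omega, sigma, eta,
                         one_cpt = FALSE) {
  p0 <- if (records$GROUP[1] == "irradiated")
    apply_radiation(theta, ratios) else theta
  p <- p0
  p$V2 <- p0$V2 * exp(eta[1])
  if (!one_cpt) p$V3 <- p0$V3 * exp(eta[2])
  ll <- 0
  for (r in seq_len(nrow(records))) {
    if (records$CMT[r] == "plasma" && records$TIME[r] <= 0) next
    tr <- pk_solve(p, dose_to_umol(records$DOSE_UG[r]), records$ROUTE[r],
                   records$TIME[r],
                   model = if (one_cpt) "one_cpt" else "two_cpt")
    mu <- if (records$CMT[r] == "urine") tr$urine else tr$conc
    s <- if (records$CMT[r] == "urine") sigma[["urine"]] else
      sigma[["plasma"]]
    ll <- ll + dnorm(records$DV[r] / records$EFF[r], mu, s, log = TRUE)
  }
  ll + sum(dnorm(eta[1], 0, omega[["V2"]], log = TRUE),
           if (!one_cpt) dnorm(eta[2], 0, omega[["V3"]], log = TRUE))
}

# Adaptive (mode-centred, curvature-scaled) tensor Gauss-Hermite
# integration of one animal's marginal likelihood over its random
# effects: the reference for the Laplace approximation.
agh_animal_loglik <- function(records, theta, ratios, omega, sigma,
                              n_nodes = 30) {
  q <- pracma::gaussHermite(n_nodes)
  f <- function(e) animal_joint(records, theta, ratios, omega, sigma, e)
  opt <- optim(c(0, 0), function(e) -f(e), method = "L-BFGS-B",
               lower = -8, upper = 8,
               control = list(factr = 10, maxit = 500))
  H <- optimHess(opt$par, function(e) -f(e))
  L <- t(chol(solve(H)))  # H^-1 = L L'
  total <- 0
  for (i in seq_len(n_nodes)) for (j in seq_len(n_nodes)) {
    x <- c(q$x[i], q$x[j])
    e <- opt$par + sqrt(2) * as.numeric(L %*% x)
    total <- total +
      q$w[i] * q$w[j] * exp(sum(x^2)) * exp(f(e) + opt$value)
  }
  # 2^(q/2) det(L) prefactor, back on the log scale
  log(total) + log(2) + 0.5 * log(det(solve(H))) - opt$value
}

# dataset-level adaptive GH marginal log-likelihood
agh_loglik <- function(data, theta, ratios, omega, sigma, n_nodes = 30) {
  sum(vapply(split(data, data$ID), agh_animal_loglik, 0,
             theta = theta, ratios = ratios, omega = omega, sigma = sigma,
             n_nodes = n_nodes))
}
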
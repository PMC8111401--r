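# Marginal likelihood of the nonlinear mixed-effects model.
#
# Observation model, per animal i with records (t_ij, y_ij):
#   plasma:  y ~ N(Cplasma(t; p_i), sigma_plasma^2)
#   urine:   y ~ N(Yurine(t; p_i),  sigma_urine^2)
# where p_i are the animal's individual parameters: the group-typical
# values (control theta, with multiplicative radiation ratios on ka,
# Cl, Q, F in the irradiated group) and log-normal random effects on
# the volumes, V2_i = V2 exp(eta_i1), V3_i = V3 exp(eta_i2),
# eta_i ~ N(0, diag(omega_V2^2, omega_V3^2)).
#
# The marginal likelihood integrates the random effects out per animal.
# The integral is approximated by the Laplace method: an exact Newton
# search for each animal's conditional mode eta*, then a second-order
# expansion of the joint log-density there.  The whole computation is
# vectorized across animals (the Newton iterations for all animals run
# in lockstep on flat vectors), which makes a full-design evaluation a
# few milliseconds.  Components with omega = 0 are treated as fixed at
# eta = 0 and drop out of the integral, recovering the plain Gaussian
# likelihood when both omegas vanish.

# ---- data preparation -------------------------------------------------

# Flattens a validated dataset into the vectors used by the likelihood.
# Pre-dose plasma rows (TIME == 0) are retained in `all` (for
# prediction output, with prediction 0) but excluded from the
# likelihood rows.  Rows are sorted by animal so per-animal sums reduce
# to a cumsum trick.
.prep_fit_data <- function(data) {
  .assert_pk_dataset(data)
  d <- data
  d$.row <- seq_len(nrow(d))
  d$.y <- correct_extraction(d$DV, d$EFF)
  d$.dose <- dose_to_umol(d$DOSE_UG)
  d$.iv <- d$ROUTE == "iv"
  d$.urine <- d$CMT == "urine"
  d$.irr <- d$GROUP == "irradiated"

  # per-animal metadata must be consistent
  meta <- unique(d[, c("ID", "GROUP", "ROUTE", "DOSE_UG")])
  dup <- meta$ID[duplicated(meta$ID)]
  if (length(dup))
    stop("inconsistent group/route/dose metadata for animal(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)

  lik <- d[!(d$.urine == FALSE & d$TIME <= 0), , drop = FALSE]
  if (nrow(lik) == 0L) stop("no post-dose observations", call. = FALSE)
  lik <- lik[order(match(lik$ID, unique(lik$ID))), , drop = FALSE]
  anim_ids <- unique(lik$ID)
  anim <- match(lik$ID, anim_ids)
  ends <- cumsum(tabulate(anim, nbins = length(anim_ids)))
  irr_anim <- lik$.irr[ends]  # consistent within animal (checked above)

  list(all = d,
       n_anim = length(anim_ids), anim_ids = anim_ids,
       anim = anim, ends = ends, irr_anim = irr_anim,
       time = lik$TIME, dose = lik$.dose, y = lik$.y,
       iv = lik$.iv, urine = lik$.urine, irr = lik$.irr,
       lik_row = lik$.row)
}

# group sums of x by the sorted animal index, via cumsum over block ends
.anim_sum <- function(x, ends) {
  cs <- cumsum(x)
  tot <- cs[ends]
  c(tot[1], diff(tot))
}

# ---- parameter transforms --------------------------------------------

# Free parameters on the estimation scale:
#   log ka, logit F, log Cl, log Q, log V2, log V3     (structural)
#   log r_ka, log r_Cl, log r_Q, log r_F               (radiation ratios)
#   log omega_V2, log omega_V3, log sigma_p, log sigma_u
# The one-compartment model drops Q, V3, r_Q and omega_V3.
.par_names <- function(model) {
  if (model == "two_cpt")
    c("lka", "logitF", "lCl", "lQ", "lV2", "lV3",
      "lr.ka", "lr.Cl", "lr.Q", "lr.F",
      "lomega.V2", "lomega.V3", "lsigma.plasma", "lsigma.urine")
  else
    c("lka", "logitF", "lCl", "lV2",
      "lr.ka", "lr.Cl", "lr.F",
      "lomega.V2", "lsigma.plasma", "lsigma.urine")
}

.pack_par <- function(theta, ratios, omega, sigma, model) {
  lg <- function(x) log(unname(x))
  if (model == "two_cpt")
    setNames(c(lg(theta$ka), qlogis(theta$F), lg(theta$Cl), lg(theta$Q),
               lg(theta$V2), lg(theta$V3),
               lg(ratios$ka), lg(ratios$Cl), lg(ratios$Q), lg(ratios$F),
               lg(omega[["V2"]]), lg(omega[["V3"]]),
               lg(sigma[["plasma"]]), lg(sigma[["urine"]])),
             .par_names(model))
  else
    setNames(c(lg(theta$ka), qlogis(theta$F), lg(theta$Cl), lg(theta$V2),
               lg(ratios$ka), lg(ratios$Cl), lg(ratios$F),
               lg(omega[["V2"]]), lg(sigma[["plasma"]]), lg(sigma[["urine"]])),
             .par_names(model))
}

.unpack_par <- function(par, model) {
  p <- as.list(par)
  names(p) <- .par_names(model)
  two <- model == "two_cpt"
  list(ka = exp(p$lka), F = plogis(p$logitF), Cl = exp(p$lCl),
       Q = if (two) exp(p$lQ) else 0,
       V2 = exp(p$lV2), V3 = if (two) exp(p$lV3) else 1,
       r_ka = exp(p$lr.ka), r_Cl = exp(p$lr.Cl),
       r_Q = if (two) exp(p$lr.Q) else 1, r_F = exp(p$lr.F),
       om2 = exp(p$lomega.V2), om3 = if (two) exp(p$lomega.V3) else 0,
       sp = exp(p$lsigma.plasma), su = exp(p$lsigma.urine))
}

# ---- the Laplace engine ----------------------------------------------

# Smooth one-sided floor: s(x) ~ x for x >> 1, s(x) -> 1 for x <= 1,
# C-infinity throughout (softplus).  Used to floor mode curvatures at
# the prior curvature without the derivative kink a hard max would
# place right where optimizers and finite differences operate.
.smooth_floor <- function(x) {
  x[!is.finite(x)] <- 0
  ifelse(x > 13, x, 1 + log1p(exp(4 * (x - 1))) / 4)
}

# Gauss-Hermite nodes and weights (Golub-Welsch), cached per order.
.gh_cache <- new.env(parent = emptyenv())
.gh_nodes <- function(K) {
  key <- as.character(K)
  if (!is.null(.gh_cache[[key]])) return(.gh_cache[[key]])
  if (K == 1) {
    out <- list(x = 0, w = sqrt(pi), lw = 0.5 * log(pi))
  } else {
    J <- matrix(0, K, K)
    off <- sqrt(seq_len(K - 1) / 2)
    J[cbind(1:(K - 1), 2:K)] <- off
    J[cbind(2:K, 1:(K - 1))] <- off
    eg <- eigen(J, symmetric = TRUE)
    out <- list(x = eg$values, w = sqrt(pi) * eg$vectors[1, ]^2)
  }
  out$lwx <- log(out$w) + out$x^2   # log of exp(x^2) * w
  .gh_cache[[key]] <- out
  out
}

# FD step for the random-effect derivatives: large enough that the
# second-difference numerator (~ curvature * h^2) stays far above
# double-precision rounding of the joint density, keeping the Laplace
# objective smooth to ~1e-9 for the outer optimizer.
.LAPLACE <- list(h = 1e-3, tol = 1e-9, maxit = 100L)

# Marginal log-likelihood for one candidate parameter vector.
# `eta_env`, when supplied, warm-starts and caches the per-animal modes
# across successive calls (used by the outer optimizer).
#
# All stencil points of the inner Newton iteration (the value, the four
# axial shifts and the two diagonal shifts of the random effects) are
# evaluated in a single batched prediction call over a 7-fold replicated
# row vector, which keeps the per-call interpreter overhead constant in
# the number of derivative evaluations.
.marginal_ll <- function(u, prep, model, eta_env = NULL, nodes = 1) {
  two <- model == "two_cpt"
  if (u$F * u$r_F >= 1)  # irradiated bioavailability must stay below 1
    return(-1e10 * (1 + u$F * u$r_F))

  rk <- ifelse(prep$irr, u$r_ka, 1)
  rc <- ifelse(prep$irr, u$r_Cl, 1)
  rq <- ifelse(prep$irr, u$r_Q, 1)
  rf <- ifelse(prep$irr, u$r_F, 1)
  ka <- u$ka * rk; F <- u$F * rf; Cl <- u$Cl * rc; Q <- u$Q * rq
  sig <- ifelse(prep$urine, u$su, u$sp)
  ln_sig <- sum(log(sig)) + 0.5 * log(2 * pi) * length(sig)

  anim <- prep$anim; ends <- prep$ends; N <- prep$n_anim
  n <- length(prep$y)
  est1 <- u$om2 > 1e-8          # is eta on V2 a free random effect?
  est2 <- two && u$om3 > 1e-8

  # joint log-density (up to ln_sig and the prior normalizer) per
  # animal for one eta configuration
  gfun <- function(e1, e2) {
    V2i <- u$V2 * exp(e1)[anim]
    V3i <- if (two) u$V3 * exp(e2)[anim] else 1
    pred <- if (two)
      .pred_rows2(prep$time, prep$dose, prep$iv, prep$urine,
                  ka, F, Cl, Q, V2i, V3i)
    else
      .pred_rows1(prep$time, prep$dose, prep$iv, prep$urine, ka, F, Cl, V2i)
    r <- (prep$y - pred) / sig
    g <- .anim_sum(-0.5 * r * r, ends)
    if (est1) g <- g - 0.5 * e1 * e1 / (u$om2 * u$om2)
    if (est2) g <- g - 0.5 * e2 * e2 / (u$om3 * u$om3)
    g[!is.finite(g)] <- -1e8  # overflowed prediction: impossibly bad fit
    g
  }

  e1 <- numeric(N); e2 <- numeric(N)
  if (!is.null(eta_env) && !is.null(eta_env$eta) &&
      nrow(eta_env$eta) == N) {
    if (est1) e1 <- eta_env$eta[, 1]
    if (est2) e2 <- eta_env$eta[, 2]
  }
  # Per-animal FD step for the eta derivatives.  One-shot evaluations
  # (no cache) refine it to ~5% of each conditional posterior's SD so
  # the curvature entering the Laplace correction is unbiased even for
  # tightly-informed animals.  Inside an optimization (cached modes)
  # the step stays fixed: refining it per call would make successive
  # objective values depend on the evaluation history, corrupting the
  # outer finite differences.
  h <- rep(.LAPLACE$h, N)
  refine_h <- is.null(eta_env)
  nref <- 0L  # post-convergence step refinements used

  if (!est1 && !est2) {
    ll <- sum(gfun(e1, e2)) - ln_sig
    if (!is.null(eta_env)) eta_env$eta <- cbind(e1, e2)
    return(if (is.finite(ll)) ll else -1e10)
  }

  # stencil offsets (scaled by h): value, +/- axial, +/- diagonal
  if (est1 && est2) {
    o1 <- c(0, 1, -1, 0, 0, 1, -1)
    o2 <- c(0, 0, 0, 1, -1, 1, -1)
  } else if (est1) {
    o1 <- c(0, 1, -1); o2 <- c(0, 0, 0)
  } else {
    o1 <- c(0, 0, 0); o2 <- c(0, 1, -1)
  }
  B <- length(o1)
  # replicated row data for the batched stencil evaluation
  timeB <- rep.int(prep$time, B); doseB <- rep.int(prep$dose, B)
  ivB <- rep.int(prep$iv, B); urineB <- rep.int(prep$urine, B)
  kaB <- rep.int(ka, B); FB <- rep.int(F, B)
  ClB <- rep.int(Cl, B); QB <- rep.int(Q, B)
  yB <- rep.int(prep$y, B); sigB <- rep.int(sig, B)
  animB <- rep.int(anim, B) + rep(seq_len(B) - 1L, each = n) * N
  endsB <- rep.int(ends, B) + rep(seq_len(B) - 1L, each = N) * n
  iom2 <- if (est1) 1 / (u$om2 * u$om2) else 0
  iom3 <- if (est2) 1 / (u$om3 * u$om3) else 0

  # batched joint evaluation over an arbitrary number of eta blocks
  .gbatch <- function(E1, E2, Kb) {
    nb <- Kb * n
    tB <- rep.int(prep$time, Kb); dB <- rep.int(prep$dose, Kb)
    vB <- rep.int(prep$iv, Kb); uB <- rep.int(prep$urine, Kb)
    aB <- rep.int(anim, Kb) + rep(seq_len(Kb) - 1L, each = n) * N
    eB <- rep.int(ends, Kb) + rep(seq_len(Kb) - 1L, each = N) * n
    V2i <- u$V2 * exp(E1)[aB]
    V3i <- if (two) u$V3 * exp(E2)[aB] else 1
    pred <- if (two)
      .pred_rows2(tB, dB, vB, uB, rep.int(ka, Kb), rep.int(F, Kb),
                  rep.int(Cl, Kb), rep.int(Q, Kb), V2i, V3i)
    else
      .pred_rows1(tB, dB, vB, uB, rep.int(ka, Kb), rep.int(F, Kb),
                  rep.int(Cl, Kb), V2i)
    r <- (rep.int(prep$y, Kb) - pred) / rep.int(sig, Kb)
    g <- .anim_sum(-0.5 * r * r, eB)
    g <- g - 0.5 * E1 * E1 * iom2 - 0.5 * E2 * E2 * iom3
    g[!is.finite(g)] <- -1e8
    g
  }

  # all stencil joints at once: a B x N matrix of per-animal values
  gsten <- function(e1, e2) {
    E1 <- rep.int(e1, B) + rep(o1, each = N) * rep.int(h, B)
    E2 <- rep.int(e2, B) + rep(o2, each = N) * rep.int(h, B)
    V2i <- u$V2 * exp(E1)[animB]
    V3i <- if (two) u$V3 * exp(E2)[animB] else 1
    pred <- if (two)
      .pred_rows2(timeB, doseB, ivB, urineB, kaB, FB, ClB, QB, V2i, V3i)
    else
      .pred_rows1(timeB, doseB, ivB, urineB, kaB, FB, ClB, V2i)
    r <- (yB - pred) / sigB
    g <- .anim_sum(-0.5 * r * r, endsB)
    g <- g - 0.5 * E1 * E1 * iom2 - 0.5 * E2 * E2 * iom3
    g[!is.finite(g)] <- -1e8
    matrix(g, N, B)
  }

  g0 <- NULL; h11 <- NULL; h22 <- NULL; h12 <- NULL
  for (it in seq_len(.LAPLACE$maxit)) {
    G <- gsten(e1, e2)
    g0 <- G[, 1]
    if (est1 && est2) {
      g1 <- (G[, 2] - G[, 3]) / (2 * h)
      g2 <- (G[, 4] - G[, 5]) / (2 * h)
      h11 <- (G[, 2] - 2 * g0 + G[, 3]) / (h * h)
      h22 <- (G[, 4] - 2 * g0 + G[, 5]) / (h * h)
      h12 <- (G[, 6] + G[, 7] - G[, 2] - G[, 3] - G[, 4] - G[, 5] +
                2 * g0) / (2 * h * h)
    } else if (est1) {
      g1 <- (G[, 2] - G[, 3]) / (2 * h)
      h11 <- (G[, 2] - 2 * g0 + G[, 3]) / (h * h)
      g2 <- numeric(N); h22 <- rep(-1, N); h12 <- numeric(N)
    } else {
      g2 <- (G[, 2] - G[, 3]) / (2 * h)
      h22 <- (G[, 2] - 2 * g0 + G[, 3]) / (h * h)
      g1 <- numeric(N); h11 <- rep(-1, N); h12 <- numeric(N)
    }
    det <- h11 * h22 - h12 * h12
    ok <- is.finite(det) & h11 < 0 & det > 0
    s1 <- numeric(N); s2 <- numeric(N)
    s1[ok] <- -(h22[ok] * g1[ok] - h12[ok] * g2[ok]) / det[ok]
    s2[ok] <- -(h11[ok] * g2[ok] - h12[ok] * g1[ok]) / det[ok]
    lr <- 1 / (1 + abs(h11) + abs(h22))
    s1[!ok] <- (g1 * lr)[!ok]
    s2[!ok] <- (g2 * lr)[!ok]
    sn <- pmax(abs(s1), abs(s2))      # cap step length
    shr <- ifelse(sn > 1, 1 / sn, 1)
    s1 <- s1 * shr; s2 <- s2 * shr
    if (!est1) s1[] <- 0
    if (!est2) s2[] <- 0

    gmax <- max(if (est1) max(abs(g1)) else 0,
                if (est2) max(abs(g2)) else 0)
    # at the mode: either the gradient is tiny, or (for very tightly
    # informed animals) the Newton step has shrunk well below the FD
    # stencil, where the coarse-step gradient hits its own bias floor
    at_mode <- gmax < .LAPLACE$tol || max(sn / h) < 1e-3
    if (at_mode) {
      if (!refine_h) break
      curv_loc <- pmax(if (est1) -h11 else -h22,
                       if (est2) -h22 else -h11, 25)
      h_new <- pmin(pmax(0.05 / sqrt(curv_loc), 1e-5), 0.02)
      if (nref >= 6L || max(abs(h_new - h) / h) < 0.2)
        break   # curvature at the mode is in hand, at the right step
      h <- h_new
      nref <- nref + 1L
      next
    }

    if (max(sn) > 1e-3) {
      # backtracking: halve steps for animals whose joint density drops
      step <- rep(1, N)
      for (ls in 1:6) {
        gn <- gfun(e1 + step * s1, e2 + step * s2)
        worse <- gn < g0 - 1e-10
        if (!any(worse)) break
        step[worse] <- step[worse] / 2
      }
      e1 <- e1 + step * s1; e2 <- e2 + step * s2
    } else {
      e1 <- e1 + s1; e2 <- e2 + s2
    }
  }

  # Integral of each animal's joint density over its random effects,
  # by mode-centred, curvature-scaled (adaptive) Gauss-Hermite
  # quadrature; nodes = 1 is exactly the Laplace approximation.  The
  # mode curvature is floored at the prior curvature: crediting an
  # animal with a conditional posterior wider than its prior would let
  # the approximation grow without bound as det(-H) approaches a fold
  # (det -> 0), planting spurious cusp optima; the exact marginal is
  # bounded by the conditional-likelihood supremum, which the floored
  # scaling respects.
  ll_anim <- g0
  gh <- .gh_nodes(nodes)
  if (est1 && est2) {
    det <- h11 * h22 - h12 * h12   # = det(-H) in even dimension
    det_prior <- 1 / (u$om2 * u$om3)^2
    det_s <- det_prior * .smooth_floor(det / det_prior)
    healthy <- is.finite(det) & h11 < 0 & det > 0
    # covariance of the scaling Gaussian, Sigma = (-H)^{-1}
    S11 <- ifelse(healthy, -h22 / det_s, u$om2^2)
    S12 <- ifelse(healthy, h12 / det_s, 0)
    S22 <- ifelse(healthy, -h11 / det_s, u$om3^2)
    if (nodes == 1) {
      ll_anim <- ll_anim + log(2 * pi) - 0.5 * log(det_s) -
        log(2 * pi * u$om2 * u$om3)
    } else {
      L11 <- sqrt(pmax(S11, 1e-12))
      L21 <- S12 / L11
      L22 <- sqrt(pmax(S22 - L21 * L21, 1e-12))
      # all nodes in one batched evaluation
      K2 <- nodes * nodes
      xi <- rep(gh$x, each = nodes)    # node index i varies slowly
      xj <- rep(gh$x, nodes)
      E1 <- rep.int(e1, K2) + sqrt(2) * rep.int(L11, K2) * rep(xi, each = N)
      E2 <- rep.int(e2, K2) +
        sqrt(2) * (rep.int(L21, K2) * rep(xi, each = N) +
                     rep.int(L22, K2) * rep(xj, each = N))
      G2 <- matrix(.gbatch(E1, E2, K2), N, K2)
      lw2 <- rep(gh$lwx, each = nodes) + rep(gh$lwx, nodes)
      S <- as.numeric(exp(pmin(G2 - g0, 50)) %*% exp(lw2))
      ll_anim <- ll_anim + log(2) + log(L11 * L22) + log(S) -
        log(2 * pi * u$om2 * u$om3)
    }
  } else {
    om <- if (est1) u$om2 else u$om3
    hxx <- if (est1) h11 else h22
    iom <- 1 / (om * om)
    curv <- iom * .smooth_floor(-hxx / iom)
    if (nodes == 1) {
      ll_anim <- ll_anim - log(om) - 0.5 * log(curv)
    } else {
      sdv <- sqrt(1 / curv)
      shift <- sqrt(2) * rep.int(sdv, nodes) * rep(gh$x, each = N)
      E1 <- rep.int(e1, nodes) + if (est1) shift else 0
      E2 <- rep.int(e2, nodes) + if (est2) shift else 0
      G1 <- matrix(.gbatch(E1, E2, nodes), N, nodes)
      S <- as.numeric(exp(pmin(G1 - g0, 50)) %*% exp(gh$lwx))
      ll_anim <- ll_anim + 0.5 * log(2) + log(sdv) + log(S) -
        0.5 * log(2 * pi) - log(om)
    }
  }

  if (!is.null(eta_env)) eta_env$eta <- cbind(e1, e2)
  ll <- sum(ll_anim) - ln_sig
  if (is.finite(ll)) ll else -1e10
}

#' Marginal log-likelihood of the mixed-effects model
#'
#' Evaluates the Laplace-approximated marginal log-likelihood of a
#' study dataset at the given population parameters: per animal the
#' volume random effects are integrated out around their conditional
#' mode.  When both `omega` components are zero the random effects drop
#' out and the value is the exact independent-Gaussian log-likelihood
#' of the residuals.
#'
#' @param data a study dataset (see [validate_pk_dataset()]); raw `DV`
#'   values are corrected by `EFF` internally.  Pre-dose (t = 0) plasma
#'   rows do not contribute.
#' @param theta control-group typical values, a [pk_params()] object.
#' @param ratios radiation-group ratios, a [radiation_effect()] object
#'   (default: no effect).
#' @param omega named SDs `c(V2 = , V3 = )` of the log-normal volume
#'   random effects.
#' @param sigma named additive residual SDs `c(plasma = , urine = )`.
#' @param model `"two_cpt"` or `"one_cpt"`.
#' @param nodes number of adaptive Gauss-Hermite nodes per random
#'   effect used to integrate each animal's marginal; `1` (the
#'   default) is exactly the Laplace approximation at the conditional
#'   mode, larger odd values refine it.
#' @return The marginal log-likelihood (a single number).
#' @export
pk_loglik <- function(data, theta, ratios = radiation_effect(),
                      omega = c(V2 = 0, V3 = 0),
                      sigma = c(plasma = 1, urine = 1),
                      model = c("two_cpt", "one_cpt"), nodes = 1) {
  model <- match.arg(model)
  stopifnot(inherits(theta, "pk_params"), inherits(ratios, "radiation_effect"))
  if (any(sigma <= 0)) stop("'sigma' components must be > 0", call. = FALSE)
  if (any(omega < 0)) stop("'omega' components must be >= 0", call. = FALSE)
  prep <- .prep_fit_data(data)
  u <- list(ka = theta$ka, F = theta$F, Cl = theta$Cl, Q = theta$Q,
            V2 = theta$V2, V3 = theta$V3,
            r_ka = ratios$ka, r_Cl = ratios$Cl, r_Q = ratios$Q,
            r_F = ratios$F,
            om2 = unname(omega[["V2"]]),
            om3 = if (model == "two_cpt") unname(omega[["V3"]]) else 0,
            sp = unname(sigma[["plasma"]]), su = unname(sigma[["urine"]]))
  .marginal_ll(u, prep, model, nodes = nodes)
}
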
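# Mixed-effects fitting front end and S3 methods.

#' Control options for [pk_fit()]
#'
#' @param rel_tol relative tolerance on the objective for the outer
#'   optimizer.
#' @param iter_max,eval_max outer optimizer iteration/evaluation caps.
#' @param restarts number of jittered restarts attempted when the
#'   optimizer fails to converge (jitter SD 0.2 on the estimation
#'   scale, drawn from a private RNG stream).
#' @param restart_seed seed of the private restart-jitter stream.
#' @param rounds maximum saddle-escape rounds per optimization attempt
#'   (each round re-runs the line-search optimizer after descending
#'   along a negative-curvature direction).
#' @param nodes adaptive Gauss-Hermite nodes per random effect in the
#'   marginal-likelihood integration; `1` is the pure Laplace
#'   approximation, the default `3` refines it at modest cost (see the
#'   package vignette for the calibration evidence behind this
#'   default).
#' @param hessian compute the Hessian of the negative log-likelihood at
#'   the optimum (needed for standard errors, CIs and p-values)?
#' @param polish apply damped Newton polishing steps on the computed
#'   Hessian after the quasi-Newton optimizer stops, to localize the
#'   optimum relative to the Wald standard errors.
#' @param trace print optimizer progress?
#' @return A list of class `"pk_control"`.
#' @export
pk_control <- function(rel_tol = 1e-8, iter_max = 500, eval_max = 4000,
                       restarts = 3, restart_seed = 20260924, nodes = 3,
                       rounds = 5, hessian = TRUE, polish = TRUE,
                       trace = 0) {
  structure(list(rel_tol = rel_tol, iter_max = iter_max,
                 eval_max = eval_max, restarts = restarts,
                 restart_seed = restart_seed, nodes = nodes,
                 rounds = rounds, hessian = hessian, polish = polish,
                 trace = trace),
            class = "pk_control")
}

#' Heuristic starting values from a non-compartmental look at the data
#'
#' Rough initial estimates: `V2` from back-extrapolation of the first
#' IV concentration, `Cl` from IV dose over trapezoidal AUC, `F` from
#' the gavage/IV urinary recovery ratio, `ka` from the time of the
#' gavage concentration peak, and fixed fallbacks wherever an arm is
#' missing.  Residual SDs start at 20% of each compartment's median
#' absolute value; both omegas start at 0.3; all ratios start at 1.
#'
#' @param data a study dataset.
#' @return A list with components `theta`, `ratios`, `omega`, `sigma`
#'   suitable as the `init` argument of [pk_fit()].
#' @export
pk_init <- function(data) {
  .assert_pk_dataset(data)
  y <- correct_extraction(data$DV, data$EFF)
  dose <- dose_to_umol(data$DOSE_UG)
  pl <- data$CMT == "plasma" & data$TIME > 0 & dose > 0
  ur <- data$CMT == "urine" & dose > 0
  ivp <- pl & data$ROUTE == "iv"
  gvp <- pl & data$ROUTE == "gavage"

  # fixed fallbacks, order-of-magnitude generic for a small rodent
  V2 <- 0.02; Cl <- 0.02; ka <- 0.5; F <- 0.3

  if (any(ivp)) {
    t1 <- min(data$TIME[ivp])
    first <- ivp & data$TIME == t1
    c0 <- median(y[first] / dose[first])
    if (is.finite(c0) && c0 > 0) V2 <- 1 / c0
    prof <- stats::aggregate(y[ivp] / dose[ivp],
                             by = list(time = data$TIME[ivp]), FUN = mean)
    if (nrow(prof) >= 2) {
      auc <- sum(diff(prof$time) * (head(prof$x, -1) + prof$x[-1]) / 2)
      if (auc > 0) Cl <- 1 / auc
    }
  }
  if (any(gvp)) {
    prof <- stats::aggregate(y[gvp] / dose[gvp],
                             by = list(time = data$TIME[gvp]), FUN = mean)
    tmax <- prof$time[which.max(prof$x)]
    if (is.finite(tmax) && tmax > 0) ka <- min(max(1 / tmax, 0.05), 20)
  }
  if (any(ur)) {
    frac <- y[ur] / dose[ur]
    fg <- mean(frac[data$ROUTE[ur] == "gavage"])
    fi <- mean(frac[data$ROUTE[ur] == "iv"])
    if (is.finite(fg) && is.finite(fi) && fi > 0 && fg > 0)
      F <- min(max(fg / fi, 0.02), 0.95)
  }
  sp <- 0.2 * max(median(abs(y[pl])), 1e-3)
  su <- if (any(ur)) 0.2 * max(median(abs(y[ur])), 1e-4) else sp
  list(theta = pk_params(ka = ka, F = F, Cl = Cl, Q = Cl,
                         V2 = V2, V3 = 20 * V2),
       ratios = radiation_effect(),
       omega = c(V2 = 0.3, V3 = 0.3),
       sigma = c(plasma = sp, urine = su))
}

#' Fit the mixed-effects two-compartment model
#'
#' Maximizes the Laplace-approximated marginal likelihood (see
#' [pk_loglik()]) over the control-group typical parameters, the
#' radiation-group multiplicative ratios, the volume random-effect SDs
#' and the compartment residual SDs.  Positive parameters are estimated
#' on the log scale, bioavailability on the logit scale and radiation
#' effects as log-ratios; Wald confidence intervals and tests are
#' formed on that scale and back-transformed.
#'
#' Bioavailability is only separable from the absorption rate because
#' the design contains an intravenous arm and urinary recovery;
#' datasets lacking either trigger a weak-identifiability warning.
#'
#' @param data a study dataset (schema of [validate_pk_dataset()]);
#'   raw `DV` values are corrected for extraction efficiency
#'   internally.
#' @param init optional list with components `theta` ([pk_params()]),
#'   `ratios` ([radiation_effect()]), `omega`, `sigma`; defaults to
#'   [pk_init()] heuristics.
#' @param model `"two_cpt"` (default) or the nested `"one_cpt"`
#'   reduction (no peripheral compartment: `Q`, `V3`, their ratio and
#'   `omega_V3` removed).
#' @param control a [pk_control()] list.
#' @return An object of class `"pkfit"`; see [summary.pkfit()],
#'   [coef.pkfit()], [predict.pkfit()], [anova.pkfit()],
#'   [r_squared()].
#' @examples
#' \donttest{
#' cfg <- sim_config(design = scale_design(study_design(), 0.25))
#' fit <- pk_fit(simulate_study(cfg, seed = 42))
#' summary(fit)
#' }
#' @export
pk_fit <- function(data, init = NULL, model = c("two_cpt", "one_cpt"),
                   control = pk_control()) {
  model <- match.arg(model)
  stopifnot(inherits(control, "pk_control"))
  prep <- .prep_fit_data(data)
  if (prep$n_anim < 2)
    stop("at least two animals are required to identify the model",
         call. = FALSE)
  if (!any(prep$iv))
    warning("no intravenous records: bioavailability and absorption are ",
            "weakly identifiable", call. = FALSE)
  if (!any(prep$urine))
    warning("no urine records: bioavailability and clearance are weakly ",
            "identifiable", call. = FALSE)
  has_irr <- any(prep$irr)

  if (is.null(init)) init <- pk_init(data)
  start <- .pack_par(init$theta, init$ratios, init$omega, init$sigma, model)
  pn <- .par_names(model)
  ratio_idx <- grep("^lr\\.", pn)

  eta_env <- new.env(parent = emptyenv())
  nll <- function(par) {
    u <- .unpack_par(par, model)
    if (!has_irr) { u$r_ka <- 1; u$r_Cl <- 1; u$r_Q <- 1; u$r_F <- 1 }
    v <- -.marginal_ll(u, prep, model, eta_env, nodes = control$nodes)
    if (!is.finite(v)) 1e10 else v
  }

  fixed <- if (!has_irr) ratio_idx else integer(0)
  free <- setdiff(seq_along(start), fixed)
  obj <- function(pf) {
    par <- start
    par[free] <- pf
    nll(par)
  }
  grad <- function(pf) {
    h <- 1e-5 * pmax(abs(pf), 1)
    vapply(seq_along(pf), function(i) {
      e <- numeric(length(pf)); e[i] <- h[i]
      (obj(pf + e) - obj(pf - e)) / (2 * h[i])
    }, 0)
  }
  # cheaper forward-difference gradient for the line-search phase; the
  # Newton polish below uses the central version
  grad_fwd <- function(pf) {
    f0 <- obj(pf)
    h <- 1e-6 * pmax(abs(pf), 1)
    vapply(seq_along(pf), function(i) {
      e <- numeric(length(pf)); e[i] <- h[i]
      (obj(pf + e) - f0) / h[i]
    }, 0)
  }

  # conditioning: the objective's curvature spans many orders of
  # magnitude across parameters; a pilot diagonal curvature at the
  # start provides per-parameter scales that keep the quasi-Newton
  # iteration well conditioned
  par_scale <- local({
    f0 <- obj(start[free])
    curv <- vapply(seq_along(free), function(i) {
      e <- numeric(length(free)); e[i] <- 0.01
      abs(obj(start[free] + e) - 2 * f0 + obj(start[free] - e)) / 1e-4
    }, 0)
    curv[!is.finite(curv)] <- 1
    sqrt(pmax(pmin(curv, 1e12), 1))
  })
  run_nlminb <- function(st) nlminb(st, obj, gradient = grad_fwd,
                                    scale = par_scale,
                                    control = list(rel.tol = control$rel_tol,
                                                   iter.max = control$iter_max,
                                                   eval.max = control$eval_max,
                                                   trace = control$trace))

  # One full attempt from a starting point.  The line-search optimizer
  # routinely halts on saddle points of this objective (flat ridges in
  # the ratio/variance directions); each round therefore checks the
  # eigenvalues of the Hessian at the halt point, and when a negative
  # curvature direction exists, descends along it and re-runs the line
  # search.  At a genuine minimum, damped Newton polishing localizes
  # the optimum relative to the Wald standard errors; convergence is
  # declared when the Newton step is below a tenth of every SE.
  attempt_fit <- function(st) {
    o <- NULL
    for (round in seq_len(control$rounds)) {
      o <- run_nlminb(st)
      o$vc <- NULL; o$reldelta <- Inf; o$converged <- FALSE
      H <- .fd_hessian(obj, o$par)
      eg <- eigen((H + t(H)) / 2, symmetric = TRUE)
      lmax <- max(eg$values)
      # eigenvalues within ~1e-6 of the stiffest direction are flat
      # (or finite-difference wobble), not genuine negative curvature;
      # clamp them for the pseudo-inverse instead of chasing a saddle
      if (all(is.finite(eg$values)) && lmax > 0 &&
          min(eg$values) > -1e-6 * lmax) {
        # polish and measure convergence only along identified
        # (non-flat) eigendirections; the Newton step along direction
        # k is -g_k / lambda_k and the standard error 1 / sqrt(lambda_k),
        # so their ratio is |g_k| / sqrt(lambda_k).  The gradient is
        # measured by central differences at steps proportional to the
        # standard errors: the per-animal mode approximations imprint
        # small-scale wiggle on the objective, and only the slope of
        # the broad quadratic is statistically meaningful.
        vdiag <- as.numeric((eg$vectors^2) %*%
                              (1 / pmax(eg$values, 1e-7 * lmax)))
        hb <- pmin(pmax(0.3 * sqrt(vdiag), 1e-5), 0.3)
        grad_b <- function(par) {
          vapply(seq_along(par), function(i) {
            e <- numeric(length(par)); e[i] <- hb[i]
            (obj(par + e) - obj(par - e)) / (2 * hb[i])
          }, 0)
        }
        newton <- function(par) {
          gk <- as.numeric(crossprod(eg$vectors, grad_b(par)))
          keep <- eg$values > 1e-6 * lmax
          list(reldelta = max(abs(gk[keep]) / sqrt(eg$values[keep])),
               delta = -as.numeric(eg$vectors[, keep, drop = FALSE] %*%
                                     (gk[keep] / eg$values[keep])))
        }
        moved <- FALSE
        for (k in seq_len(10)) {        # Newton polish
          nw <- newton(o$par)
          o$reldelta <- nw$reldelta
          if (!is.finite(o$reldelta) || o$reldelta < 0.05) break
          if (!control$polish) break
          accepted <- FALSE
          for (damp in c(1, 0.5, 0.25)) {
            cand <- o$par + damp * nw$delta
            fc <- obj(cand)
            if (fc < o$objective) {
              o$par <- cand; o$objective <- fc
              accepted <- TRUE; moved <- TRUE
              break
            }
          }
          if (!accepted) break
        }
        if (moved && control$hessian) {
          # the optimum moved during polishing; refresh the SEs once
          H2 <- .fd_hessian(obj, o$par)
          eg2 <- eigen((H2 + t(H2)) / 2, symmetric = TRUE)
          lmax2 <- max(eg2$values)
          if (all(is.finite(eg2$values)) && lmax2 > 0 &&
              min(eg2$values) > -1e-6 * lmax2) {
            eg <- eg2
            lmax <- lmax2
          }
          o$reldelta <- newton(o$par)$reldelta
        }
        o$vc <- eg$vectors %*% (t(eg$vectors) / pmax(eg$values,
                                                     1e-7 * lmax))
        o$converged <- is.finite(o$reldelta) && o$reldelta < 0.1
        break
      }
      # saddle: line search along the most negative curvature direction
      v <- eg$vectors[, which.min(eg$values)]
      cand <- expand.grid(sgn = c(1, -1), t = c(0.03, 0.1, 0.3, 1, 3))
      fbest <- o$objective; stbest <- NULL
      for (i in seq_len(nrow(cand))) {
        p2 <- o$par + cand$sgn[i] * cand$t[i] * v
        f2 <- obj(p2)
        if (f2 < fbest - 1e-9) { fbest <- f2; stbest <- p2 }
      }
      if (is.null(stbest)) break  # no descent found: report as-is
      st <- stbest
    }
    o
  }

  opt <- attempt_fit(start[free])
  attempt <- 0
  while (!opt$converged && attempt < control$restarts) {
    attempt <- attempt + 1
    jit <- .with_seed(control$restart_seed + attempt,
                      rnorm(length(free), 0, 0.2))
    opt2 <- attempt_fit(start[free] + jit)
    if (opt2$objective < opt$objective || opt2$converged) opt <- opt2
    if (opt$converged) break
  }
  convergence <- if (opt$converged) 0L else 1L
  vc <- opt$vc
  if (!is.null(vc)) dimnames(vc) <- list(pn[free], pn[free])

  par <- start
  par[free] <- opt$par
  u <- .unpack_par(par, model)
  loglik <- -opt$objective

  # final conditional modes and predictions for every record
  eta <- if (!is.null(eta_env$eta)) eta_env$eta else
    matrix(0, prep$n_anim, 2)
  dimnames(eta) <- list(prep$anim_ids, c("V2", "V3"))
  preds <- .pkfit_predictions(u, prep, model, eta)

  theta <- pk_params(ka = u$ka, F = u$F, Cl = u$Cl,
                     Q = if (model == "two_cpt") u$Q else 0,
                     V2 = u$V2, V3 = if (model == "two_cpt") u$V3 else 1)
  structure(list(
    call = match.call(),
    model = model,
    coefficients = par,
    free = free,
    theta = theta,
    ratios = radiation_effect(ka = u$r_ka, Cl = u$r_Cl, Q = u$r_Q,
                              F = u$r_F),
    omega = c(V2 = u$om2, V3 = u$om3),
    sigma = c(plasma = u$sp, urine = u$su),
    logLik = loglik,
    vcov = vc,
    eta = eta,
    predictions = preds,
    data = data,
    prep = prep,
    convergence = convergence,
    message = opt$message,
    iterations = opt$iterations,
    restarts_used = attempt,
    has_irr = has_irr,
    init = init,
    control = control),
    class = "pkfit")
}

# Central-difference Hessian with per-coordinate adaptive steps.
# Curvatures of the marginal likelihood span several orders of
# magnitude across parameters (stiff structural directions versus
# nearly flat variance components), so a fixed step either truncates
# the stiff directions or drowns the flat ones in rounding noise.  A
# pilot pass estimates each diagonal curvature at a moderate step,
# then every step is rescaled so its second-difference numerator is
# of order one: far above both the objective's rounding noise and the
# small-scale wiggle that mode-centred per-animal approximations
# imprint on the marginal likelihood (sampling curvature below that
# scale corrupts the cross-terms).
.fd_hessian <- function(f, x, target = 1) {
  n <- length(x)
  f0 <- f(x)
  pilot <- 1e-2 * pmax(abs(x), 1)
  curv <- numeric(n)
  for (i in seq_len(n)) {
    ei <- numeric(n); ei[i] <- pilot[i]
    curv[i] <- abs((f(x + ei) - 2 * f0 + f(x - ei))) / pilot[i]^2
  }
  hi <- sqrt(target / pmax(curv, 1e-4))
  hi <- pmin(pmax(hi, 1e-4), 0.3)
  H <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    ei <- numeric(n); ei[i] <- hi[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / hi[i]^2
    if (i < n) for (j in seq((i + 1), n)) {
      ej <- numeric(n); ej[j] <- hi[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * hi[i] * hi[j])
    }
  }
  H
}

# population (eta = 0) and individual (eta = conditional mode)
# predictions for every record of the dataset
.pkfit_predictions <- function(u, prep, model, eta) {
  d <- prep$all
  two <- model == "two_cpt"
  rowpred <- function(V2i, V3i) {
    ka <- u$ka * ifelse(d$.irr, u$r_ka, 1)
    F  <- u$F * ifelse(d$.irr, u$r_F, 1)
    Cl <- u$Cl * ifelse(d$.irr, u$r_Cl, 1)
    Q  <- u$Q * ifelse(d$.irr, u$r_Q, 1)
    p <- if (two)
      .pred_rows2(d$TIME, d$.dose, d$.iv, d$.urine, ka, F, Cl, Q, V2i, V3i)
    else
      .pred_rows1(d$TIME, d$.dose, d$.iv, d$.urine, ka, F, Cl, V2i)
    p[!d$.urine & d$TIME <= 0] <- 0
    p
  }
  n <- nrow(d)
  pop <- rowpred(rep(u$V2, n), rep(if (two) u$V3 else 1, n))
  idx <- match(d$ID, rownames(eta))
  e1 <- ifelse(is.na(idx), 0, eta[idx, 1])
  e2 <- ifelse(is.na(idx), 0, eta[idx, 2])
  ind <- rowpred(u$V2 * exp(e1), (if (two) u$V3 else 1) * exp(if (two) e2 else 0))
  in_lik <- seq_len(n) %in% prep$lik_row
  data.frame(population = pop, individual = ind, in_likelihood = in_lik)
}
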
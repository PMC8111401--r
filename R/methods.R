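# S3 methods for "pkfit" objects.

# map from transformed coefficient names to natural-scale names and
# back-transforms
.coef_map <- function(model) {
  pn <- .par_names(model)
  nat <- c(lka = "ka", logitF = "F", lCl = "Cl", lQ = "Q", lV2 = "V2",
           lV3 = "V3", lr.ka = "ratio.ka", lr.Cl = "ratio.Cl",
           lr.Q = "ratio.Q", lr.F = "ratio.F",
           lomega.V2 = "omega.V2", lomega.V3 = "omega.V3",
           lsigma.plasma = "sigma.plasma", lsigma.urine = "sigma.urine")
  nat[pn]
}

.backtrans <- function(name, x) if (name == "logitF") plogis(x) else exp(x)

#' Extract natural-scale coefficients from a model fit
#'
#' @param object a `pkfit` object.
#' @param ... unused.
#' @return Named numeric vector on the natural scale: structural
#'   parameters, radiation ratios, random-effect SDs and residual SDs.
#' @export
coef.pkfit <- function(object, ...) {
  co <- object$coefficients
  nat <- .coef_map(object$model)
  setNames(vapply(seq_along(co),
                  function(i) .backtrans(names(co)[i], co[i]), 0),
           unname(nat))
}

#' @export
logLik.pkfit <- function(object, ...) {
  structure(object$logLik, df = length(object$free),
            nobs = length(object$prep$y), class = "logLik")
}

#' @export
vcov.pkfit <- function(object, ...) object$vcov

#' Wald confidence intervals on the natural scale
#'
#' Intervals are computed on the estimation scale (log, or logit for
#' bioavailability) and back-transformed.
#'
#' @param object a `pkfit` object.
#' @param parm optional subset of natural-scale coefficient names.
#' @param level confidence level.
#' @param ... unused.
#' @return Matrix with columns `lwr`, `upr`.
#' @export
confint.pkfit <- function(object, parm = NULL, level = 0.95, ...) {
  if (is.null(object$vcov))
    stop("no variance-covariance matrix available (refit with hessian = TRUE)",
         call. = FALSE)
  co <- object$coefficients
  nat <- .coef_map(object$model)
  se <- setNames(rep(NA_real_, length(co)), names(co))
  se[rownames(object$vcov)] <- sqrt(diag(object$vcov))
  z <- qnorm(1 - (1 - level) / 2)
  out <- t(vapply(seq_along(co), function(i) {
    nm <- names(co)[i]
    c(.backtrans(nm, co[i] - z * se[nm]), .backtrans(nm, co[i] + z * se[nm]))
  }, numeric(2)))
  dimnames(out) <- list(unname(nat), c("lwr", "upr"))
  if (!is.null(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Summarize a mixed-effects PK fit
#'
#' Produces the two headline tables of the analysis: control-group
#' typical parameter estimates with 95% Wald intervals, and
#' radiation-group multiplicative ratios with intervals and p-values
#' for the Wald test of each log-ratio against 0 (ratio = 1, no
#' radiation effect).
#'
#' @param object a `pkfit` object.
#' @param level confidence level for the intervals.
#' @param ... unused.
#' @return An object of class `"summary.pkfit"` with components
#'   `base` (data frame), `ratios` (data frame), `variance`
#'   (random-effect/residual SDs), `logLik`, `r_squared`,
#'   `convergence`.
#' @export
summary.pkfit <- function(object, level = 0.95, ...) {
  ci <- if (!is.null(object$vcov)) confint(object, level = level) else NULL
  co <- coef(object)
  units <- c(ka = "1/hr", F = "scalar", Cl = "L/hr", Q = "L/hr",
             V2 = "L", V3 = "L")
  base_nm <- intersect(c("ka", "F", "Cl", "Q", "V2", "V3"), names(co))
  base <- data.frame(parameter = base_nm, estimate = co[base_nm],
                     lwr = if (is.null(ci)) NA else ci[base_nm, "lwr"],
                     upr = if (is.null(ci)) NA else ci[base_nm, "upr"],
                     units = units[base_nm], row.names = NULL)

  ratios <- NULL
  if (object$has_irr) {
    rnm <- grep("^ratio\\.", names(co), value = TRUE)
    tn <- names(object$coefficients)[match(rnm, unname(.coef_map(object$model)))]
    se <- if (!is.null(object$vcov))
      sqrt(diag(object$vcov))[tn] else rep(NA_real_, length(tn))
    z <- object$coefficients[tn] / se
    ratios <- data.frame(parameter = rnm, estimate = co[rnm],
                         lwr = if (is.null(ci)) NA else ci[rnm, "lwr"],
                         upr = if (is.null(ci)) NA else ci[rnm, "upr"],
                         p_value = 2 * pnorm(-abs(z)), row.names = NULL)
  }
  structure(list(call = object$call, model = object$model, base = base,
                 ratios = ratios,
                 variance = c(object$omega[
                   if (object$model == "two_cpt") c("V2", "V3") else "V2"],
                   object$sigma),
                 logLik = object$logLik,
                 r_squared = r_squared(object),
                 convergence = object$convergence,
                 n_animals = object$prep$n_anim,
                 n_obs = length(object$prep$y)),
            class = "summary.pkfit")
}

#' @export
print.summary.pkfit <- function(x, digits = 3, ...) {
  cat(sprintf("%s mixed-effects fit: %d observations, %d animals\n",
              if (x$model == "two_cpt") "Two-compartment" else "One-compartment",
              x$n_obs, x$n_animals))
  cat(sprintf("log-likelihood %.3f; R2 = %.1f%%; convergence code %d\n\n",
              x$logLik, 100 * x$r_squared, x$convergence))
  cat("Base parameter estimates (control group):\n")
  xb <- x$base; xb[2:4] <- lapply(xb[2:4], signif, digits)
  print(xb, row.names = FALSE)
  if (!is.null(x$ratios)) {
    cat("\nRadiation-group parameter ratios (irradiated / control):\n")
    xr <- x$ratios
    xr[2:4] <- lapply(xr[2:4], signif, digits)
    xr$p_value <- format.pval(xr$p_value, digits = 2)
    print(xr, row.names = FALSE)
  }
  cat("\nVariance components (SDs):\n")
  print(signif(x$variance, digits))
  invisible(x)
}

#' @export
print.pkfit <- function(x, digits = 3, ...) {
  cat(sprintf("%s mixed-effects PK fit (logLik %.2f, convergence %d)\n",
              if (x$model == "two_cpt") "Two-compartment" else "One-compartment",
              x$logLik, x$convergence))
  print(signif(coef(x), digits))
  invisible(x)
}

#' Predictions from a fitted model
#'
#' @param object a `pkfit` object.
#' @param newdata optional study dataset; when given, only population
#'   predictions (random effects at zero) are returned.  By default the
#'   fitted dataset is used and both population and individual
#'   (conditional-mode) predictions are available.
#' @param level `"individual"` or `"population"`.
#' @param ... unused.
#' @return Numeric vector of predictions, one per record: plasma
#'   concentration (umol/L) or cumulative urine amount (umol).
#' @export
predict.pkfit <- function(object, newdata = NULL,
                          level = c("individual", "population"), ...) {
  level <- match.arg(level)
  if (is.null(newdata))
    return(object$predictions[[level]])
  if (level == "individual")
    stop("individual predictions are only defined for the fitted dataset",
         call. = FALSE)
  .assert_pk_dataset(newdata)
  d <- newdata
  u <- .unpack_par(object$coefficients, object$model)
  irr <- d$GROUP == "irradiated"
  iv <- d$ROUTE == "iv"
  urine <- d$CMT == "urine"
  dose <- dose_to_umol(d$DOSE_UG)
  n <- nrow(d)
  two <- object$model == "two_cpt"
  p <- if (two)
    .pred_rows2(d$TIME, dose, iv, urine,
                u$ka * ifelse(irr, u$r_ka, 1), u$F * ifelse(irr, u$r_F, 1),
                u$Cl * ifelse(irr, u$r_Cl, 1), u$Q * ifelse(irr, u$r_Q, 1),
                rep(u$V2, n), rep(u$V3, n))
  else
    .pred_rows1(d$TIME, dose, iv, urine,
                u$ka * ifelse(irr, u$r_ka, 1), u$F * ifelse(irr, u$r_F, 1),
                u$Cl * ifelse(irr, u$r_Cl, 1), rep(u$V2, n))
  p[!urine & d$TIME <= 0] <- 0
  p
}

#' @export
fitted.pkfit <- function(object, ...) object$predictions$individual

#' Residuals of a fitted model
#'
#' Efficiency-corrected observed values minus predictions.
#'
#' @param object a `pkfit` object.
#' @param level `"individual"` (conditional-mode) or `"population"`.
#' @param ... unused.
#' @return Numeric vector, one element per record of the fitted
#'   dataset.
#' @export
residuals.pkfit <- function(object, level = c("individual", "population"),
                            ...) {
  level <- match.arg(level)
  correct_extraction(object$data$DV, object$data$EFF) -
    object$predictions[[level]]
}

#' Pooled goodness-of-fit of a mixed-effects PK fit
#'
#' `1 - SS_res / SS_tot` of observed versus individual-predicted
#' values, pooled over the plasma and urine records that entered the
#' likelihood, with each compartment standardized by its fitted
#' residual SD so the two measurement scales are comparable.
#'
#' @param fit a `pkfit` object.
#' @return A fraction (can be negative for a fit worse than the mean).
#' @export
r_squared <- function(fit) {
  stopifnot(inherits(fit, "pkfit"))
  keep <- fit$predictions$in_likelihood
  obs <- correct_extraction(fit$data$DV, fit$data$EFF)[keep]
  pred <- fit$predictions$individual[keep]
  urine <- (fit$data$CMT == "urine")[keep]
  sc <- ifelse(urine, fit$sigma[["urine"]], fit$sigma[["plasma"]])
  zo <- obs / sc; zp <- pred / sc
  sst <- sum((zo - mean(zo))^2)
  if (sst == 0)
    stop("total variance of the standardized observations is zero; ",
         "R-squared is undefined", call. = FALSE)
  1 - sum((zo - zp)^2) / sst
}

#' Likelihood-ratio comparison of nested compartmental fits
#'
#' Compares two fits of the same dataset (typically the one-compartment
#' reduction against the full two-compartment model) by the
#' likelihood-ratio chi-square test.
#'
#' @param object,... two `pkfit` objects (in either order).
#' @return A data frame of class `"anova"` with log-likelihoods,
#'   degrees of freedom, the LRT statistic and its chi-square p-value.
#' @export
anova.pkfit <- function(object, ...) {
  fits <- c(list(object), list(...))
  fits <- Filter(function(x) inherits(x, "pkfit"), fits)
  if (length(fits) != 2)
    stop("supply exactly two pkfit objects to compare", call. = FALSE)
  df <- vapply(fits, function(f) length(f$free), 0L)
  ord <- order(df)
  fits <- fits[ord]; df <- df[ord]
  if (df[1] == df[2])
    stop("models have the same number of parameters; not nested", call. = FALSE)
  ll <- vapply(fits, function(f) f$logLik, 0)
  stat <- 2 * (ll[2] - ll[1])
  if (stat < -1e-6)
    warning("the larger model has a lower log-likelihood: an optimization ",
            "failure in one of the fits", call. = FALSE)
  stat <- max(stat, 0)
  df_diff <- df[2] - df[1]
  out <- data.frame(
    model = vapply(fits, function(f) f$model, ""),
    df = df, logLik = ll,
    LRT = c(NA, stat), df_diff = c(NA, df_diff),
    p_value = c(NA, pchisq(stat, df_diff, lower.tail = FALSE)))
  structure(out, class = c("anova", "data.frame"),
            heading = "Likelihood ratio test of nested compartmental models")
}

#' Simulate response data from a fitted model
#'
#' Re-simulates the `DV` column of the fitted dataset at the estimated
#' parameters: fresh volume random effects per animal and fresh
#' additive residual noise per record, under the original design
#' (same animals, routes, doses and times).
#'
#' @param object a `pkfit` object.
#' @param nsim number of replicate datasets.
#' @param seed optional integer seed (caller's RNG state is preserved).
#' @param ... unused.
#' @return A list of `nsim` study datasets.
#' @export
simulate.pkfit <- function(object, nsim = 1, seed = NULL, ...) {
  d <- object$data
  u <- .unpack_par(object$coefficients, object$model)
  two <- object$model == "two_cpt"
  ids <- unique(d$ID)
  irr <- d$GROUP == "irradiated"
  iv <- d$ROUTE == "iv"
  urine <- d$CMT == "urine"
  dose <- dose_to_umol(d$DOSE_UG)
  ka <- u$ka * ifelse(irr, u$r_ka, 1); F <- u$F * ifelse(irr, u$r_F, 1)
  Cl <- u$Cl * ifelse(irr, u$r_Cl, 1); Q <- u$Q * ifelse(irr, u$r_Q, 1)
  sig <- ifelse(urine, u$su, u$sp)
  .with_seed(seed, {
    lapply(seq_len(nsim), function(k) {
      e1 <- rnorm(length(ids), 0, u$om2)[match(d$ID, ids)]
      e2 <- rnorm(length(ids), 0, u$om3)[match(d$ID, ids)]
      V2i <- u$V2 * exp(e1)
      pred <- if (two)
        .pred_rows2(d$TIME, dose, iv, urine, ka, F, Cl, Q, V2i,
                    u$V3 * exp(e2))
      else
        .pred_rows1(d$TIME, dose, iv, urine, ka, F, Cl, V2i)
      dv <- pred + rnorm(nrow(d), 0, sig)
      dv[!urine & d$TIME <= 0] <- 0
      out <- d
      out$DV <- dv * d$EFF
      out
    })
  })
}

#' Observed-versus-predicted diagnostic plot
#'
#' @param x a `pkfit` object.
#' @param level `"individual"` or `"population"` predictions.
#' @param ... passed to [plot()].
#' @return Invisibly, `x`.
#' @export
plot.pkfit <- function(x, level = c("individual", "population"), ...) {
  level <- match.arg(level)
  keep <- x$predictions$in_likelihood
  obs <- correct_extraction(x$data$DV, x$data$EFF)[keep]
  pred <- x$predictions[[level]][keep]
  urine <- (x$data$CMT == "urine")[keep]
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  for (u in c(FALSE, TRUE)) {
    sel <- urine == u
    plot(pred[sel], obs[sel],
         xlab = sprintf("predicted (%s)", level), ylab = "observed",
         main = if (u) "urine (umol)" else "plasma (umol/L)", ...)
    abline(0, 1, lty = 2)
  }
  invisible(x)
}
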
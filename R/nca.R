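# Non-compartmental analysis for the sparse batch design.
#
# Each animal contributes plasma samples at only a few of the scheduled
# times (a batch / serial-sacrifice layout), so the AUC is estimated by
# the linear trapezoidal rule applied to the arithmetic per-time means
# of dose-normalized concentrations, and uncertainty is assessed by a
# bootstrap-t that resamples animals within each time-point batch.

#' Dose-normalize concentration values
#'
#' Scales efficiency-corrected values to a common reference dose
#' (default 300 ug): `value * reference / dose`.
#'
#' @param data a study dataset.
#' @param reference_dose_ug reference dose in micrograms.
#' @return The dataset with `DV` replaced by the corrected,
#'   dose-normalized value and `EFF` reset to 1.
#' @export
nca_normalize <- function(data, reference_dose_ug = 300) {
  .assert_pk_dataset(data)
  if (any(data$DOSE_UG <= 0))
    stop("dose normalization requires a positive dose for every record",
         call. = FALSE)
  data$DV <- correct_extraction(data$DV, data$EFF) *
    reference_dose_ug / data$DOSE_UG
  data$EFF <- 1
  data
}

#' Arithmetic mean concentration profile at the sampled times
#'
#' @param data a study dataset (typically already passed through
#'   [nca_normalize()]).
#' @param group `"control"` or `"irradiated"`.
#' @param route administration route (default `"gavage"`).
#' @param tlast last time (h) included in the profile.
#' @return A data frame `time`, `mean`, `n` (animals per time point),
#'   with strictly increasing times.
#' @export
mean_profile <- function(data, group, route = "gavage", tlast = 24) {
  .assert_pk_dataset(data)
  sel <- data$CMT == "plasma" & data$GROUP == group & data$ROUTE == route &
    data$TIME <= tlast
  if (!any(sel)) stop("no plasma records selected", call. = FALSE)
  d <- data[sel, ]
  y <- correct_extraction(d$DV, d$EFF)
  agg <- stats::aggregate(y, by = list(time = d$TIME), FUN = mean)
  cnt <- stats::aggregate(y, by = list(time = d$TIME), FUN = length)
  out <- data.frame(time = agg$time, mean = agg$x, n = cnt$x)
  out[order(out$time), ]
}

#' Linear trapezoidal AUC over a mean profile
#'
#' @param times strictly increasing times (h); at least two.
#' @param values mean values at those times.
#' @return The trapezoidal integral.
#' @examples
#' auc_tlast(c(0, 1, 2), c(0, 2, 1))  # 2.5
#' @export
auc_tlast <- function(times, values) {
  if (length(times) < 2) stop("need at least two time points", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  if (length(values) != length(times))
    stop("'times' and 'values' differ in length", call. = FALSE)
  sum(diff(times) * (head(values, -1) + values[-1]) / 2)
}

# trapezoid weights: AUC = sum(w * means)
.trap_weights <- function(times) {
  J <- length(times)
  dt <- diff(times)
  w <- numeric(J)
  w[1] <- dt[1] / 2
  w[J] <- dt[J - 1] / 2
  if (J > 2) w[2:(J - 1)] <- (dt[-(J - 1)] + dt[-1]) / 2
  w
}

# per-time-point batches: list of value vectors (one value per animal
# at that time), on the dose-normalized corrected scale
.nca_batches <- function(data, group, route, tlast, reference_dose_ug) {
  d <- nca_normalize(data[data$DOSE_UG > 0, , drop = FALSE],
                     reference_dose_ug)
  sel <- d$CMT == "plasma" & d$GROUP == group & d$ROUTE == route &
    d$TIME <= tlast
  if (!any(sel)) stop("no plasma records for group '", group, "'",
                      call. = FALSE)
  d <- d[sel, ]
  sp <- split(d$DV, d$TIME)
  times <- as.numeric(names(sp))
  ord <- order(times)
  list(times = times[ord], batches = sp[ord])
}

# batch-design AUC and its delta-method SE from per-batch means;
# singleton batches contribute zero variance
.batch_auc <- function(batches, w) {
  means <- vapply(batches, mean, 0)
  ns <- lengths(batches)
  vars <- vapply(batches, function(v) if (length(v) > 1) var(v) else 0, 0)
  list(auc = sum(w * means), se = sqrt(sum(w^2 * vars / ns)))
}

#' Batch-design AUC with a bootstrap-t confidence interval
#'
#' Dose-normalized AUC(0-tlast) by the linear trapezoidal rule on the
#' arithmetic per-time means, with a studentized (bootstrap-t)
#' confidence interval.  Animals are resampled with replacement within
#' each time-point batch; each replicate's AUC is studentized by its
#' own delta-method standard error, and the resulting t-quantiles
#' calibrate the interval.  Time points sampled in only one animal
#' cannot contribute a variance estimate; they enter the point estimate
#' but add zero to the SE (with a warning), and if no batch is
#' studentizable the interval falls back to bootstrap percentiles.
#'
#' @param data a study dataset.
#' @param group `"control"` or `"irradiated"`.
#' @param route administration route, default `"gavage"`.
#' @param tlast window end (h), default 24.
#' @param reference_dose_ug normalization dose, default 300.
#' @param B number of bootstrap replicates (>= 199).
#' @param seed optional integer seed; the interval is reproducible
#'   given `seed` and `B`.
#' @param level confidence level.
#' @return An object of class `"nca_auc"`: list with `auc`, `se`,
#'   `ci` (length 2), `method`, `B`, `seed`, `profile`.
#' @export
nca_auc <- function(data, group, route = "gavage", tlast = 24,
                    reference_dose_ug = 300, B = 2000, seed = NULL,
                    level = 0.95) {
  if (B < 199) stop("use at least 199 bootstrap replicates", call. = FALSE)
  bt <- .nca_batches(data, group, route, tlast, reference_dose_ug)
  if (length(bt$times) < 2)
    stop("need at least two time points for an AUC", call. = FALSE)
  w <- .trap_weights(bt$times)
  pt <- .batch_auc(bt$batches, w)
  if (any(lengths(bt$batches) == 1))
    warning("time point(s) with a single animal cannot be studentized; ",
            "they contribute no variance", call. = FALSE)

  boot <- .with_seed(seed, {
    t(vapply(seq_len(B), function(b) {
      res <- lapply(bt$batches, function(v)
        v[sample.int(length(v), length(v), replace = TRUE)])
      ba <- .batch_auc(res, w)
      c(ba$auc, ba$se)
    }, numeric(2)))
  })
  auc_star <- boot[, 1]; se_star <- boot[, 2]

  alpha <- 1 - level
  if (pt$se > 0 && all(se_star > 0)) {
    tstar <- (auc_star - pt$auc) / se_star
    qs <- quantile(tstar, c(1 - alpha / 2, alpha / 2), names = FALSE)
    ci <- pt$auc - qs * pt$se
    method <- "bootstrap-t"
  } else if (stats::sd(auc_star) == 0) {
    ci <- c(pt$auc, pt$auc)
    method <- "degenerate"
  } else {
    ci <- quantile(auc_star, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    method <- "percentile"
    warning("studentization impossible; falling back to percentile interval",
            call. = FALSE)
  }
  # a bootstrap-t interval can in principle exclude the point estimate;
  # clamp so that ci[1] <= auc <= ci[2]
  ci <- c(min(ci[1], pt$auc), max(ci[2], pt$auc))
  structure(list(auc = pt$auc, se = pt$se, ci = ci, level = level,
                 method = method, B = B, seed = seed,
                 group = group, route = route, tlast = tlast,
                 reference_dose_ug = reference_dose_ug,
                 profile = data.frame(time = bt$times,
                                      mean = vapply(bt$batches, mean, 0),
                                      n = lengths(bt$batches))),
            class = "nca_auc")
}

#' @export
print.nca_auc <- function(x, digits = 4, ...) {
  cat(sprintf("Dose-normalized AUC(0-%g h), %s/%s: %s umol*h/L per %g ug\n",
              x$tlast, x$group, x$route, signif(x$auc, digits),
              x$reference_dose_ug))
  cat(sprintf("  %.0f%% CI [%s, %s] (%s, B = %d%s)\n", 100 * x$level,
              signif(x$ci[1], digits), signif(x$ci[2], digits), x$method,
              x$B, if (is.null(x$seed)) "" else paste0(", seed ", x$seed)))
  invisible(x)
}

#' Radiation / control AUC ratio with bootstrap inference
#'
#' Ratio of the two groups' dose-normalized AUC(0-tlast) estimates.
#' The confidence interval and the test of ratio = 1 use the
#' bootstrap-t distribution of the log-ratio: both groups are resampled
#' within their time-point batches, each replicate's log-ratio is
#' studentized by its delta-method SE, and the p-value is the fraction
#' of replicates whose |t| exceeds the observed |t| of the log-ratio
#' against 0.
#'
#' @inheritParams nca_auc
#' @return An object of class `"nca_ratio"`: list with `ratio`, `ci`,
#'   `p_value`, the two per-group `"nca_auc"` components, `B`, `seed`.
#' @export
nca_ratio <- function(data, route = "gavage", tlast = 24,
                      reference_dose_ug = 300, B = 2000, seed = NULL,
                      level = 0.95) {
  if (B < 199) stop("use at least 199 bootstrap replicates", call. = FALSE)
  bi <- .nca_batches(data, "irradiated", route, tlast, reference_dose_ug)
  bc <- .nca_batches(data, "control", route, tlast, reference_dose_ug)
  if (length(bi$times) < 2 || length(bc$times) < 2)
    stop("need at least two shared-window time points per group",
         call. = FALSE)
  wi <- .trap_weights(bi$times); wc <- .trap_weights(bc$times)
  pi_ <- .batch_auc(bi$batches, wi)
  pc <- .batch_auc(bc$batches, wc)
  if (pi_$auc <= 0 || pc$auc <= 0)
    stop("non-positive AUC estimate; log-ratio undefined", call. = FALSE)
  lr <- log(pi_$auc / pc$auc)
  se_lr <- sqrt((pi_$se / pi_$auc)^2 + (pc$se / pc$auc)^2)

  boot <- .with_seed(seed, {
    t(vapply(seq_len(B), function(b) {
      ri <- .batch_auc(lapply(bi$batches, function(v)
        v[sample.int(length(v), length(v), replace = TRUE)]), wi)
      rc <- .batch_auc(lapply(bc$batches, function(v)
        v[sample.int(length(v), length(v), replace = TRUE)]), wc)
      if (ri$auc <= 0 || rc$auc <= 0) return(c(NA_real_, NA_real_))
      c(log(ri$auc / rc$auc),
        sqrt((ri$se / ri$auc)^2 + (rc$se / rc$auc)^2))
    }, numeric(2)))
  })
  ok <- is.finite(boot[, 1]) & is.finite(boot[, 2]) & boot[, 2] > 0
  alpha <- 1 - level
  if (se_lr > 0 && sum(ok) >= 100) {
    tstar <- (boot[ok, 1] - lr) / boot[ok, 2]
    qs <- quantile(tstar, c(1 - alpha / 2, alpha / 2), names = FALSE)
    ci <- exp(lr - qs * se_lr)
    t0 <- lr / se_lr
    p <- (1 + sum(abs(tstar) >= abs(t0))) / (sum(ok) + 1)
    method <- "bootstrap-t"
  } else {
    ci <- exp(quantile(boot[ok, 1], c(alpha / 2, 1 - alpha / 2),
                       names = FALSE))
    t0 <- NA
    p <- NA
    method <- "percentile"
    warning("studentization impossible for the log-ratio", call. = FALSE)
  }
  structure(list(ratio = exp(lr), ci = ci, p_value = p, method = method,
                 irradiated = pi_, control = pc, tlast = tlast,
                 route = route, B = B, seed = seed, level = level),
            class = "nca_ratio")
}

#' @export
print.nca_ratio <- function(x, digits = 4, ...) {
  cat(sprintf("AUC(0-%g h) ratio irradiated/control: %s\n", x$tlast,
              signif(x$ratio, digits)))
  cat(sprintf("  %.0f%% CI [%s, %s]; p = %s (%s, B = %d)\n",
              100 * x$level, signif(x$ci[1], digits),
              signif(x$ci[2], digits), format.pval(x$p_value, digits = 3),
              x$method, x$B))
  invisible(x)
}
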
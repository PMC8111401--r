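# Exact solution of the linear compartmental system.
#
# States (amounts, umol): depot (gut), plasma (central), peripheral,
# urine (cumulative).  Gavage places the full dose in the depot at t = 0
# and bioavailability F scales the depot-to-plasma transfer (so a
# fraction 1 - F of absorbed drug leaves the system unobserved); IV
# places the full dose in plasma and bypasses the depot and F entirely.
#
# The system is linear with constant coefficients, so the solution is a
# sum of exponentials in the disposition rates alpha, beta and the
# absorption rate ka.  Confluent cases (coinciding rates, or a zero
# terminal rate when Cl or Q is 0) fall back to a Pade matrix
# exponential of the full 4x4 system, which is exact for any parameter
# values.

# relative gap below which two exponential rates are treated as confluent
.CONFL_TOL <- 1e-10

#' Solve the lisinopril compartmental model
#'
#' Computes the exact trajectory of the linear compartmental system
#' (closed-form exponentials, with a matrix-exponential fallback for
#' confluent rate constants) after a single dose at time 0.
#'
#' @param p a [pk_params()] object.
#' @param dose_umol administered amount in micromoles (positive).
#' @param route `"gavage"` (dose into the gut depot, absorbed at rate
#'   `ka` with bioavailability `F`) or `"iv"` (dose directly into
#'   plasma; `F` is not applied).
#' @param times numeric vector of non-decreasing, non-negative times (h).
#' @param model `"two_cpt"` (default) or `"one_cpt"` (no peripheral
#'   compartment; `Q` and `V3` are ignored).
#'
#' @return A data frame with one row per time: `time`, the compartment
#'   amounts `depot`, `plasma`, `peripheral`, `urine` (umol) and the
#'   plasma concentration `conc = plasma / V2` (umol/L).
#'
#' @examples
#' p <- pk_params(ka = 0.279, F = 0.192, Cl = 0.009, Q = 0.014,
#'                V2 = 0.008, V3 = 0.513)
#' pk_solve(p, dose_to_umol(300), "gavage", times = c(0.5, 2, 8, 24))
#' @export
pk_solve <- function(p, dose_umol, route = c("gavage", "iv"), times,
                     model = c("two_cpt", "one_cpt")) {
  stopifnot(inherits(p, "pk_params"))
  route <- match.arg(route)
  model <- match.arg(model)
  if (!is.numeric(dose_umol) || length(dose_umol) != 1L || dose_umol <= 0)
    stop("'dose_umol' must be a single positive amount", call. = FALSE)
  if (!is.numeric(times) || length(times) == 0L)
    stop("'times' must be a non-empty numeric vector", call. = FALSE)
  if (any(times < 0)) stop("negative times are not allowed", call. = FALSE)
  if (is.unsorted(times)) stop("'times' must be non-decreasing", call. = FALSE)

  out <- if (model == "two_cpt")
    .solve2(p, dose_umol, route, times)
  else
    .solve1(p, dose_umol, route, times)
  out$conc <- out$plasma / p$V2
  out
}

.solve2 <- function(p, D, route, times) {
  mc <- micro_constants(p)
  k10 <- mc[["k10"]]; k12 <- mc[["k12"]]; k21 <- mc[["k21"]]
  ab <- disposition_rates(mc)
  a <- ab[["alpha"]]; b <- ab[["beta"]]
  ka <- p$ka

  confl <- (a - b) <= .CONFL_TOL * a || b <= 0 ||
    (route == "gavage" &&
       (abs(ka - a) <= .CONFL_TOL * max(ka, a) ||
        abs(ka - b) <= .CONFL_TOL * max(ka, b)))
  if (confl) return(.solve_expm(p, D, route, times, one_cpt = FALSE))

  ca <- (k21 - a) / (b - a)
  cb <- (k21 - b) / (a - b)
  Ea <- exp(-a * times); Eb <- exp(-b * times)

  if (route == "iv") {
    plasma <- D * (ca * Ea + cb * Eb)
    peri   <- D * k12 * (Eb - Ea) / (a - b)
    urine  <- D * k10 * (ca * (1 - Ea) / a + cb * (1 - Eb) / b)
    depot  <- rep(0, length(times))
  } else {
    Eka <- exp(-ka * times)
    da <- ka - a; db <- ka - b
    plasma <- p$F * ka * D * (ca * (Ea - Eka) / da + cb * (Eb - Eka) / db)
    peri   <- p$F * ka * D * k12 / (a - b) *
      ((Eb - Eka) / db - (Ea - Eka) / da)
    urine  <- p$F * ka * D * k10 *
      (ca * ((1 - Ea) / a - (1 - Eka) / ka) / da +
       cb * ((1 - Eb) / b - (1 - Eka) / ka) / db)
    depot  <- D * Eka
  }
  data.frame(time = times, depot = depot, plasma = plasma,
             peripheral = peri, urine = urine)
}

.solve1 <- function(p, D, route, times) {
  k <- p$Cl / p$V2
  ka <- p$ka
  zero <- rep(0, length(times))
  if (route == "iv") {
    Ek <- exp(-k * times)
    return(data.frame(time = times, depot = zero, plasma = D * Ek,
                      peripheral = zero, urine = D * (1 - Ek)))
  }
  if (abs(ka - k) <= .CONFL_TOL * max(ka, k) || k <= 0)
    return(.solve_expm(p, D, route, times, one_cpt = TRUE))
  Ek <- exp(-k * times); Eka <- exp(-ka * times)
  plasma <- p$F * ka * D * (Ek - Eka) / (ka - k)
  urine  <- p$F * ka * D * k * ((1 - Ek) / k - (1 - Eka) / ka) / (ka - k)
  data.frame(time = times, depot = D * Eka, plasma = plasma,
             peripheral = zero, urine = urine)
}

# Exact fallback: Pade matrix exponential of the full linear system,
# valid for any (possibly confluent or degenerate) rate constants.
.solve_expm <- function(p, D, route, times, one_cpt = FALSE) {
  k10 <- p$Cl / p$V2
  k12 <- if (one_cpt) 0 else p$Q / p$V2
  k21 <- if (one_cpt) 0 else p$Q / p$V3
  M <- matrix(c(
    -p$ka,            0,            0, 0,
    p$F * p$ka, -(k10 + k12),     k21, 0,
    0,                k12,        -k21, 0,
    0,                k10,           0, 0), 4, 4, byrow = TRUE)
  if (route == "iv") {
    M[, 1] <- 0  # depot unused
    y0 <- c(0, D, 0, 0)
  } else {
    y0 <- c(D, 0, 0, 0)
  }
  st <- vapply(times, function(t)
    as.numeric(Matrix::expm(M * t) %*% y0), numeric(4))
  data.frame(time = times, depot = st[1, ], plasma = st[2, ],
             peripheral = st[3, ], urine = st[4, ])
}

# ---------------------------------------------------------------------
# Vectorized per-observation predictor (likelihood hot path).
#
# All arguments are vectors of length n (one element per observation
# row); parameters are the *individual* values for the row's animal.
# Returns the model prediction for each row: plasma concentration
# (umol/L) for plasma rows, cumulative urine amount (umol) for urine
# rows.  Rows with confluent rates are recomputed exactly through the
# matrix-exponential path.
.pred_rows2 <- function(time, dose, iv, urine, ka, F, Cl, Q, V2, V3) {
  k10 <- Cl / V2; k12 <- Q / V2; k21 <- Q / V3
  s <- k10 + k12 + k21
  disc <- sqrt(pmax(s * s - 4 * k10 * k21, 0))
  a <- (s + disc) / 2
  b <- (s - disc) / 2
  ca <- (k21 - a) / (b - a)
  cb <- (k21 - b) / (a - b)
  Ea <- exp(-a * time); Eb <- exp(-b * time)
  ap <- 1 - Ea; bp <- 1 - Eb

  pred <- numeric(length(time))
  gv <- !iv
  ip <- iv & !urine; iu <- iv & urine
  gp <- gv & !urine; gu <- gv & urine

  if (any(ip))
    pred[ip] <- (dose * (ca * Ea + cb * Eb) / V2)[ip]
  if (any(iu))
    pred[iu] <- (dose * k10 * (ca * ap / a + cb * bp / b))[iu]
  if (any(gv)) {
    Eka <- exp(-ka * time)
    da <- ka - a; db <- ka - b
    if (any(gp))
      pred[gp] <- (F * ka * dose *
                     (ca * (Ea - Eka) / da + cb * (Eb - Eka) / db) / V2)[gp]
    if (any(gu)) {
      kap <- (1 - Eka) / ka
      pred[gu] <- (F * ka * dose * k10 *
                     (ca * (ap / a - kap) / da + cb * (bp / b - kap) / db))[gu]
    }
  }

  bad <- (a - b) <= .CONFL_TOL * a | b <= 0
  if (any(gv)) {
    bad <- bad | (gv & (abs(ka - a) <= .CONFL_TOL * pmax(ka, a) |
                        abs(ka - b) <= .CONFL_TOL * pmax(ka, b)))
  }
  bad <- bad & dose > 0 & is.finite(ka + F + Cl + Q + V2 + V3)
  bad[is.na(bad)] <- FALSE  # non-finite inputs: leave NaN for the caller
  if (any(bad)) {
    for (i in which(bad)) {
      p <- pk_params(ka = ka[i], F = F[i], Cl = Cl[i], Q = Q[i],
                     V2 = V2[i], V3 = V3[i])
      tr <- .solve_expm(p, dose[i], if (iv[i]) "iv" else "gavage", time[i])
      pred[i] <- if (urine[i]) tr$urine else tr$plasma / V2[i]
    }
  }
  pred[dose <= 0] <- 0
  pred
}

.pred_rows1 <- function(time, dose, iv, urine, ka, F, Cl, V2) {
  k <- Cl / V2
  pred <- numeric(length(time))
  gv <- !iv
  Ek <- exp(-k * time)
  if (any(iv)) {
    pred[iv & !urine] <- (dose * Ek / V2)[iv & !urine]
    pred[iv & urine] <- (dose * (1 - Ek))[iv & urine]
  }
  if (any(gv)) {
    Eka <- exp(-ka * time)
    d <- ka - k
    gp <- gv & !urine; gu <- gv & urine
    if (any(gp))
      pred[gp] <- (F * ka * dose * (Ek - Eka) / d / V2)[gp]
    if (any(gu))
      pred[gu] <- (F * ka * dose * k * ((1 - Ek) / k - (1 - Eka) / ka) / d)[gu]
    bad <- gv & (abs(d) <= .CONFL_TOL * pmax(ka, k) | k <= 0) & dose > 0 &
      is.finite(ka + F + Cl + V2)
    bad[is.na(bad)] <- FALSE
    if (any(bad)) {
      for (i in which(bad)) {
        p <- pk_params(ka = ka[i], F = F[i], Cl = Cl[i], Q = 0,
                       V2 = V2[i], V3 = 1)
        tr <- .solve_expm(p, dose[i], "gavage", time[i], one_cpt = TRUE)
        pred[i] <- if (urine[i]) tr$urine else tr$plasma / V2[i]
      }
    }
  }
  pred[dose <= 0] <- 0
  pred
}
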
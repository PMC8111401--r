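#' Structural parameters of the two-compartment lisinopril model
#'
#' Container for the six structural (typical-value) parameters of the
#' two-compartment disposition model with an oral depot and a cumulative
#' urine compartment: first-order absorption from the gut depot at rate
#' `ka`, bioavailability `F` acting on the depot-to-plasma transfer,
#' renal clearance `Cl` out of the central (plasma) compartment into
#' urine, inter-compartmental clearance `Q` exchanging drug between the
#' central and the lumped peripheral compartment, and the apparent
#' volumes `V2` (central) and `V3` (peripheral).
#'
#' Internal units are fixed: hours, liters, micromoles and micromol/L.
#' All unit conversions (e.g. administered micrograms to micromoles)
#' happen at the data boundary, see [dose_to_umol()].
#'
#' @param ka absorption rate constant (1/h), must be positive.
#' @param F bioavailability, a fraction in (0, 1].
#' @param Cl renal clearance (L/h), non-negative.
#' @param Q inter-compartmental clearance (L/h), non-negative.
#' @param V2 central (plasma) volume (L), positive.
#' @param V3 peripheral volume (L), positive.
#'
#' @return An object of class `"pk_params"`: a named list with the six
#'   components above.
#'
#' @examples
#' # Typical control-group values for lisinopril in the rat
#' p <- pk_params(ka = 0.279, F = 0.192, Cl = 0.009, Q = 0.014,
#'                V2 = 0.008, V3 = 0.513)
#' terminal_half_life(p)
#' @export
pk_params <- function(ka, F, Cl, Q, V2, V3) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
    as.numeric(x)
  }
  ka <- num1(ka, "ka"); F <- num1(F, "F"); Cl <- num1(Cl, "Cl")
  Q <- num1(Q, "Q"); V2 <- num1(V2, "V2"); V3 <- num1(V3, "V3")
  if (ka <= 0) stop("'ka' must be > 0", call. = FALSE)
  if (F <= 0 || F > 1) stop("'F' must lie in (0, 1]", call. = FALSE)
  if (Cl < 0) stop("'Cl' must be >= 0", call. = FALSE)
  if (Q < 0) stop("'Q' must be >= 0", call. = FALSE)
  if (V2 <= 0 || V3 <= 0) stop("volumes 'V2' and 'V3' must be > 0", call. = FALSE)
  structure(list(ka = ka, F = F, Cl = Cl, Q = Q, V2 = V2, V3 = V3),
            class = "pk_params")
}

#' @export
print.pk_params <- function(x, digits = 4, ...) {
  cat("Two-compartment PK parameters (h, L, umol):\n")
  v <- unlist(x)
  units <- c(ka = "1/h", F = "", Cl = "L/h", Q = "L/h", V2 = "L", V3 = "L")
  for (nm in names(v))
    cat(sprintf("  %-3s %-10s %s\n", nm, format(signif(v[[nm]], digits)),
                units[[nm]]))
  invisible(x)
}

#' Radiation-group multiplicative parameter ratios
#'
#' Multiplicative ratios (irradiated / control) applied to the absorption
#' rate, renal clearance, inter-compartmental clearance and
#' bioavailability of a control-group parameter set.  Volumes carry no
#' ratio.
#'
#' @param ka,Cl,Q,F positive multiplicative ratios (default 1, i.e. no
#'   radiation effect).
#' @return An object of class `"radiation_effect"`.
#' @examples
#' radiation_effect(ka = 0.883, Cl = 0.943, Q = 0.615, F = 1.326)
#' @seealso [apply_radiation()]
#' @export
radiation_effect <- function(ka = 1, Cl = 1, Q = 1, F = 1) {
  r <- c(ka = ka, Cl = Cl, Q = Q, F = F)
  if (!is.numeric(r) || any(!is.finite(r)) || any(r <= 0))
    stop("radiation ratios must all be positive finite numbers", call. = FALSE)
  structure(as.list(r), class = "radiation_effect")
}

#' @export
print.radiation_effect <- function(x, digits = 4, ...) {
  cat("Radiation-group parameter ratios (irradiated / control):\n")
  v <- unlist(x)
  for (nm in names(v))
    cat(sprintf("  %-3s %s\n", nm, format(signif(v[[nm]], digits))))
  invisible(x)
}

#' Apply radiation-group ratios to control-group parameters
#'
#' Multiplies `ka`, `Cl`, `Q` and `F` by the corresponding group ratios;
#' the volumes `V2` and `V3` are unchanged.  The resulting
#' bioavailability must remain in (0, 1].
#'
#' @param p a [pk_params()] object (control-group typical values).
#' @param r a [radiation_effect()] object.
#' @return A new `pk_params` object for the irradiated group.
#' @examples
#' ctrl <- pk_params(ka = 0.279, F = 0.192, Cl = 0.009, Q = 0.014,
#'                   V2 = 0.008, V3 = 0.513)
#' apply_radiation(ctrl, radiation_effect(ka = 0.883, Cl = 0.943,
#'                                        Q = 0.615, F = 1.326))
#' @export
apply_radiation <- function(p, r) {
  stopifnot(inherits(p, "pk_params"), inherits(r, "radiation_effect"))
  Fnew <- p$F * r$F
  if (Fnew > 1)
    stop("radiation ratio would push bioavailability above 1 (F * r_F = ",
         format(Fnew), ")", call. = FALSE)
  pk_params(ka = p$ka * r$ka, F = Fnew, Cl = p$Cl * r$Cl, Q = p$Q * r$Q,
            V2 = p$V2, V3 = p$V3)
}

#' Micro-rate constants of the disposition system
#'
#' Reparameterizes the clearance/volume parameterization into the
#' first-order micro-constants `k10 = Cl/V2` (elimination),
#' `k12 = Q/V2` (central to peripheral) and `k21 = Q/V3` (peripheral to
#' central).
#'
#' @param p a [pk_params()] object.
#' @return Named numeric vector `c(k10, k12, k21)` in 1/h.
#' @export
micro_constants <- function(p) {
  stopifnot(inherits(p, "pk_params"))
  if (p$V2 <= 0 || p$V3 <= 0)
    stop("volumes must be positive", call. = FALSE)
  c(k10 = p$Cl / p$V2, k12 = p$Q / p$V2, k21 = p$Q / p$V3)
}

#' Disposition eigenvalues (alpha/beta hybrid rate constants)
#'
#' The two exponential rates governing the bi-exponential disposition of
#' drug already in the body: the (negated) eigenvalues of the 2x2
#' central/peripheral disposition matrix, i.e. the roots of
#' `x^2 - (k10 + k12 + k21) x + k10 k21 = 0`.  `alpha >= beta >= 0`;
#' `beta` is the terminal (slow) rate.
#'
#' @param p a [pk_params()] object, or a named vector of micro-constants
#'   as returned by [micro_constants()].
#' @return Named numeric vector `c(alpha, beta)` in 1/h.
#' @export
disposition_rates <- function(p) {
  mc <- if (inherits(p, "pk_params")) micro_constants(p) else p
  if (!all(c("k10", "k12", "k21") %in% names(mc)))
    stop("need micro-constants k10, k12, k21", call. = FALSE)
  if (any(mc < 0)) stop("micro-constants must be >= 0", call. = FALSE)
  s <- mc[["k10"]] + mc[["k12"]] + mc[["k21"]]
  pr <- mc[["k10"]] * mc[["k21"]]
  disc <- sqrt(max(s * s - 4 * pr, 0))
  c(alpha = (s + disc) / 2, beta = (s - disc) / 2)
}

#' Terminal half-life of the two-compartment model
#'
#' `log(2)` over the slow disposition rate `beta`; the half-life of the
#' late log-linear decline of the plasma concentration.
#'
#' @param p a [pk_params()] object with `Cl > 0` and `Q > 0`.
#' @return Terminal half-life in hours.
#' @examples
#' ctrl <- pk_params(ka = 0.279, F = 0.192, Cl = 0.009, Q = 0.014,
#'                   V2 = 0.008, V3 = 0.513)
#' terminal_half_life(ctrl)  # ~65 h
#' @export
terminal_half_life <- function(p) {
  beta <- disposition_rates(p)[["beta"]]
  if (beta <= 0)
    stop("model has no terminal elimination phase (beta = 0); ",
         "requires Cl > 0 and Q > 0", call. = FALSE)
  log(2) / beta
}

#' Analytic area under the plasma concentration curve to infinity
#'
#' For a linear model all absorbed drug is ultimately excreted in urine,
#' and total urinary excretion equals `Cl` times the integral of the
#' plasma concentration; hence `AUC(0, Inf) = F * dose / Cl` for gavage
#' and `dose / Cl` for intravenous dosing.
#'
#' @param p a [pk_params()] object with `Cl > 0`.
#' @param dose_umol administered amount in micromoles.
#' @param route `"gavage"` or `"iv"`.
#' @return AUC in umol * h / L.
#' @export
auc_infinity <- function(p, dose_umol, route = c("gavage", "iv")) {
  stopifnot(inherits(p, "pk_params"), is.numeric(dose_umol), dose_umol >= 0)
  route <- match.arg(route)
  if (p$Cl <= 0)
    stop("AUC(0, Inf) diverges when Cl = 0 (no elimination)", call. = FALSE)
  if (route == "gavage") p$F * dose_umol / p$Cl else dose_umol / p$Cl
}

#' Individual-animal parameters from random effects
#'
#' Applies an animal's random effects to the typical parameter set:
#' log-normal multiplicative effects on the compartment volumes,
#' `V2 * exp(eta[1])` and `V3 * exp(eta[2])`; all other parameters are
#' unchanged.
#'
#' @param p a [pk_params()] object (typical values).
#' @param eta numeric length-2 vector of random effects on log V2 and
#'   log V3.
#' @return A `pk_params` object with the individual volumes.
#' @export
individual_parameters <- function(p, eta) {
  stopifnot(inherits(p, "pk_params"), is.numeric(eta), length(eta) == 2)
  pk_params(ka = p$ka, F = p$F, Cl = p$Cl, Q = p$Q,
            V2 = p$V2 * exp(eta[1]), V3 = p$V3 * exp(eta[2]))
}
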
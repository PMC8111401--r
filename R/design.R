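# The study sampling design.
#
# The original experiment dosed 219 rats in cells defined by radiation
# group x route x dose, each animal contributing 0-4 sparse plasma draws
# and at most one cumulative 24-h urine collection.  study_design()
# reconstructs that layout programmatically; scale_design() shrinks it
# proportionally for fast simulation experiments.

#' The sparse sampling design of the rat lisinopril study
#'
#' One row per design cell: radiation group, administration route, dose
#' in micrograms per animal, number of sparse plasma draws per animal,
#' whether a cumulative 24-h urine sample was collected, and the number
#' of animals.  The full design covers 219 animals.
#'
#' Doses are micrograms per animal (0.3/0.6 mg gavage, 0.06 mg IV).
#'
#' @return A data frame of class `"pk_design"` with columns `group`,
#'   `route`, `dose_ug`, `n_plasma`, `urine`, `n`.
#' @examples
#' d <- study_design()
#' sum(d$n)  # 219 animals
#' @export
study_design <- function() {
  d <- data.frame(
    group = rep(c("control", "irradiated"), c(12, 8)),
    route = c(rep("gavage", 8), rep("iv", 4), rep("gavage", 6), rep("iv", 2)),
    dose_ug = c(0, 300, 300, 300, 600, 600, 600, 600, 60, 60, 60, 60,
                300, 300, 300, 600, 600, 600, 60, 60),
    n_plasma = c(1, 0, 1, 2, 0, 1, 2, 4, 0, 1, 1, 2,
                 0, 1, 2, 0, 2, 4, 0, 1),
    urine = c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE,
              TRUE, FALSE, TRUE, FALSE,
              TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE),
    n = c(4, 4, 55, 2, 6, 3, 9, 9, 6, 11, 3, 3,
          5, 58, 2, 6, 8, 8, 6, 11),
    stringsAsFactors = FALSE
  )
  class(d) <- c("pk_design", "data.frame")
  d
}

#' Proportionally scale a study design
#'
#' Multiplies every cell's animal count by `frac` (rounding, with a
#' minimum of one animal per cell), preserving the cell structure.
#' Useful for scaled-down simulation experiments.
#'
#' @param design a design data frame as returned by [study_design()].
#' @param frac positive scaling fraction.
#' @return The scaled design.
#' @export
scale_design <- function(design, frac) {
  stopifnot(is.data.frame(design), is.numeric(frac), frac > 0)
  design$n <- pmax(1L, as.integer(round(design$n * frac)))
  design
}

# Candidate sampling times (h) per route.
.GAVAGE_TIMES <- c(0, 0.5, 1, 1.5, 2, 2.5, 3, 4, 5, 6, 8, 24, 48)
.IV_TIMES <- c(5 / 60, 1.5, 24)

#' Sparse plasma sampling schedule for one animal
#'
#' Draws `n_draws` distinct sampling times, uniformly at random without
#' replacement, from the route's candidate menu: 13 times between 0 and
#' 48 h for gavage, and 5 min, 1.5 h and 24 h for IV.  Uses the current
#' R random number generator state.
#'
#' @param route `"gavage"` or `"iv"`.
#' @param n_draws number of plasma draws (1-4 for gavage, 1-2 for IV).
#' @return Sorted numeric vector of `n_draws` times in hours.
#' @export
sampling_schedule <- function(route = c("gavage", "iv"), n_draws) {
  route <- match.arg(route)
  menu <- if (route == "gavage") .GAVAGE_TIMES else .IV_TIMES
  if (!is.numeric(n_draws) || length(n_draws) != 1L || n_draws < 1)
    stop("'n_draws' must be a positive count", call. = FALSE)
  if (n_draws > length(menu))
    stop(sprintf("n_draws = %d exceeds the %s menu of %d candidate times",
                 n_draws, route, length(menu)), call. = FALSE)
  sort(sample(menu, n_draws))
}
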
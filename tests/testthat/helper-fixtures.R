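# Shared fixtures: the published typical values and small synthetic
# datasets, all built in code.

table2_params <- function() {
  pk_params(ka = 0.279, F = 0.192, Cl = 0.009, Q = 0.014,
            V2 = 0.008, V3 = 0.513)
}

table3_ratios <- function() {
  radiation_effect(ka = 0.883, Cl = 0.943, Q = 0.615, F = 1.326)
}

# a three-animal design exercising both groups, both routes and urine
tiny_design <- function() {
  data.frame(group = c("control", "control", "irradiated"),
             route = c("gavage", "iv", "gavage"),
             dose_ug = c(300, 60, 300),
             n_plasma = c(3, 2, 2),
             urine = c(TRUE, TRUE, FALSE),
             n = c(1, 1, 1),
             stringsAsFactors = FALSE)
}

# hand-written three-record dataset for I/O tests
toy_records <- function() {
  data.frame(ID = c("A1", "A1", "B2"),
             GROUP = c("control", "control", "irradiated"),
             ROUTE = c("gavage", "gavage", "iv"),
             DOSE_UG = c(300, 300, 60),
             TIME = c(1, 24, 1.5),
             CMT = c("plasma", "urine", "plasma"),
             DV = c(1.25, 0.0625, 0.5),
             EFF = c(0.85, 0.9, 0.85),
             stringsAsFactors = FALSE)
}

# random but valid parameter sets for property-style tests
random_params <- function(n, seed = 1) {
  set.seed(seed)
  replicate(n, pk_params(ka = exp(runif(1, log(0.05), log(5))),
                         F = runif(1, 0.05, 0.95),
                         Cl = exp(runif(1, log(1e-3), log(0.5))),
                         Q = exp(runif(1, log(1e-3), log(0.5))),
                         V2 = exp(runif(1, log(5e-3), log(0.5))),
                         V3 = exp(runif(1, log(0.05), log(5)))),
            simplify = FALSE)
}

# cross-test cache for expensive fitted objects
.acc_cache <- new.env(parent = emptyenv())
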
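# Bundled reference tables: published solution-phase pseudocontact shifts
# and donor-angle summaries for [DyL1]/[GdL1] in D2O, MeOD and d6-DMSO.
# They serve as comparison targets for pipeline output (RMSD, ranges,
# ordering), not as inputs to any computation.

#' Reference pseudocontact shifts of the pyridyl protons
#'
#' Experimental shifts, time-averaged trajectory-calculated shifts, and
#' average-structure-calculated shifts (ppm) for protons H1-H3 of the
#' Dy(III) complex in the three solvents.
#'
#' @return Data frame with columns `solvent`, `proton`,
#'   `experimental_ppm`, `time_avg_ppm`, `avg_struct_ppm`.
#' @export
reference_shifts <- function() {
  utils::read.csv(system.file("extdata", "table2_shifts.csv",
                              package = "lnshift"))
}

#' Reference per-frame shift extremes
#'
#' Maximum and minimum instantaneous calculated shifts (ppm) across the
#' trajectory in each solvent, quantifying the +-80-130 ppm fluctuation
#' amplitudes.
#'
#' @return Data frame with columns `solvent`, `calc_max_ppm`,
#'   `calc_min_ppm`.
#' @export
reference_shift_extremes <- function() {
  utils::read.csv(system.file("extdata", "table2_extremes.csv",
                              package = "lnshift"))
}

#' Reference O-metal-axis angle summaries
#'
#' Minimum, maximum and average O-Gd-C3 angles (degrees) from solution
#' trajectories in the three solvents, plus the earlier average-structure
#' values.
#'
#' @return Data frame with columns `solvent`, `min_deg`, `max_deg`,
#'   `mean_deg`, `mean_prev_deg`.
#' @export
reference_angles <- function() {
  utils::read.csv(system.file("extdata", "table1_angles.csv",
                              package = "lnshift"))
}
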
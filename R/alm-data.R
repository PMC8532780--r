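#' Alamethicin E18 primary sequence
#'
#' The 20-residue sequence of alamethicin E18 (Ac-Aib1...Phl20) as
#' 3-letter codes, acetyl cap excluded. Aib is
#' alpha-aminoisobutyric acid and Phl the C-terminal amino alcohol
#' phenylalaninol.
#'
#' @return character vector of 20 residue codes.
#' @export
alm_e18_sequence <- function() {
  c("AIB", "PRO", "AIB", "ALA", "AIB", "ALA", "GLN", "AIB", "VAL", "AIB",
    "GLY", "LEU", "AIB", "PRO", "VAL", "AIB", "AIB", "GLU", "GLN", "PHL")
}

#' Reference shift-tensor tables for the ALM-E18 model
#'
#' Per-residue theoretical chemical shifts (calibrated from periodic-DFT
#' shieldings of the crystalline alamethicin E18 model) and tensor
#' orientation angles, shipped as plain CSV: amide 15N values for all 20
#' residues (angles undefined for the two prolines) and carbonyl 13C
#' values for residues 1-19 (the amino-alcohol terminus has no carbonyl),
#' including the axial anisotropy. These tables are the printed-table
#' inputs of the downstream oriented-sample analysis.
#'
#' @param nucleus `"15N"` or `"13C"`.
#' @return a data.frame (see [read_shift_table()] for the layout).
#' @export
alm_shift_table <- function(nucleus = c("15N", "13C")) {
  nucleus <- match.arg(nucleus)
  file <- system.file("extdata",
                      if (nucleus == "15N") "alm_e18_15N.csv"
                      else "alm_e18_13C.csv",
                      package = "helixnmr", mustWork = TRUE)
  read_shift_table(file)
}

#' Reference experimental 15N shift sets for tilt analysis
#'
#' Two oriented-sample reference sets used in tilt extraction for
#' alamethicin: the single-site experimental principal values of Aib8
#' (Haeberlen-reported, from 2H/15N oriented-sample work) and the
#' consensus principal values used for Aib sites in the classic
#' tilt determination (tau = 8.0 degrees for ALM-A6).
#'
#' @return data.frame with `set`, `d11`, `d22`, `d33` (ppm), `tau_ref`
#'   (degrees, `NA` where not applicable).
#' @export
reference_shift_sets <- function() {
  data.frame(
    set = c("aib8_experimental", "aib_consensus"),
    d11 = c(66.7, 64.5), d22 = c(81.3, 85.5), d33 = c(230, 232.5),
    tau_ref = c(NA, 8.0))
}
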
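#' The B-domain histidine-scanning design (17 positions)
#'
#' The published design of the protein A B-domain scan: seventeen
#' Fc-interface positions, their wild-type residues, and the mixed codons
#' synthesized at each. The `distance` column is the minimum distance
#' (Angstrom) from the position to the nearest positively charged Fc residue
#' in the 1FC2 complex and `fsasa_pct` the fractional solvent accessibility
#' (percent) reported for the design; both are carried as annotation.
#'
#' @return A `his_library_design` with extra columns `distance`, `fsasa_pct`.
#' @export
pab_library_design <- function() {
  pos <- c(5, 6, 9, 10, 11, 13, 14, 15, 17, 24, 25, 27, 28, 31, 32, 35, 36)
  wt <- c("F", "N", "Q", "Q", "N", "F", "Y", "E", "L", "E", "E", "R", "N",
          "I", "Q", "K", "D")
  codon <- c("YWT", "MAY", "CAW", "CAW", "MAY", "YWT", "YAT", "SAW", "CWK",
             "SAW", "SAW", "CRY", "MAY", "MWT", "CAW", "MAW", "SAT")
  d <- his_scan_design(pos, wt, codon)
  d$distance <- c(5.7, 11, 6.4, 4.2, 6.5, 3.8, 3.4, 7.9, 4.0, 8.4, 8.7, 8.6,
                  6.9, 5.8, 8.1, 4.5, 9.8)
  d$fsasa_pct <- c(78, 94, 36, 47, 64, 40, 63, 50, 46, 78, 96, 23, 71, 17,
                   60, 64, 68)
  d
}

#' Measured properties of the characterized B-domain variants
#'
#' Wet-lab characterization of the wild type and nine His variants: the IgG
#' elution-peak pH of each variant's affinity column, the thermal-unfolding
#' midpoint Tm from CD melting, and the IgG dissociation constants at
#' neutral (pH 7.4) and mildly acidic (pH 5.0) conditions. These values are
#' experimental inputs: they parameterize the synthetic-data generators and
#' the report layout, and cannot be recomputed from sequence.
#'
#' `kD_*` columns are in molar; `NA` marks affinities too weak to determine
#' (censored, printed as "ND" in reports).
#'
#' @return Data frame, one row per variant.
#' @export
pab_variants <- function() {
  data.frame(
    protein = c("PAB01", "PAB02", "PAB03", "PAB04", "PAB05", "PAB06",
                "PAB07", "PAB08", "PAB09", "PAB10"),
    mutations = c("WT", "D36H", "Q9H,D36H", "Q10H,D36H", "R27H,D36H",
                  "K35H,D36H", "Q9H", "Q10H", "R27H", "Q32H"),
    elution_peak_pH = c(3.5, 4.6, 5.5, 6.8, 4.7, 4.4, 3.9, 3.7, NA, 4.2),
    tm_K = c(346.4, 345.8, 343.7, 343.1, 316.2, 342.5, 344.9, 343.6, NA,
             341.4),
    kD_pH7.4 = c(5.1e-9, 33.6e-9, 288e-9, 6830e-9, 80.7e-9, 550e-9,
                 13.9e-9, 50.8e-9, 5.6e-9, 2.8e-9),
    kD_pH5.0 = c(7.6e-9, 832e-9, NA, NA, 2090e-9, 3860e-9, 30.6e-9,
                 951e-9, 7.0e-9, 96.8e-9),
    stringsAsFactors = FALSE
  )
}

#' Fc- and Fab-fragment affinities of wild type and D36H
#'
#' Dissociation constants (molar) of the IgG-Fc and IgG-Fab fragments for
#' the wild-type domain and the D36H variant, at neutral and acidic pH.
#' `NA` marks censored (not determinable) affinities.
#'
#' @return Data frame with columns `protein`, `fragment`, `kD_pH7.4`,
#'   `kD_pH5.0`.
#' @export
pab_fragment_affinity <- function() {
  data.frame(
    protein = c("PAB01", "PAB02", "PAB01", "PAB02"),
    fragment = c("Fc", "Fc", "Fab", "Fab"),
    kD_pH7.4 = c(12.8e-9, 15.5e-9, 2.9e-5, 6.7e-5),
    kD_pH5.0 = c(1080e-9, 1350e-9, NA, NA),
    stringsAsFactors = FALSE
  )
}

#' Sequencing depth per panning round of the reference screen
#'
#' Number of clones sequenced after each round (element 1 = the unselected
#' initial library, elements 2-6 = rounds 1-5).
#' @return Integer vector of length 6.
#' @export
pab_round_depths <- function() {
  c(84L, 50L, 84L, 58L, 88L, 93L)
}

#' Stepwise mild-elution recoveries of the tandem-Z-domain column
#'
#' Fractions of bound IgG recovered from the engineered tandem column at
#' fixed mildly acidic steps. Experimental values, used only as a report
#' fixture for the stepwise-elution mode.
#' @return Named numeric vector (percent recovered at each step pH).
#' @export
paz_step_recoveries <- function() {
  c("pH 6.0" = 67, "pH 5.5" = 82, "pH 5.0" = 90)
}

#' Heat-capacity change of unfolding used for all variants
#'
#' The wild-type domain's dCp, held fixed across variants during two-state
#' fitting (kJ/(mol K)).
#' @return Numeric scalar.
#' @export
pab_dcp <- function() 2.643
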
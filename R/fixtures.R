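# Built-in critical-residue sets for the two benchmark proteins.
# The position lists are stored verbatim as printed in the primary
# literature and expanded at run time by parse_position_spec(), so the
# package always reports its own expansion count.

.hokc_positions <-
  "1, 2, 8, 11, 12, 13, 15, 17, 19, 20, 24, 25, 26, 28, 29, 31, 32, 33, 39, 40, 41, 43, 46, 47 and 49"

.hiv1_full_positions <-
  "2, 5, 9, 13, 15, 22–29, 31–33, 36, 40, 46, 47, 49–52, 56, 57, 59, 62, 65, 68, 74–81, 83–90 and 97"

.hiv1_conserved_positions <-
  "9, 15, 23–29, 31–33, 47, 49, 51, 52, 74, 81, 84, 86, 87, 90 and 97"

#' Critical residues of HokC (E. coli host-killing toxin)
#'
#' The combined list of residues known to be critical for HokC killing
#' activity (25 positions out of L = 50), merging the positions identified by
#' saturation mutagenesis of the transmembrane region with previously
#' reported ones. Stored as the verbatim printed list and expanded at call
#' time.
#'
#' @return A [critical_residue_set()] (L = 50, 25 positions).
#' @examples
#' hokc_critical_residues()
#' @export
hokc_critical_residues <- function() {
  critical_residue_set("HokC", 50L, .hokc_positions)
}

#' Critical residues of the HIV-1 protease
#'
#' Two published criteria are available: the full mutagenesis-derived list
#' (printed as "46 residues", though the printed position list expands to 47
#' distinct positions — the package reports its own expansion and does not
#' resolve the discrepancy) and the stricter conserved-position criterion
#' (23 positions: residues that lose protease activity upon mutation to a
#' non-conservative amino acid). Protein length L = 99.
#'
#' @param conserved If `TRUE`, return the 23-residue conserved-position set;
#'   otherwise the full list.
#' @return A [critical_residue_set()].
#' @examples
#' hiv1_protease_critical_residues()
#' hiv1_protease_critical_residues(conserved = TRUE)
#' @export
hiv1_protease_critical_residues <- function(conserved = FALSE) {
  spec <- if (conserved) .hiv1_conserved_positions else .hiv1_full_positions
  critical_residue_set("HIV1-protease", 99L, spec)
}
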
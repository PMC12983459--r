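# Field constants: diagnostic positions, S1-pocket positions, reference
# lineage profiles, residue chemistry classes. All positions use
# mature-protein numbering with the catalytic threonine (Thr1) = 1.

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.NT_AMBIG <- c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

# Eight positions whose residues discriminate the ancient A and F allelic
# lineages of PSMB8.
.DIAGNOSTIC_POSITIONS <- c(13L, 99L, 147L, 150L, 156L, 188L, 189L, 194L)

# Six S1 substrate-binding-pocket positions (Thr1 tracked separately).
.S1_POCKET_POSITIONS <- c(20L, 31L, 35L, 45L, 49L, 53L)

.LINEAGE_REF_A <- c(`13` = "I", `99` = "S", `147` = "M", `150` = "E",
                    `156` = "G", `188` = "C", `189` = "K", `194` = "E")
.LINEAGE_REF_F <- c(`13` = "M", `99` = "T", `147` = "L", `150` = "P",
                    `156` = "A", `188` = "S", `189` = "Q", `194` = "D")

#' Reference diagnostic-residue profiles for the A and F lineages
#'
#' The eight diagnostic mature-protein positions (13, 99, 147, 150, 156,
#' 188, 189, 194) and the residues expected for the A lineage
#' (I, S, M, E, G, C, K, E) and the F lineage (M, T, L, P, A, S, Q, D).
#'
#' @return list with elements `A` and `F`, each a named character vector
#'   (names = mature positions).
#' @seealso [classifyLineage()], [diagnosticProfile()]
#' @export
#' @examples
#' lineageRefProfiles()$A
lineageRefProfiles <- function() {
  list(A = .LINEAGE_REF_A, F = .LINEAGE_REF_F)
}

#' Mature-protein positions used by the classifiers
#'
#' @return named list: `diagnostic` (8 lineage-diagnostic positions) and
#'   `s1Pocket` (6 S1-pocket positions, excluding Thr1).
#' @export
classifierPositions <- function() {
  list(diagnostic = .DIAGNOSTIC_POSITIONS, s1Pocket = .S1_POCKET_POSITIONS)
}

# Side-chain chemistry classes used to annotate pocket residues.
.residueClass <- function(ch) {
  vapply(ch, function(x) {
    if (is.na(x)) return(NA_character_)
    if (x %in% c("K", "R", "H")) "positive"
    else if (x %in% c("D", "E")) "negative"
    else if (x %in% c("S", "T")) "polar-hydroxyl"
    else if (x %in% c("F", "Y", "W")) "aromatic"
    else if (x %in% c("A", "G", "V", "L", "I", "M", "P", "C")) "small-nonpolar"
    else "other"
  }, character(1), USE.NAMES = FALSE)
}
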
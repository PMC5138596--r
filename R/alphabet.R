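#' The canonical 20-letter amino-acid alphabet
#'
#' Every feature module in the package indexes residues by this fixed,
#' alphabetical ordering: A, C, D, E, F, G, H, I, K, L, M, N, P, Q, R, S, T,
#' V, W, Y.  `A` has index 1 and `Y` index 20 (0-based: 0 and 19).
#'
#' @return Character vector of the 20 canonical one-letter residue codes, in
#'   the fixed order shared by all descriptor blocks.
#' @examples
#' aa_alphabet()
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Wildcard used for sanitized non-canonical residues.  Feature modules treat
# it as "no property group / no composition contribution".
AA_WILDCARD <- "X"

#' Map residues to alphabet indices
#'
#' @param residues character vector of single residues.
#' @return Integer indices in 1..20; the wildcard `X` (and anything else
#'   non-canonical) maps to `NA`.
#' @keywords internal
aa_index <- function(residues) {
  match(residues, aa_alphabet())
}

# Split a sequence string into single-residue characters.
split_residues <- function(sequence) {
  strsplit(sequence, "", fixed = TRUE)[[1]]
}
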
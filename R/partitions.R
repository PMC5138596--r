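#' Physicochemical three-group partitions of the amino-acid alphabet
#'
#' The 188-D descriptor evaluates composition/transition/distribution (CTD)
#' statistics over eight properties, each of which partitions the 20 residues
#' into three disjoint groups.  The registry below ships the classical CTD
#' partitions from the SVM-Prot / protein-fold-recognition literature
#' (hydrophobicity, polarity, polarizability, charge, secondary-structure
#' propensity, solvent accessibility, surface tension), with one exception:
#' the normalized van-der-Waals-volume grouping is the variant validated
#' against this package's worked photosystem-II example (see the methods
#' vignette), which differs from the textbook volume cut-points in placing
#' cysteine with the mid-size residues and methionine outside the largest
#' group.
#'
#' Group order within each property is fixed and is part of the descriptor
#' column ordering.
#'
#' @return A named list of 8 partitions, in registry order.  Each partition is
#'   a list with elements `name` and `groups` (a list of three character
#'   vectors of residues).
#' @seealso [extract_188()], [validate_partition()]
#' @examples
#' property_partitions()$charge
#' @export
property_partitions <- function() {
  reg <- list(
    hydrophobicity = list(
      c("R", "K", "E", "D", "Q", "N"),                      # polar
      c("G", "A", "S", "T", "P", "H", "Y"),                 # neutral
      c("C", "L", "V", "I", "M", "F", "W")                  # hydrophobic
    ),
    normalized_vdw_volume = list(
      c("C", "D", "E", "I", "L", "M", "N", "Q", "V"),
      c("A", "G", "P", "S", "T"),
      c("F", "H", "K", "R", "W", "Y")
    ),
    polarity = list(
      c("L", "I", "F", "W", "C", "M", "V", "Y"),            # low polarity
      c("P", "A", "T", "G", "S"),
      c("H", "Q", "R", "K", "N", "E", "D")                  # high polarity
    ),
    polarizability = list(
      c("G", "A", "S", "D", "T"),
      c("C", "P", "N", "V", "E", "Q", "I", "L"),
      c("K", "M", "H", "F", "R", "Y", "W")
    ),
    charge = list(
      c("K", "R"),                                          # positive
      c("A", "N", "C", "Q", "G", "H", "I", "L", "M", "F",
        "P", "S", "T", "W", "Y", "V"),                      # neutral
      c("D", "E")                                           # negative
    ),
    surface_tension = list(
      c("G", "Q", "D", "N", "A", "H", "R"),
      c("K", "T", "S", "E", "C"),
      c("I", "L", "M", "F", "P", "W", "Y", "V")
    ),
    secondary_structure = list(
      c("E", "A", "L", "M", "Q", "K", "R", "H"),            # helix
      c("V", "I", "Y", "C", "W", "F", "T"),                 # strand
      c("G", "N", "P", "S", "D")                            # coil
    ),
    solvent_accessibility = list(
      c("A", "L", "F", "C", "G", "I", "V", "W"),            # buried
      c("R", "K", "Q", "E", "N", "D"),                      # exposed
      c("M", "S", "P", "T", "H", "Y")                       # intermediate
    )
  )
  lapply(stats::setNames(names(reg), names(reg)), function(nm) {
    p <- list(name = nm, groups = reg[[nm]])
    class(p) <- "property_partition"
    p
  })
}

#' Validate a property partition
#'
#' Checks that the three groups are disjoint and jointly cover the canonical
#' 20-letter alphabet exactly.
#'
#' @param partition A partition as stored in [property_partitions()], or a
#'   bare list of three residue vectors.
#' @return The validated partition (class `property_partition`), invisibly
#'   usable downstream.  Errors describe the violation.
#' @export
validate_partition <- function(partition) {
  groups <- if (!is.null(partition$groups)) partition$groups else partition
  if (length(groups) != 3L) stop("a partition must have exactly 3 groups")
  all_res <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_res)) {
    stop("partition groups overlap: ",
         paste(unique(all_res[duplicated(all_res)]), collapse = ", "))
  }
  missing <- setdiff(aa_alphabet(), all_res)
  extra <- setdiff(all_res, aa_alphabet())
  if (length(missing) > 0L) {
    stop("partition does not cover residue(s): ", paste(missing, collapse = ", "))
  }
  if (length(extra) > 0L) {
    stop("partition contains non-canonical residue(s): ",
         paste(extra, collapse = ", "))
  }
  out <- list(name = partition$name %||% "custom", groups = groups)
  class(out) <- "property_partition"
  out
}

#' Read a partition registry from a TSV file
#'
#' The file format is a headered TSV with columns `property`, `group_index`
#' (1-3) and `residues` (a string of one-letter codes), one row per group.
#' This is the interface for validating alternate partition tables against
#' the worked example.
#'
#' @param path TSV path.
#' @return Named list of validated partitions in file order.
#' @export
read_partition_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("property", "group_index", "residues")
  if (!all(need %in% names(tab))) {
    stop("partition table must have columns: ", paste(need, collapse = ", "))
  }
  props <- unique(tab$property)
  out <- lapply(stats::setNames(props, props), function(p) {
    rows <- tab[tab$property == p, ]
    rows <- rows[order(rows$group_index), ]
    groups <- lapply(rows$residues, split_residues)
    validate_partition(list(name = p, groups = groups))
  })
  out
}

#' @export
print.property_partition <- function(x, ...) {
  cat("Property partition:", x$name, "\n")
  for (i in 1:3) {
    cat(sprintf("  group %d: %s\n", i, paste(x$groups[[i]], collapse = " ")))
  }
  invisible(x)
}
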
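#' Amino-acid composition (percent scale)
#'
#' @param sequence A single sequence: character scalar, `AAString`, or a
#'   length-one `AAStringSet`.
#' @return Named numeric vector of 20 percentages in alphabet order
#'   (`100 * count / L`).  Wildcard residues contribute nothing to any count
#'   but remain in the denominator `L`, so the components sum to 100 only for
#'   wildcard-free sequences.
#' @examples
#' aac("ACDE")
#' @export
aac <- function(sequence) {
  res <- residues_of(sequence)
  L <- length(res)
  idx <- aa_index(res)
  counts <- tabulate(idx, nbins = 20L)
  stats::setNames(100 * counts / L, aa_alphabet())
}

# Coerce the various single-sequence inputs to a residue character vector.
residues_of <- function(sequence) {
  if (methods::is(sequence, "AAStringSet")) {
    if (length(sequence) != 1L) stop("expected a single sequence")
    sequence <- as.character(sequence)[[1L]]
  } else if (methods::is(sequence, "AAString")) {
    sequence <- as.character(sequence)
  }
  if (!is.character(sequence) || length(sequence) != 1L) {
    stop("expected a single sequence string")
  }
  if (nchar(sequence) == 0L) stop("empty sequence")
  split_residues(toupper(sequence))
}

#' Encode a sequence as property-group indices
#'
#' @inheritParams aac
#' @param partition A `property_partition` (see [property_partitions()]).
#' @return Integer vector of length `L` with values in 1..3; wildcard (or any
#'   non-canonical) residues are encoded as 0 and ignored by all CTD counts.
#' @export
encode_groups <- function(sequence, partition) {
  partition <- validate_partition(partition)
  res <- residues_of(sequence)
  map <- integer(20L)
  for (g in 1:3) map[aa_index(partition$groups[[g]])] <- g
  idx <- aa_index(res)
  out <- integer(length(res))
  known <- !is.na(idx)
  out[known] <- map[idx[known]]
  out
}

#' CTD composition: percentage of residues in each property group
#'
#' @inheritParams encode_groups
#' @return Numeric vector `c(C1, C2, C3)` with `Cj = 100 * n_j / L`.
#' @export
ctd_composition <- function(sequence, partition) {
  g <- encode_groups(sequence, partition)
  100 * tabulate(g, nbins = 3L) / length(g)
}

#' CTD transition: percentage of adjacent residue pairs crossing groups
#'
#' For the unordered group pairs (1,2), (1,3), (2,3),
#' `T_jk = 100 * (N_jk + N_kj) / (L - 1)` where `N_jk` counts adjacent
#' positions with group `j` followed by group `k`.  Pairs involving a
#' wildcard are not counted; the denominator stays `L - 1`.
#'
#' @inheritParams encode_groups
#' @return Numeric vector of the three transition percentages in the fixed
#'   pair order (1,2), (1,3), (2,3).  A length-1 sequence yields `c(0,0,0)`
#'   by convention, with a message.
#' @export
ctd_transition <- function(sequence, partition) {
  g <- encode_groups(sequence, partition)
  L <- length(g)
  if (L < 2L) {
    message("sequence of length 1: all transition features set to 0")
    return(c(0, 0, 0))
  }
  a <- g[-L]
  b <- g[-1L]
  keep <- a > 0L & b > 0L
  a <- a[keep]; b <- b[keep]
  n <- function(j, k) sum((a == j & b == k) | (a == k & b == j))
  100 * c(n(1L, 2L), n(1L, 3L), n(2L, 3L)) / (L - 1L)
}

#' CTD distribution: relative positions of group occurrence quantiles
#'
#' For each group the five descriptors locate the first, 25%, 50%, 75% and
#' 100% (last) occurrence of that group along the chain, each reported as
#' `100 * position / L`.  The q-th occurrence index is
#' `max(1, ceiling(f * n_j))` for `f` in 0, .25, .5, .75, 1.  A group with no
#' occurrences yields five zeros.
#'
#' @inheritParams encode_groups
#' @return Numeric vector of 15 percentages, group-major (group 1's five
#'   quantiles, then group 2's, then group 3's).
#' @export
ctd_distribution <- function(sequence, partition) {
  g <- encode_groups(sequence, partition)
  L <- length(g)
  fracs <- c(0, 0.25, 0.5, 0.75, 1)
  out <- numeric(15L)
  for (j in 1:3) {
    pos <- which(g == j)
    n_j <- length(pos)
    if (n_j > 0L) {
      q <- pmax(1L, ceiling(fracs * n_j))
      out[(j - 1L) * 5L + 1:5] <- 100 * pos[q] / L
    }
  }
  out
}

ctd_feature_names <- function() {
  quant <- c("first", "q25", "q50", "q75", "q100")
  unlist(lapply(names(property_partitions()), function(p) {
    c(paste0(p, ".C", 1:3),
      paste0(p, ".T", c("1_2", "1_3", "2_3")),
      paste0(p, ".D", rep(1:3, each = 5L), ".", rep(quant, times = 3L)))
  }), use.names = FALSE)
}

#' Extract the 188-dimensional SVM-Prot descriptor
#'
#' Concatenates the 20 amino-acid-composition percentages with, for each of
#' the eight physicochemical property partitions in registry order, a
#' 21-component CTD block: composition (3), transition (3, pair order (1,2),
#' (1,3), (2,3)) and distribution (15, group-major, five quantile points per
#' group).  All components are on the percent scale.
#'
#' @inheritParams aac
#' @param partitions Partition registry; defaults to [property_partitions()].
#' @return Named numeric vector of length 188 (`20 + 8 * 21`).
#' @examples
#' length(extract_188("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"))
#' @export
extract_188 <- function(sequence, partitions = property_partitions()) {
  if (length(partitions) != 8L) {
    stop("the 188-D descriptor requires exactly 8 property partitions")
  }
  blocks <- lapply(partitions, function(p) {
    c(ctd_composition(sequence, p),
      ctd_transition(sequence, p),
      ctd_distribution(sequence, p))
  })
  v <- c(aac(sequence), unlist(blocks, use.names = FALSE))
  names(v) <- c(paste0("AAC.", aa_alphabet()), ctd_feature_names())
  v
}

#' Extract 188-D descriptors for a set of records
#'
#' @param records An `AAStringSet` or named character vector of sequences.
#' @inheritParams extract_188
#' @return Numeric matrix, one row per record (rownames = ids), 188 named
#'   columns in the fixed descriptor order.
#' @export
extract_188_batch <- function(records, partitions = property_partitions()) {
  records <- as_protein_set(records, allow_empty = TRUE)
  cols <- c(paste0("AAC.", aa_alphabet()), ctd_feature_names())
  if (length(records) == 0L) {
    return(matrix(numeric(0), nrow = 0L, ncol = 188L,
                  dimnames = list(NULL, cols)))
  }
  seqs <- as.character(records)
  m <- t(vapply(seqs, extract_188, numeric(188L), partitions = partitions))
  dimnames(m) <- list(names(records), cols)
  m
}

#' Write a feature matrix as headered TSV
#'
#' First column `id`, then one named column per descriptor component.
#'
#' @param features Numeric matrix with rownames (record ids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  df <- data.frame(id = rownames(features), features,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_features()]
#'
#' @param path TSV path.
#' @return Numeric matrix with rownames taken from the `id` column.
#' @export
read_features <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "id") stop("feature table must start with an 'id' column")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$id
  m
}
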
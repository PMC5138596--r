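#' Pairwise sequence identity
#'
#' Identity between two protein sequences, defined as the number of identical
#' aligned positions in an identity-maximizing global alignment (match = 1,
#' mismatch = 0, linear gap penalty 1) divided by the length of the shorter
#' sequence.  This is the convention used by greedy incremental clustering
#' tools for redundancy removal.
#'
#' @param a,b Sequences (character scalars, `AAString`, or length-one
#'   `AAStringSet`).
#' @return Identity fraction in `[0, 1]`; symmetric in its arguments.
#' @export
pairwise_identity <- function(a, b) {
  a <- paste(residues_of(a), collapse = "")
  b <- paste(residues_of(b), collapse = "")
  n_match <- alignment_matches(a, b)
  n_match / min(nchar(a), nchar(b))
}

# Matches in the identity-maximizing global alignment of one pattern set
# against one subject.  Vectorized over `patterns`.
alignment_matches <- function(patterns, subject) {
  letters_all <- c(aa_alphabet(), AA_WILDCARD)
  sub_mat <- matrix(0L, nrow = length(letters_all), ncol = length(letters_all),
                    dimnames = list(letters_all, letters_all))
  diag(sub_mat) <- 1L
  sub_mat[AA_WILDCARD, AA_WILDCARD] <- 0L  # wildcards never count as matches
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(patterns),
    subject = subject,
    type = "global",
    substitutionMatrix = sub_mat,
    gapOpening = 0,
    gapExtension = 1
  )
  Biostrings::nmatch(aln)
}

#' Greedy incremental clustering at an identity threshold
#'
#' Records are sorted by decreasing length (ties broken by id,
#' lexicographically) and processed sequentially: each record joins the first
#' existing cluster whose representative it matches at or above `threshold`
#' identity, otherwise it founds a new cluster.  Representatives are the
#' longest (first-processed) member of each cluster.  The procedure is
#' deterministic for a given input.
#'
#' @param records An `AAStringSet` or named character vector.
#' @param threshold Identity threshold in `(0, 1]` (default 0.70).
#' @return An object of class `protein_clusters`: a list of clusters, each a
#'   list with `representative` (id), `members` (ids, representative first)
#'   and `identities` (member-to-representative identity fractions).
#' @details Greedy clustering guarantees every removed sequence is within
#'   `threshold` of its representative, but not that all representative
#'   pairs fall below the threshold.  Cost is O(n_records x n_clusters)
#'   alignments, each O(L^2); no k-mer prefilter is applied, which is
#'   adequate at desk scale.
#' @export
cluster_greedy <- function(records, threshold = 0.70) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]")
  }
  records <- as_protein_set(records, allow_empty = TRUE)
  if (length(records) == 0L) {
    return(structure(list(), class = "protein_clusters",
                     threshold = threshold))
  }
  lens <- Biostrings::width(records)
  ord <- order(-lens, names(records), method = "radix")
  seqs <- as.character(records)[ord]
  ids <- names(records)[ord]
  lens <- lens[ord]

  rep_seq <- character(0)
  rep_len <- integer(0)
  clusters <- list()
  for (i in seq_along(seqs)) {
    assigned <- FALSE
    if (length(rep_seq) > 0L) {
      ident <- alignment_matches(rep_seq, seqs[i]) / pmin(rep_len, lens[i])
      hit <- which(ident >= threshold)
      if (length(hit) > 0L) {
        k <- hit[1L]  # first existing cluster wins
        clusters[[k]]$members <- c(clusters[[k]]$members, ids[i])
        clusters[[k]]$identities <- c(clusters[[k]]$identities, ident[k])
        assigned <- TRUE
      }
    }
    if (!assigned) {
      clusters[[length(clusters) + 1L]] <- list(
        representative = ids[i],
        members = ids[i],
        identities = 1.0
      )
      rep_seq <- c(rep_seq, seqs[i])
      rep_len <- c(rep_len, lens[i])
    }
  }
  structure(clusters, class = "protein_clusters", threshold = threshold)
}

#' @export
print.protein_clusters <- function(x, ...) {
  cat(sprintf("%d cluster(s) at identity threshold %.2f\n",
              length(x), attr(x, "threshold")))
  sizes <- vapply(x, function(cl) length(cl$members), integer(1L))
  if (length(sizes)) {
    cat("cluster sizes:", paste(sizes, collapse = " "), "\n")
  }
  invisible(x)
}

#' Remove redundant sequences, keeping one representative per cluster
#'
#' @inheritParams cluster_greedy
#' @return The subset of `records` that are cluster representatives, in
#'   cluster order.  The clustering is attached as attribute `"clusters"`.
#' @examples
#' recs <- c(a = "MKTAYIAKQR", b = "MKTAYIAKQR", c = "WWWWPPPPGG")
#' names(dereplicate(recs, threshold = 0.7))
#' @export
dereplicate <- function(records, threshold = 0.70) {
  records <- as_protein_set(records, allow_empty = TRUE)
  cl <- cluster_greedy(records, threshold)
  reps <- vapply(cl, function(c) c$representative, character(1L))
  out <- records[reps]
  attr(out, "clusters") <- cl
  out
}

#' Write a cluster report as TSV
#'
#' Columns: `cluster_id`, `representative_id`, `member_id`, `identity`.
#'
#' @param clusters A `protein_clusters` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_report <- function(clusters, path) {
  rows <- do.call(rbind, lapply(seq_along(clusters), function(k) {
    cl <- clusters[[k]]
    data.frame(cluster_id = k,
               representative_id = cl$representative,
               member_id = cl$members,
               identity = cl$identities,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(cluster_id = integer(0), representative_id = character(0),
                       member_id = character(0), identity = numeric(0))
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
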
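#' Read protein sequences from a FASTA file
#'
#' Sequences are upper-cased and sanitized against the canonical 20-letter
#' alphabet.  The returned container is a [Biostrings::AAStringSet] whose
#' `names()` are the record ids (first whitespace-delimited token of each
#' header); the remainder of each header is kept as a `description` column in
#' `S4Vectors::mcols()`.
#'
#' @param path Path to a FASTA file.
#' @param sanitize Policy for non-canonical residues (B, J, O, U, X, Z, `*`,
#'   gap characters, ...): `"map_to_x"` (default) replaces each offending
#'   residue by the wildcard `X`, which downstream feature modules exclude
#'   from all counts; `"strict"` raises an error naming the first offending
#'   residue and record; `"drop_record"` silently excludes offending records
#'   and reports how many were dropped via the `"n_dropped"` attribute.
#' @return An `AAStringSet` of sanitized records, in file order.  Attribute
#'   `"n_dropped"` gives the number of records removed under `"drop_record"`.
#' @details Duplicate record ids are an error: downstream label joins must be
#'   unambiguous.  Empty files and empty sequences are errors.
#' @seealso [write_fasta()], [load_labels()]
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 toy", "ACDE"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, sanitize = c("map_to_x", "strict", "drop_record")) {
  sanitize <- match.arg(sanitize)
  if (!file.exists(path)) {
    stop("FASTA file does not exist: ", path)
  }
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ", conditionMessage(e))
  )
  if (length(set) == 0L) {
    stop("empty FASTA file: ", path)
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for record(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }

  ok_pattern <- paste0("^[", paste(aa_alphabet(), collapse = ""), "]*$")
  clean <- grepl(ok_pattern, seqs)
  n_dropped <- 0L
  if (!all(clean)) {
    if (sanitize == "strict") {
      bad_id <- ids[!clean][1L]
      bad_seq <- seqs[!clean][1L]
      bad_res <- setdiff(split_residues(bad_seq), aa_alphabet())[1L]
      stop("non-canonical residue '", bad_res, "' in record '", bad_id,
           "' under sanitize = \"strict\"")
    } else if (sanitize == "drop_record") {
      n_dropped <- sum(!clean)
      ids <- ids[clean]
      desc <- desc[clean]
      seqs <- seqs[clean]
      if (length(seqs) == 0L) {
        stop("all records dropped by sanitize = \"drop_record\"")
      }
    } else {
      bad_chr <- paste0("[^", paste(aa_alphabet(), collapse = ""), "]")
      seqs <- gsub(bad_chr, AA_WILDCARD, seqs)
    }
  }

  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out)$description <- desc
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write protein sequences to canonical FASTA
#'
#' @param records An `AAStringSet` (as returned by [read_fasta()]) or a named
#'   character vector of sequences.
#' @param path Output path.
#' @param width Line width for sequence wrapping (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  records <- as_protein_set(records, allow_empty = TRUE)
  desc <- S4Vectors::mcols(records)$description
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(records) == 0L) {
    return(invisible(path))
  }
  seqs <- as.character(records)
  ids <- names(records)
  headers <- if (is.null(desc)) ids else ifelse(nzchar(desc), paste(ids, desc), ids)
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", headers[i]), con)
    s <- seqs[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coerce sequences to the package's record container
#'
#' Accepts an `AAStringSet` or a named character vector and returns an
#' `AAStringSet` with unique non-empty names.
#'
#' @param x Sequences.
#' @param allow_empty Permit a zero-length set.
#' @return An `AAStringSet`.
#' @keywords internal
as_protein_set <- function(x, allow_empty = FALSE) {
  if (is.character(x)) {
    if (is.null(names(x)) && length(x) > 0L) {
      names(x) <- paste0("seq", seq_along(x))
    }
    x <- Biostrings::AAStringSet(x)
  }
  if (!methods::is(x, "AAStringSet")) {
    stop("records must be an AAStringSet or a character vector of sequences")
  }
  if (!allow_empty && length(x) == 0L) {
    stop("no records supplied")
  }
  if (length(x) > 0L) {
    if (is.null(names(x)) || any(!nzchar(names(x)))) {
      stop("all records must be named (unique ids)")
    }
    if (anyDuplicated(names(x))) {
      stop("duplicate record id(s): ",
           paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
    }
  }
  x
}

#' Build a label table from a positive and a negative id source
#'
#' Each source may be a FASTA file (ids are taken from the headers) or a
#' plain text file with one id per line.  Positives are the R-gene class.
#'
#' @param pos_path,neg_path Paths to the positive / negative sources.
#' @return A data.frame with columns `id` and `label`
#'   (`"R-gene"` / `"non-R-gene"`), one row per id.
#' @details An id present in both sources is a conflict and raises an error.
#' @export
load_labels <- function(pos_path, neg_path) {
  pos_ids <- read_id_source(pos_path)
  neg_ids <- read_id_source(neg_path)
  both <- intersect(pos_ids, neg_ids)
  if (length(both) > 0L) {
    stop("id(s) present in both label sources: ",
         paste(utils::head(both, 5L), collapse = ", "))
  }
  data.frame(
    id = c(pos_ids, neg_ids),
    label = c(rep("R-gene", length(pos_ids)), rep("non-R-gene", length(neg_ids))),
    stringsAsFactors = FALSE
  )
}

read_id_source <- function(path) {
  if (!file.exists(path)) stop("label source does not exist: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  ids <- if (length(first) && startsWith(first, ">")) {
    lines <- readLines(path, warn = FALSE)
    sub("\\s.*$", "", sub("^>", "", lines[startsWith(lines, ">")]))
  } else {
    lines <- trimws(readLines(path, warn = FALSE))
    lines[nzchar(lines)]
  }
  if (anyDuplicated(ids)) {
    stop("duplicate id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  ids
}

#' Read / write a two-column label table
#'
#' Headered TSV with columns `id` and `label`; labels are `"R-gene"` or
#' `"non-R-gene"`.
#'
#' @param path File path.
#' @return `read_label_table()` returns the label data.frame;
#'   `write_label_table()` returns `path` invisibly.
#' @export
read_label_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% names(tab))) {
    stop("label table must have columns 'id' and 'label'")
  }
  bad <- setdiff(unique(tab$label), c("R-gene", "non-R-gene"))
  if (length(bad) > 0L) {
    stop("unknown label(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(tab$id)) stop("duplicate id(s) in label table")
  tab[, c("id", "label")]
}

#' @rdname read_label_table
#' @param labels Label data.frame as returned by [load_labels()].
#' @export
write_label_table <- function(labels, path) {
  utils::write.table(labels[, c("id", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
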
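#' Standard residue property scales for Pse-AAC
#'
#' The classical type-I pseudo amino acid composition correlates residues
#' through three physicochemical scales: hydrophobicity, hydrophilicity
#' (Hopp-Woods) and side-chain mass.  Raw values are returned; they are
#' standardized to zero mean / unit variance over the 20 residues inside
#' [pseaac_config()], so the correlation function is unit-free.
#'
#' @return Numeric matrix, 3 rows (`hydrophobicity`, `hydrophilicity`,
#'   `side_chain_mass`) by 20 columns in alphabet order.
#' @export
pseaac_scales <- function() {
  h1 <- c(A =  0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19,
          G =  0.48, H = -0.40, I = 1.38, K = -1.50, L = 1.06,
          M =  0.64, N = -0.78, P = 0.12, Q = -0.85, R = -2.53,
          S = -0.18, T = -0.05, V = 1.08, W = 0.81, Y = 0.26)
  h2 <- c(A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5,
          G =  0.0, H = -0.5, I = -1.8, K = 3.0, L = -1.8,
          M = -1.3, N =  0.2, P = 0.0, Q = 0.2, R = 3.0,
          S =  0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3)
  m  <- c(A = 15, C = 47, D = 59, E = 73, F = 91,
          G =  1, H = 82, I = 57, K = 73, L = 57,
          M = 75, N = 58, P = 42, Q = 72, R = 101,
          S = 31, T = 45, V = 43, W = 130, Y = 107)
  rbind(hydrophobicity = h1[aa_alphabet()],
        hydrophilicity = h2[aa_alphabet()],
        side_chain_mass = m[aa_alphabet()])
}

#' Configuration for pseudo amino acid composition
#'
#' @param lambda Non-negative integer: the highest correlation rank (lag)
#'   included.  The descriptor has `20 + lambda` components; the default
#'   `lambda = 10` gives the 30-dimensional vector used throughout this
#'   package.
#' @param omega Positive weight factor balancing the sequence-order
#'   correlation terms against the composition terms (default 0.05).
#' @param scales Numeric matrix of per-residue property values, one row per
#'   property, 20 columns in alphabet order.  Each row is standardized to
#'   zero mean and unit (population) variance over the 20 residues.
#' @return A `pseaac_config` object.
#' @export
pseaac_config <- function(lambda = 10L, omega = 0.05, scales = pseaac_scales()) {
  lambda <- as.integer(lambda)
  if (is.na(lambda) || lambda < 0L) stop("lambda must be a non-negative integer")
  if (!is.numeric(omega) || length(omega) != 1L || omega <= 0) {
    stop("omega must be a positive number")
  }
  if (!is.matrix(scales) || ncol(scales) != 20L) {
    stop("scales must be a numeric matrix with 20 columns (alphabet order)")
  }
  std <- t(apply(scales, 1L, function(v) {
    (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  }))
  colnames(std) <- aa_alphabet()
  structure(list(lambda = lambda, omega = omega, scales = std),
            class = "pseaac_config")
}

# Mean over the property set of squared differences of standardized values,
# for residue index vectors a, b (1..20).  Symmetric by construction.
theta_pairs <- function(a, b, scales) {
  d2 <- (scales[, a, drop = FALSE] - scales[, b, drop = FALSE])^2
  colMeans(d2)
}

#' Sequence-order correlation factor
#'
#' `e_j = mean_i Theta(r_i, r_(i+j))` over all residue pairs at lag `j`,
#' where `Theta` averages squared differences of the standardized property
#' values.  Pairs involving a wildcard residue are excluded from both the sum
#' and the denominator.
#'
#' @inheritParams aac
#' @param j Lag, `1 <= j < L`.
#' @param config A [pseaac_config()].
#' @return The correlation factor `e_j` (non-negative scalar).
#' @export
correlation_factor <- function(sequence, j, config = pseaac_config()) {
  res <- residues_of(sequence)
  L <- length(res)
  j <- as.integer(j)
  if (j < 1L) stop("lag j must be >= 1")
  if (L <= j) stop("sequence shorter than lag: L = ", L, ", j = ", j)
  idx <- aa_index(res)
  a <- idx[seq_len(L - j)]
  b <- idx[seq_len(L - j) + j]
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) return(0)
  # denominator is the number of scored pairs (wildcard pairs excluded)
  mean(theta_pairs(a[keep], b[keep], config$scales))
}

#' Extract the type-I pseudo amino acid composition vector
#'
#' The first 20 components are normalized residue frequencies; components
#' `20 + 1 .. 20 + lambda` carry the lag-j correlation factors weighted by
#' `omega`.  All components share the denominator
#' `sum(f) + omega * sum(e_j)`, so the vector sums to 1.
#'
#' @inheritParams correlation_factor
#' @return Named numeric vector of length `20 + lambda`.
#' @examples
#' v <- extract_pseaac(paste(rep("ACDEFGHIKL", 5), collapse = ""))
#' length(v)  # 30 with the default lambda = 10
#' sum(v)     # 1
#' @export
extract_pseaac <- function(sequence, config = pseaac_config()) {
  res <- residues_of(sequence)
  L <- length(res)
  if (L <= config$lambda) {
    stop("sequence shorter than lambda: L = ", L,
         ", lambda = ", config$lambda)
  }
  idx <- aa_index(res)
  if (all(is.na(idx))) stop("sequence contains no canonical residues")
  f <- tabulate(idx[!is.na(idx)], nbins = 20L) / L
  e <- if (config$lambda > 0L) {
    vapply(seq_len(config$lambda), correlation_factor, numeric(1L),
           sequence = sequence, config = config)
  } else {
    numeric(0L)
  }
  denom <- sum(f) + config$omega * sum(e)
  v <- c(f, config$omega * e) / denom
  names(v) <- c(paste0("f.", aa_alphabet()),
                if (config$lambda > 0L) paste0("e.", seq_len(config$lambda)))
  v
}

#' Extract Pse-AAC vectors for a set of records
#'
#' @param records An `AAStringSet` or named character vector.
#' @inheritParams extract_pseaac
#' @return Numeric matrix, one row per record, `20 + lambda` named columns.
#' @export
extract_pseaac_batch <- function(records, config = pseaac_config()) {
  records <- as_protein_set(records, allow_empty = TRUE)
  p <- 20L + config$lambda
  cols <- c(paste0("f.", aa_alphabet()),
            if (config$lambda > 0L) paste0("e.", seq_len(config$lambda)))
  if (length(records) == 0L) {
    return(matrix(numeric(0), nrow = 0L, ncol = p, dimnames = list(NULL, cols)))
  }
  seqs <- as.character(records)
  m <- t(vapply(seqs, extract_pseaac, numeric(p), config = config))
  dimnames(m) <- list(names(records), cols)
  m
}
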
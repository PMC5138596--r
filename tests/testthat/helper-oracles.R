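# Independent brute-force oracles and fixtures shared across the suite.
# These deliberately use naive explicit loops, never the package's own
# vectorized code paths.

random_sequence <- function(L, residues = aa_alphabet()) {
  paste(sample(residues, L, replace = TRUE), collapse = "")
}

# --- CTD oracles -----------------------------------------------------------

oracle_group_of <- function(res, partition) {
  for (g in 1:3) {
    if (res %in% partition$groups[[g]]) return(g)
  }
  0L
}

oracle_ctd_c <- function(sequence, partition) {
  res <- strsplit(sequence, "")[[1]]
  n <- c(0, 0, 0)
  for (r in res) {
    g <- oracle_group_of(r, partition)
    if (g > 0) n[g] <- n[g] + 1
  }
  100 * n / length(res)
}

oracle_ctd_t <- function(sequence, partition) {
  res <- strsplit(sequence, "")[[1]]
  L <- length(res)
  if (L < 2) return(c(0, 0, 0))
  n12 <- n13 <- n23 <- 0
  for (i in 1:(L - 1)) {
    a <- oracle_group_of(res[i], partition)
    b <- oracle_group_of(res[i + 1], partition)
    if (a == 0 || b == 0) next
    pair <- sort(c(a, b))
    if (pair[1] == 1 && pair[2] == 2) n12 <- n12 + 1
    if (pair[1] == 1 && pair[2] == 3) n13 <- n13 + 1
    if (pair[1] == 2 && pair[2] == 3) n23 <- n23 + 1
  }
  100 * c(n12, n13, n23) / (L - 1)
}

oracle_ctd_d <- function(sequence, partition) {
  res <- strsplit(sequence, "")[[1]]
  L <- length(res)
  out <- numeric(15)
  for (g in 1:3) {
    pos <- c()
    for (i in seq_len(L)) {
      if (oracle_group_of(res[i], partition) == g) pos <- c(pos, i)
    }
    if (length(pos) > 0) {
      n <- length(pos)
      idx <- sapply(c(0, 0.25, 0.5, 0.75, 1), function(f) max(1, ceiling(f * n)))
      out[(g - 1) * 5 + 1:5] <- 100 * pos[idx] / L
    }
  }
  out
}

# --- Pse-AAC correlation oracle -------------------------------------------

oracle_correlation <- function(sequence, j, config) {
  res <- strsplit(sequence, "")[[1]]
  L <- length(res)
  total <- 0
  count <- 0
  for (i in 1:(L - j)) {
    a <- match(res[i], aa_alphabet())
    b <- match(res[i + j], aa_alphabet())
    if (is.na(a) || is.na(b)) next
    th <- 0
    for (k in seq_len(nrow(config$scales))) {
      th <- th + (config$scales[k, a] - config$scales[k, b])^2
    }
    total <- total + th / nrow(config$scales)
    count <- count + 1
  }
  if (count == 0) 0 else total / count
}

# --- Global alignment score oracle (Needleman-Wunsch) ----------------------
# match = 1, mismatch = 0, linear gap penalty 1 (same scoring as the
# implementation's alignment engine); returns the optimal score.

oracle_alignment_score <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -(0:n)
  S[1, ] <- -(0:m)
  for (i in 1:n) {
    for (j in 1:m) {
      S[i + 1, j + 1] <- max(S[i, j] + as.integer(x[i] == y[j]),
                             S[i, j + 1] - 1,
                             S[i + 1, j] - 1)
    }
  }
  S[n + 1, m + 1]
}

# --- ROC area oracle: all-pairs concordance --------------------------------

oracle_roc_area <- function(labels, scores) {
  pos <- scores[labels == "R-gene"]
  neg <- scores[labels == "non-R-gene"]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# --- Worked-example fixture ------------------------------------------------
# Residue counts of a 363-residue photosystem-II D1 protein used as the
# package's descriptor worked example, plus the expected order-free
# descriptor values.  Any permutation of the residues has the same AAC and
# composition triples.

psba1_counts <- function() {
  c(A = 34, C = 1, D = 6, E = 13, F = 22, G = 31, H = 14, I = 26, K = 3,
    L = 44, M = 17, N = 13, P = 18, Q = 10, R = 12, S = 34, T = 25, V = 20,
    W = 10, Y = 10)
}

psba1_sequence <- function(seed = 1) {
  counts <- psba1_counts()
  res <- rep(names(counts), counts)
  set.seed(seed)
  paste(sample(res), collapse = "")
}

psba1_expected_aac <- function() {
  c(9.3664, 0.2755, 1.6529, 3.5813, 6.0606, 8.5399, 3.8567, 7.1625, 0.8264,
    12.1212, 4.6832, 3.5813, 4.9587, 2.7548, 3.3058, 9.3664, 6.8871, 5.5096,
    2.7548, 2.7548)
}

psba1_expected_hydro_c <- function() c(15.7025, 45.7300, 38.5675)
psba1_expected_vdw_c <- function() c(41.3223, 39.1185, 19.5592)

# --- Small dataset builders ------------------------------------------------

toy_separable_dataset <- function(n_per_class = 50, seed = 1) {
  set.seed(seed)
  pos <- matrix(rnorm(2 * n_per_class, mean = 1, sd = 0.1), ncol = 2)
  neg <- matrix(rnorm(2 * n_per_class, mean = 0, sd = 0.1), ncol = 2)
  m <- rbind(pos, neg)
  colnames(m) <- c("x", "y")
  rownames(m) <- paste0("i", seq_len(nrow(m)))
  labeled_dataset(m, rep(c("R-gene", "non-R-gene"), each = n_per_class))
}

synthetic_feature_dataset <- function(n_pos, n_neg, effect, seed) {
  d <- generate_dataset(generator_config(n_pos, n_neg, effect = effect,
                                         seed = seed))
  labeled_dataset(extract_188_batch(d$records), d$labels$label)
}
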
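#' Background amino-acid frequencies
#'
#' Average residue frequencies of well-annotated protein databases, used as
#' the default emission distribution of the synthetic generator.  Values are
#' normalized to sum to 1.
#'
#' @return Named numeric vector of 20 probabilities in alphabet order.
#' @export
background_frequencies <- function() {
  f <- c(A = 8.3, C = 1.4, D = 5.5, E = 6.7, F = 3.9,
         G = 7.1, H = 2.3, I = 5.9, K = 5.8, L = 9.6,
         M = 2.4, N = 4.1, P = 4.7, Q = 3.9, R = 5.5,
         S = 6.7, T = 5.4, V = 6.9, W = 1.1, Y = 2.9)
  f / sum(f)
}

#' Configuration for the synthetic two-class sequence generator
#'
#' Positive-class residues are drawn i.i.d. from the base distribution with a
#' total-variation shift of size `effect` toward `target_residues`; negatives
#' are drawn from the base itself.  `effect = 0` makes the two classes
#' identically distributed (the no-signal null); the maximum feasible effect
#' is `1 - sum(base[target_residues])`.
#'
#' @param n_pos,n_neg Number of positive / negative records.
#' @param effect Total-variation distance in `[0, 1)` between the class
#'   emission distributions.
#' @param seed Integer seed; generation is deterministic per seed.
#' @param target_residues Residue subset receiving the shifted mass.
#' @param base Base emission distribution (20 probabilities, alphabet order).
#' @param length_meanlog,length_sdlog Log-normal length parameters; lengths
#'   are rounded and clipped to `length_range`.
#' @param length_range Two-element integer range of admissible lengths.
#' @return A `generator_config` object.
#' @export
generator_config <- function(n_pos, n_neg, effect = 0, seed = 1L,
                             target_residues = c("K", "R", "C", "W"),
                             base = background_frequencies(),
                             length_meanlog = log(250), length_sdlog = 0.5,
                             length_range = c(50L, 1000L)) {
  if (!is.numeric(base) || length(base) != 20L || any(base < 0)) {
    stop("base must be 20 non-negative probabilities")
  }
  if (abs(sum(base) - 1) > 1e-8) stop("base probabilities must sum to 1")
  names(base) <- aa_alphabet()
  if (!all(target_residues %in% aa_alphabet())) {
    stop("target_residues must be canonical residues")
  }
  p_s <- sum(base[target_residues])
  if (effect < 0 || effect > 1 - p_s + 1e-12) {
    stop(sprintf("effect must lie in [0, %.4f] for this base/target choice",
                 1 - p_s))
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 effect = effect, seed = as.integer(seed),
                 target_residues = target_residues, base = base,
                 length_meanlog = length_meanlog, length_sdlog = length_sdlog,
                 length_range = as.integer(length_range)),
            class = "generator_config")
}

#' Class emission distributions implied by a generator config
#'
#' @param config A [generator_config()].
#' @return List with `positive` and `negative` probability vectors; the
#'   total-variation distance between them equals `config$effect`.
#' @export
class_emissions <- function(config) {
  base <- config$base
  s <- names(base) %in% config$target_residues
  p_s <- sum(base[s])
  q <- base
  if (config$effect > 0) {
    q[s] <- base[s] * (1 + config$effect / p_s)
    q[!s] <- base[!s] * (1 - config$effect / (1 - p_s))
  }
  list(positive = q, negative = base)
}

rand_lengths <- function(n, config) {
  L <- round(stats::rlnorm(n, config$length_meanlog, config$length_sdlog))
  pmin(pmax(L, config$length_range[1L]), config$length_range[2L])
}

rand_sequences <- function(n, probs, config, prefix) {
  lens <- rand_lengths(n, config)
  seqs <- vapply(lens, function(L) {
    paste(sample(aa_alphabet(), L, replace = TRUE, prob = probs), collapse = "")
  }, character(1L))
  names(seqs) <- sprintf("%s%04d", prefix, seq_len(n))
  seqs
}

#' Generate a labeled synthetic two-class dataset
#'
#' @param config A [generator_config()].
#' @return List with `records` (an `AAStringSet`, positives first) and
#'   `labels` (data.frame `id`, `label`).
#' @examples
#' d <- generate_dataset(generator_config(n_pos = 5, n_neg = 5, effect = 0.3,
#'                                        seed = 42))
#' table(d$labels$label)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  em <- class_emissions(config)
  old <- .Random.seed_exists()
  set.seed(config$seed)
  pos <- rand_sequences(config$n_pos, em$positive, config, "POS")
  neg <- rand_sequences(config$n_neg, em$negative, config, "NEG")
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  records <- Biostrings::AAStringSet(c(pos, neg))
  S4Vectors::mcols(records)$description <- rep("synthetic", length(records))
  labels <- data.frame(
    id = names(records),
    label = rep(c("R-gene", "non-R-gene"), c(config$n_pos, config$n_neg)),
    stringsAsFactors = FALSE
  )
  list(records = records, labels = labels)
}

#' Generate redundant sequence families for clustering tests
#'
#' Each family consists of one ancestor drawn from the base distribution plus
#' mutated copies in which every site is independently substituted (by a
#' residue drawn from the base, possibly identical) with probability
#' `mutation_rate`.  Expected within-family identity is approximately
#' `1 - mutation_rate * (1 - mean(base^2))`.
#'
#' @param n_families Number of families.
#' @param copies_per_family Records per family (ancestor + copies).
#' @param mutation_rate Per-site substitution probability in `[0, 1]`.
#' @param seed Integer seed.
#' @param config Optional [generator_config()] supplying base distribution
#'   and length model (its class-signal fields are ignored).  The default
#'   draws ancestors in a narrow length band (log-normal around 200
#'   residues, sdlog 0.15): identity uses the shorter sequence as
#'   denominator, so grossly unequal lengths would let long random
#'   sequences absorb short ones; comparable lengths keep between-family
#'   identity far below usual clustering thresholds.
#' @return An `AAStringSet`; ids are `FAM<i>_<j>` with `j = 1` the ancestor.
#' @export
generate_redundant_families <- function(n_families, copies_per_family,
                                        mutation_rate, seed = 1L,
                                        config = generator_config(
                                          1L, 1L, seed = seed,
                                          length_meanlog = log(200),
                                          length_sdlog = 0.15)) {
  stopifnot(mutation_rate >= 0, mutation_rate <= 1)
  base <- config$base
  old <- .Random.seed_exists()
  set.seed(as.integer(seed))
  out <- character(0)
  for (i in seq_len(n_families)) {
    L <- rand_lengths(1L, config)
    ancestor <- sample(aa_alphabet(), L, replace = TRUE, prob = base)
    fam <- vapply(seq_len(copies_per_family), function(j) {
      s <- ancestor
      if (j > 1L && mutation_rate > 0) {
        hit <- stats::runif(L) < mutation_rate
        if (any(hit)) {
          s[hit] <- sample(aa_alphabet(), sum(hit), replace = TRUE, prob = base)
        }
      }
      paste(s, collapse = "")
    }, character(1L))
    names(fam) <- sprintf("FAM%d_%d", i, seq_len(copies_per_family))
    out <- c(out, fam)
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  Biostrings::AAStringSet(out)
}
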
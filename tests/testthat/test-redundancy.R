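test_that("pairwise identity is exact on crafted cases and symmetric", {
  expect_equal(pairwise_identity("ACDEFG", "ACDEFG"), 1.0)
  expect_equal(pairwise_identity("AAAA", "CCCC"), 0.0)
  # shorter-sequence denominator: a perfect prefix counts as full identity
  expect_equal(pairwise_identity("ACDEFG", "ACDE"), 1.0)
  set.seed(91)
  for (i in 1:10) {
    a <- random_sequence(sample(10:60, 1))
    b <- random_sequence(sample(10:60, 1))
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("the alignment engine reproduces the dynamic-programming oracle score", {
  set.seed(101)
  for (i in 1:25) {
    a <- random_sequence(sample(5:40, 1))
    b <- random_sequence(sample(5:40, 1))
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(a), b, type = "global",
      substitutionMatrix = {
        letters_all <- c(aa_alphabet(), "X")
        m <- matrix(0L, 21, 21, dimnames = list(letters_all, letters_all))
        diag(m) <- 1L; m["X", "X"] <- 0L
        m
      },
      gapOpening = 0, gapExtension = 1)
    expect_equal(Biostrings::score(aln), oracle_alignment_score(a, b))
  }
})

test_that("greedy clustering groups identical and dissimilar sequences correctly", {
  same <- setNames(rep("MKTAYIAKQRQISFVK", 4), paste0("s", 1:4))
  cl <- cluster_greedy(same, threshold = 0.9)
  expect_length(cl, 1L)
  expect_equal(sort(cl[[1]]$members), paste0("s", 1:4))

  # pairwise-dissimilar homopolymers below threshold: all singletons
  distinct <- setNames(c(strrep("A", 30), strrep("C", 30), strrep("D", 30)),
                       c("a", "c", "d"))
  expect_length(cluster_greedy(distinct, threshold = 0.5), 3L)
  expect_length(cluster_greedy(character(0)), 0L)
})

test_that("a crafted two-family toy set yields two clusters at threshold 0.7", {
  base1 <- strsplit(strrep("ACDEFGHIKL", 3), "")[[1]]
  base2 <- strsplit(strrep("YWVTSRQPNM", 3), "")[[1]]
  mutate <- function(res, k, seed) {
    set.seed(seed)
    idx <- sample(length(res), k)
    res[idx] <- sample(aa_alphabet(), k, replace = TRUE)
    paste(res, collapse = "")
  }
  seqs <- c(f1a = paste(base1, collapse = ""), f1b = mutate(base1, 4, 1),
            f1c = mutate(base1, 5, 2),
            f2a = paste(base2, collapse = ""), f2b = mutate(base2, 4, 3),
            f2c = mutate(base2, 5, 4))
  # oracle: verify the family structure with the all-pairs identity matrix
  ids <- names(seqs)
  fam <- substr(ids, 1, 2)
  for (i in 1:5) for (j in (i + 1):6) {
    ident <- pairwise_identity(seqs[[i]], seqs[[j]])
    if (fam[i] == fam[j]) expect_gte(ident, 0.7) else expect_lt(ident, 0.7)
  }
  cl <- cluster_greedy(seqs, threshold = 0.7)
  expect_length(cl, 2L)
  expect_setequal(vapply(cl, function(c) length(c$members), integer(1)), c(3L, 3L))
})

test_that("cluster invariants hold: representative length, membership, identity", {
  set.seed(111)
  fams <- generate_redundant_families(4, 4, 0.08, seed = 5)
  cl <- cluster_greedy(fams, threshold = 0.7)
  lens <- setNames(Biostrings::width(fams), names(fams))
  all_members <- unlist(lapply(cl, function(c) c$members))
  expect_setequal(all_members, names(fams))       # every record in one cluster
  expect_equal(anyDuplicated(all_members), 0L)
  for (c in cl) {
    expect_true(all(lens[c$representative] >= lens[c$members]))
    expect_true(all(c$identities >= 0.7))
  }
})

test_that("raising the threshold never decreases the cluster count", {
  fams <- generate_redundant_families(5, 3, 0.15, seed = 6)
  n_clusters <- sapply(c(0.5, 0.7, 0.9, 0.99),
                       function(t) length(cluster_greedy(fams, t)))
  expect_true(all(diff(n_clusters) >= 0))
})

test_that("clustering is deterministic and dereplication halves duplicates", {
  fams <- generate_redundant_families(3, 3, 0.1, seed = 7)
  cl1 <- cluster_greedy(fams, 0.7)
  cl2 <- cluster_greedy(fams[sample(length(fams))], 0.7)
  expect_equal(unclass(cl1), unclass(cl2))  # input order must not matter

  doubled <- c(fams, setNames(fams, paste0(names(fams), "_dup")))
  reps <- dereplicate(doubled, threshold = 0.99)
  expect_length(reps, length(fams))

  singles <- setNames(c(strrep("A", 20), strrep("C", 20)), c("x", "y"))
  expect_equal(names(dereplicate(singles, 0.7)), c("x", "y"))
})

test_that("cluster reports serialize with one row per member", {
  fams <- generate_redundant_families(3, 2, 0.05, seed = 8)
  cl <- cluster_greedy(fams, 0.7)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cluster_report(cl, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), length(fams))
  expect_true(all(tab$identity >= 0.7))
})
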
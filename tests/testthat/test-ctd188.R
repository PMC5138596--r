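pp <- property_partitions()

test_that("the partition registry holds 8 valid partitions in fixed order", {
  expect_length(pp, 8L)
  expect_equal(names(pp)[1:2], c("hydrophobicity", "normalized_vdw_volume"))
  for (p in pp) {
    expect_silent(validate_partition(p))
    expect_setequal(unlist(p$groups), aa_alphabet())
  }
  expect_error(validate_partition(list(c("A"), c("A"), aa_alphabet())), "overlap")
  expect_error(validate_partition(list(c("A"), c("C"), c("D"))), "cover")
})

test_that("amino-acid composition matches direct counting", {
  expect_equal(unname(aac("AAAA")), c(100, rep(0, 19)))
  v <- aac("ACDE")
  expect_equal(unname(v[c("A", "C", "D", "E")]), rep(25, 4))
  expect_equal(sum(v), 100)
  expect_error(aac(""), "empty")
})

test_that("group encoding maps residues positionally, wildcards to 0", {
  charge <- pp$charge
  expect_equal(encode_groups("KKDD", charge), c(1L, 1L, 3L, 3L))
  expect_equal(encode_groups("KXDA", charge), c(1L, 0L, 3L, 2L))
  expect_false(3L %in% encode_groups("KKAA", charge))
  expect_equal(ctd_composition("XXXX", charge), c(0, 0, 0))
})

test_that("composition triple counts groups on the percent scale", {
  expect_equal(ctd_composition("KKDD", pp$charge), c(50, 0, 50))
  set.seed(21)
  for (i in 1:20) {
    s <- random_sequence(sample(2:80, 1))
    expect_equal(sum(ctd_composition(s, pp$hydrophobicity)), 100)
  }
})

test_that("transitions count unordered adjacent group crossings over L - 1", {
  expect_equal(ctd_transition("AAAA", pp$hydrophobicity), c(0, 0, 0))
  # alternating positive/negative charge: every adjacent pair crosses (1,3)
  expect_equal(ctd_transition("KDKDKD", pp$charge), c(0, 100, 0))
  expect_message(t1 <- ctd_transition("A", pp$charge), "length 1")
  expect_equal(t1, c(0, 0, 0))
})

test_that("C/T/D agree with brute-force oracles on random 30-mers", {
  set.seed(7)
  for (i in 1:200) {
    s <- random_sequence(30)
    p <- pp[[sample(8, 1)]]
    expect_equal(ctd_composition(s, p), oracle_ctd_c(s, p))
    expect_equal(ctd_transition(s, p), oracle_ctd_t(s, p))
    expect_equal(ctd_distribution(s, p), oracle_ctd_d(s, p))
  }
})

test_that("distribution quantiles collapse correctly in degenerate cases", {
  # single occurrence at position p of length L: all five slots = 100 p / L
  d <- ctd_distribution("AAAC", pp$hydrophobicity)
  expect_equal(d[11:15], rep(100, 5))  # C is hydrophobic, position 4 of 4
  # absent group: five zeros
  d2 <- ctd_distribution("KKKK", pp$charge)
  expect_equal(d2[6:15], rep(0, 10))   # neutral and negative groups empty
  expect_true(all(d2 >= 0 & d2 <= 100))
})

test_that("the 188-D vector has fixed length, ordering and bounds", {
  v <- extract_188("AAAA")
  expect_length(v, 188L)
  expect_equal(unname(v[1]), 100)
  expect_true(all(v[grepl("\\.T", names(v))] == 0))  # homopolymer: no crossings
  set.seed(31)
  for (i in 1:10) {
    v <- extract_188(random_sequence(sample(2:300, 1)))
    expect_length(v, 188L)
    expect_true(all(v >= 0 & v <= 100 + 1e-9))
    expect_equal(sum(v[1:20]), 100, tolerance = 1e-9)
  }
})

test_that("permuting a sequence preserves AAC and C but not, generally, T/D", {
  set.seed(41)
  s <- random_sequence(120)
  perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  v1 <- extract_188(s); v2 <- extract_188(perm)
  expect_equal(v1[1:20], v2[1:20])
  c_idx <- grepl("\\.C[123]$", names(v1))
  expect_equal(v1[c_idx], v2[c_idx])
  expect_false(isTRUE(all.equal(v1, v2)))
})

test_that("batch extraction equals the per-record loop and handles 0 records", {
  empty <- extract_188_batch(character(0))
  expect_equal(dim(empty), c(0L, 188L))
  expect_length(colnames(empty), 188L)

  set.seed(51)
  seqs <- c(a = random_sequence(40), b = random_sequence(60),
            b2 = random_sequence(60))
  m <- extract_188_batch(seqs)
  for (i in seq_along(seqs)) {
    expect_equal(m[i, ], extract_188(seqs[[i]]))
  }
  # identical sequences give identical rows
  m2 <- extract_188_batch(c(x = "ACDEACDE", y = "ACDEACDE"))
  expect_equal(unname(m2[1, ]), unname(m2[2, ]))
})

test_that("worked-example composition rows reproduce to 4 decimals", {
  s <- psba1_sequence()
  expect_equal(round(unname(aac(s)), 4), psba1_expected_aac())
  expect_equal(round(ctd_composition(s, pp$hydrophobicity), 4),
               psba1_expected_hydro_c())
  expect_equal(round(ctd_composition(s, pp$normalized_vdw_volume), 4),
               psba1_expected_vdw_c())
})

test_that("alternate partition tables load from TSV and validate", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("property\tgroup_index\tresidues",
               "charge\t1\tKR",
               "charge\t2\tANCQGHILMFPSTWYV",
               "charge\t3\tDE"), f)
  reg <- read_partition_table(f)
  expect_equal(reg$charge$groups[[1]], c("K", "R"))
  expect_equal(ctd_composition("KKDD", reg$charge), c(50, 0, 50))
})
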
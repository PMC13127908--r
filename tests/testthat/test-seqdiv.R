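test_that("read_alignment ingests FASTA, preserves order and validates", {
  fa <- write_fasta(c("a", "b"), c("acgtacgtac", "ACGTACGTAC"))
  aln <- read_alignment(fa)
  expect_equal(attr(aln, "n"), 2)
  expect_equal(attr(aln, "length"), 10)
  expect_equal(aln$id, c("a", "b"))
  expect_equal(aln$seq[1], "ACGTACGTAC")  # upper-cased

  # wrapped records read identically to unwrapped ones
  fa_wrapped <- write_fasta(c("a", "b"), c("ACGTACGTAC", "ACGTACGTAC"),
                            width = 4)
  expect_equal(read_alignment(fa_wrapped)$seq, aln$seq)

  expect_error(read_alignment(write_fasta(character(0), character(0))),
               "no records")
  # unequal lengths rejected unless trimming is requested
  fa_bad <- write_fasta(c("a", "b"), c("ACGTACGTAC", "ACGTACG"))
  expect_error(read_alignment(fa_bad), "unequal")
  trimmed <- read_alignment(fa_bad, trim_to_overlap = TRUE)
  expect_equal(attr(trimmed, "length"), 7)
  # IUPAC ambiguity codes other than N are rejected
  expect_error(read_alignment(write_fasta("a", "ACGTR")), "disallowed")
})

test_that("synthetic alignments round-trip through ingestion", {
  g <- gen_alignment(length = 120, haplotype_counts = c(26, 2, 1),
                     mutations_per_haplotype = 2, seed = 11,
                     path = tempfile(fileext = ".fasta"))
  aln <- read_alignment(g$path)
  expect_equal(attr(aln, "n"), 29)
  expect_equal(attr(aln, "length"), 120)
  expect_equal(aln$seq, g$alignment$seq)
})

test_that("haplotype collapsing counts exact-identity classes", {
  g1 <- gen_alignment(length = 80, haplotype_counts = 29,
                      mutations_per_haplotype = 1, seed = 1)
  expect_equal(nrow(collapse_haplotypes(g1$alignment)), 1)

  aln2 <- as_alignment(tibble::tibble(id = c("x", "y"),
                                      seq = c("AAAA", "AAAT")))
  expect_equal(nrow(collapse_haplotypes(aln2)), 2)

  g3 <- gen_alignment(length = 200, haplotype_counts = c(26, 1, 1), seed = 3)
  ht <- collapse_haplotypes(g3$alignment)
  expect_equal(nrow(ht), 3)
  expect_equal(sum(ht$count), 28)
  expect_equal(sum(ht$frequency), 1, tolerance = 1e-12)
})

test_that("site filter removes gap/N columns from both haplotypes and pi", {
  aln <- as_alignment(tibble::tibble(
    id = c("a", "b", "c"),
    seq = c("A-GTA", "ANGTA", "ACGTT")))  # cols 2 dropped (gap + N)
  ht <- collapse_haplotypes(aln)
  expect_equal(attr(ht, "n_sites"), 4)
  expect_equal(nrow(ht), 2)  # a and b identical after filtering
  nd <- nucleotide_diversity(aln)
  expect_equal(nd$n_sites, 4)
  # all sites removed -> error
  aln_bad <- as_alignment(tibble::tibble(id = c("a", "b"),
                                         seq = c("-N", "NN")))
  expect_error(nucleotide_diversity(aln_bad), "complete-deletion")
})

test_that("haplotype diversity matches Nei's estimator and variance", {
  expect_equal(haplotype_diversity(29)$h, 0)
  expect_equal(haplotype_diversity(c(1, 1))$h, 1)
  # frozen from direct evaluation of h = n/(n-1)(1 - sum p_i^2) and Nei's V(h)
  hd <- haplotype_diversity(c(29, 2))
  expect_equal(hd$h, 0.1247312, tolerance = 1e-6)
  expect_equal(hd$h_sd, 0.0770590, tolerance = 1e-4)
  hd2 <- haplotype_diversity(c(26, 1, 1))
  expect_equal(hd2$h, 0.1402116, tolerance = 1e-6)
  expect_equal(hd2$h_sd, 0.0870787, tolerance = 1e-4)
  expect_error(haplotype_diversity(1), "undefined")
})

test_that("nucleotide diversity equals its defining ordered-pair sum", {
  # identical sequences
  g <- gen_alignment(length = 60, haplotype_counts = 5, seed = 2)
  expect_equal(nucleotide_diversity(g$alignment)$pi, 0)
  # n = 2, one site in 10 differing: unbiased estimator equals the distance
  aln <- as_alignment(tibble::tibble(id = c("a", "b"),
                                     seq = c("AAAAAAAAAA", "AAAAAAAAAT")))
  expect_equal(nucleotide_diversity(aln)$pi, 0.1)
  # random alignments against the brute-force double-loop oracle
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(3:12, 1)
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = ""),
      character(1))
    aln <- as_alignment(tibble::tibble(id = as.character(seq_len(n)),
                                       seq = seqs))
    expect_equal(nucleotide_diversity(aln)$pi, oracle_pi(seqs),
                 tolerance = 1e-12)
  }
})

test_that("diversity is invariant to record order and id renaming", {
  g <- gen_alignment(length = 150, haplotype_counts = c(10, 4, 2),
                     mutations_per_haplotype = 3, seed = 9)
  aln <- g$alignment
  set.seed(1)
  perm <- sample(nrow(aln))
  aln2 <- as_alignment(tibble::tibble(id = paste0("z", seq_len(nrow(aln))),
                                      seq = aln$seq[perm]))
  expect_equal(diversity_summary(aln)[c("h", "pi")],
               diversity_summary(aln2)[c("h", "pi")], tolerance = 1e-12)
})

test_that("duplicating an alignment changes h only via the n/(n-1) factor", {
  g <- gen_alignment(length = 100, haplotype_counts = c(7, 2, 1), seed = 5)
  aln <- g$alignment
  n <- nrow(aln)
  dup <- as_alignment(tibble::tibble(id = paste0("d", seq_len(2 * n)),
                                     seq = rep(aln$seq, 2)))
  h1 <- haplotype_diversity(collapse_haplotypes(aln))$h
  h2 <- haplotype_diversity(collapse_haplotypes(dup))$h
  # sum p_i^2 is unchanged, so the ratio is exactly the correction ratio
  expect_equal(h2 / h1, (2 * n / (2 * n - 1)) / (n / (n - 1)),
               tolerance = 1e-12)
})

test_that("h = 0 iff a single haplotype; pi = 0 when sites monomorphic", {
  for (seed in 1:4) {
    counts <- sample(1:6, sample(1:3, 1), replace = TRUE) + 1
    g <- gen_alignment(length = 90, haplotype_counts = counts, seed = seed)
    ds <- diversity_summary(g$alignment)
    expect_identical(ds$h == 0, ds$nh == 1)
    if (ds$nh == 1) expect_equal(ds$pi, 0)
  }
})

test_that("sharedness report classifies focal haplotypes and exclusives", {
  # one haplotype shared with every other region
  sets <- list(balearic = "H1", a = c("H1", "H2"), b = "H1", c = "H1",
               d = c("H1", "H9"))
  rep1 <- sharedness_report(sets, "balearic")
  expect_false(rep1$focal_report$unique_to_focal[1])
  expect_equal(rep1$focal_report$n_regions[1], 4)

  # disjoint sets: everything unique
  rep2 <- sharedness_report(list(x = c("A", "B"), y = "C"), "x")
  expect_true(all(rep2$focal_report$unique_to_focal))

  # three focal haplotypes absent everywhere else
  sets3 <- list(balearic = c("R1", "R2", "R3"), malta = c("M1", "M2"))
  rep3 <- sharedness_report(sets3, "balearic")
  ex <- rep3$exclusive_counts
  expect_equal(ex$nh_exclusive[ex$region == "balearic"], 3)

  expect_error(sharedness_report(list(a = character(0), b = "H"), "a"),
               "empty focal")
})
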
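test_that("alignment construction validates lengths and popmap coverage", {
  a <- tiny_alignment(rep("ACGTACGTAA", 3), c("d1", "d1", "d2"))
  expect_s3_class(a, "hd_alignment")
  expect_equal(alignment_length(a), 10)
  expect_equal(length(a$ids), 3)
  expect_error(tiny_alignment(c("ACGT", "ACG"), c("d1", "d1")),
               "unequal length")
  seqs <- setNames(rep("ACGT", 2), c("x1", "x2"))
  expect_error(hd_alignment(seqs, c(x1 = "d1")), "missing from popmap")
  # unknown symbols map to N
  b <- tiny_alignment(c("ACXT", "ACGT"), c("d1", "d1"))
  expect_equal(unname(b$seqs[1, 3]), "N")
})

test_that("write/read round-trips the synthetic study fixture byte-identically", {
  fx <- make_study_fixture(seed = 3)
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "a.fasta"); pm <- file.path(dir, "a.csv")
  co <- file.path(dir, "c.csv")
  write_alignment(fx$alignment, fa, pm, co)
  rt <- read_alignment(fa, pm, partitions = fx$alignment$partitions,
                       coords_path = co)
  expect_identical(rt$seqs, fx$alignment$seqs)
  expect_identical(unname(rt$deme_of[rt$ids]),
                   unname(fx$alignment$deme_of[fx$alignment$ids]))
  expect_identical(rt$group_of[sort(names(rt$group_of))],
                   fx$alignment$group_of[sort(names(fx$alignment$group_of))])
  # second write of the re-read alignment is byte-identical
  fa2 <- file.path(dir, "b.fasta")
  write_alignment(rt, fa2, file.path(dir, "b.csv"))
  expect_identical(readLines(fa), readLines(fa2))
})

test_that("haplotype collapsing forms identity classes with N merged leniently", {
  a <- tiny_alignment(rep("AAAAA", 5), rep("d1", 5))
  h <- collapse_haplotypes(a)
  expect_equal(length(h$hap_seqs), 1)
  expect_equal(sum(h$counts), 5)

  b <- tiny_alignment(c("AAA", "AAA", "AAT"), c("d1", "d2", "d2"))
  hb <- collapse_haplotypes(b)
  expect_equal(dim(hb$counts), c(2L, 2L))
  expect_equal(unname(hb$counts), matrix(c(1L, 0L, 1L, 1L), 2))
  expect_equal(names(hb$hap_seqs), c("H1", "H2"))

  # N-only differences merge into the earlier haplotype
  cc <- tiny_alignment(c("ANA", "AAA", "ATA"), c("d1", "d1", "d1"))
  hc <- collapse_haplotypes(cc)
  expect_equal(length(hc$hap_seqs), 2)
  expect_equal(unname(hc$counts[, "d1"]), c(2L, 1L))
})

test_that("study fixture collapses to exactly 27 planted haplotypes", {
  fx <- make_study_fixture(seed = 1)
  h <- collapse_haplotypes(fx$alignment)
  expect_equal(length(h$hap_seqs), 27)
  expect_equal(sum(h$counts), 93)
  # per-deme counts match the planted design
  expect_equal(sort(unname(h$counts[, "CP"])[h$counts[, "CP"] > 0]), c(1L, 9L))
  # identical seeds give identical alignments
  fx2 <- make_study_fixture(seed = 1)
  expect_identical(fx$alignment$seqs, fx2$alignment$seqs)
  fx3 <- make_study_fixture(seed = 2)
  expect_false(identical(fx$alignment$seqs, fx3$alignment$seqs))
})

test_that("collapse is idempotent and conserves counts on random fixtures", {
  for (s in 1:5) {
    sim <- simulate_coalescent("island", n = 6, n_demes = 3, theta = 2,
                               M = 1, L = 300, seed = s)
    h <- collapse_haplotypes(sim$alignment)
    expect_equal(sum(h$counts), length(sim$alignment$ids))
    reps <- tiny_alignment(unname(h$hap_seqs), rep("d", length(h$hap_seqs)))
    h2 <- collapse_haplotypes(reps)
    expect_equal(length(h2$hap_seqs), length(h$hap_seqs))
    expect_equal(unname(h2$hap_seqs), unname(h$hap_seqs))
  }
})

test_that("site statistics match a brute-force column scan", {
  a <- tiny_alignment(rep("AAAA", 4), rep("d", 4))
  st <- site_statistics(a)
  expect_equal(st$per_partition$n_variable[1], 0)
  expect_equal(st$per_partition$n_parsimony_informative[1], 0)

  b <- tiny_alignment(c("AA", "AT", "TT", "TT"), rep("d", 4))
  stb <- site_statistics(b)
  # column 1 {A,A,T,T}: variable and informative; column 2 {A,T,T,T}:
  # variable, not informative
  expect_equal(stb$per_partition$n_variable[1], 2)
  expect_equal(stb$per_partition$n_parsimony_informative[1], 1)

  set.seed(42)
  for (rep in 1:3) {
    seqs <- matrix(sample(c("A", "C", "G", "T", "N"), 20 * 100, replace = TRUE,
                          prob = c(.3, .2, .2, .25, .05)), 20, 100)
    rownames(seqs) <- sprintf("r%02d", 1:20)
    a <- hd_alignment(seqs, setNames(rep("d", 20), rownames(seqs)))
    st <- site_statistics(a)
    nv <- 0; ni <- 0
    for (j in 1:100) {
      col <- seqs[, j]; col <- col[col %in% c("A", "C", "G", "T")]
      tb <- table(col)
      if (sum(tb > 0) >= 2) {
        nv <- nv + 1
        if (sum(tb >= 2) >= 2) ni <- ni + 1
      }
    }
    expect_equal(st$per_partition$n_variable[1], nv)
    expect_equal(st$per_partition$n_parsimony_informative[1], ni)
  }
  expect_error(site_statistics(a, codon_partition = "all"), "frame")
})

test_that("base-frequency homogeneity chi-square matches hand computation", {
  a <- tiny_alignment(rep("ACGTACGT", 4), rep("d", 4))
  r <- base_homogeneity_chi2(a)
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)
  expect_equal(r$df, 9)

  # 2 taxa with counts [[10,0,0,0],[0,10,0,0]] -> chi2 = 20, df = 3
  b <- tiny_alignment(c(strrep("A", 10), strrep("C", 10)), c("d", "d"))
  rb <- base_homogeneity_chi2(b)
  expect_equal(rb$chi2, 20)
  expect_equal(rb$df, 3)

  # fixture with homogeneous composition is not rejected
  fx <- make_study_fixture(seed = 5)
  expect_gt(base_homogeneity_chi2(fx$alignment)$p, 0.05)
})
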
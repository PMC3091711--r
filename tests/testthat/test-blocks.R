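seg_events <- function(lengths, times) {
  data.frame(type = "segmental", block_length = lengths, time = times)
}

test_that("self_match guards against spurious k-mer sizes", {
  expect_error(self_match(rand_dna(100, seed = 1), k = 7), "spurious")
  expect_error(self_match("ACGT", k = 8), "shorter")
})

test_that("a random sequence has essentially no off-diagonal 16-mer matches", {
  # expected collisions ~ n^2 * 4^-16 << 1 for n = 1e5
  m <- self_match(rand_dna(100000, seed = 2), k = 16)
  expect_lte(nrow(m), 2)
})

test_that("a sequence concatenated with itself matches along a full off-diagonal", {
  s <- rand_dna(5000, seed = 3)
  m <- self_match(paste0(s, s), k = 16)
  on_diag <- m[m$diag == 5000, ]
  expect_equal(nrow(on_diag), 5000 - 16 + 1)
})

test_that("matches of a simulated duplication concentrate on one diagonal band", {
  cfg <- evolution_config(seed = 4, duplication_events = seg_events(30000, 0.02),
                          branch_lengths = 0.002)
  tr <- simulate_family(cfg)
  m <- self_match(tr$locus, k = 16)
  frac_band <- mean(abs(m$diag - 30000) < 100)
  expect_gt(frac_band, 0.95)
})

test_that("a triplicated block is delimited within a kilobase of the truth", {
  cfg <- evolution_config(seed = 5,
                          duplication_events = seg_events(c(40000, 40000), c(0.01, 0.02)),
                          branch_lengths = 0.003)
  tr <- simulate_family(cfg)
  det <- chain_and_delimit(self_match(tr$locus, k = 16))
  expect_equal(nrow(det$blocks), 3)
  expect_true(all(abs(det$blocks$start - tr$blocks$start) <= 1000))
  expect_true(all(det$blocks$class == "segmental"))
})

test_that("a small single-gene duplication is classified tandem", {
  cfg <- evolution_config(seed = 6, promoter_length = 1000,
                          ancestral_cds_length = 400,
                          duplication_events = data.frame(type = "tandem",
                                                          block_length = 5000,
                                                          time = 0.01),
                          branch_lengths = 0.002)
  tr <- simulate_family(cfg)
  det <- chain_and_delimit(self_match(tr$locus, k = 16), min_block = 2000)
  expect_equal(nrow(det$blocks), 2)
  expect_true(all(det$blocks$class == "tandem"))
})

test_that("empty match input yields empty block output", {
  m <- self_match(rand_dna(50000, seed = 7), k = 16)
  det <- chain_and_delimit(m)
  expect_equal(nrow(det$blocks), 0)
})

test_that("genes are assigned to their blocks", {
  cfg <- evolution_config(seed = 8,
                          duplication_events = seg_events(30000, 0.015),
                          branch_lengths = 0.002)
  tr <- simulate_family(cfg)
  genes <- data.frame(id = tr$copies$copy, start = tr$copies$gene_start,
                      end = tr$copies$gene_end)
  det <- chain_and_delimit(self_match(tr$locus, k = 16), genes = genes)
  expect_equal(det$blocks$n_genes, c(1L, 1L))
})

test_that("identical blocks score 100% identity", {
  s <- rand_dna(20000, seed = 9)
  bp <- block_identity(s, s)
  expect_equal(bp$percent_identity, 100)
  expect_false(bp$undefined)
})

test_that("block identity matches the substitution-model expectation", {
  devs <- vapply(1:5, function(i) {
    s <- rand_dna(30000, seed = 20 + i)
    s2 <- evolve_sequence(s, 0.05, 2, seed = 40 + i)
    block_identity(s, s2)$percent_identity
  }, 1.0)
  expected <- 100 * k80_expected(0.05, 2)$identity
  se <- 100 * sqrt(k80_expected(0.05, 2)$identity *
                     (1 - k80_expected(0.05, 2)$identity) / 30000)
  expect_lt(abs(mean(devs) - expected), 3 * se / sqrt(5))
})

test_that("unrelated blocks have no anchors and undefined identity", {
  bp <- block_identity(rand_dna(5000, seed = 31), rand_dna(5000, seed = 32))
  expect_true(bp$undefined)
})

test_that("LTR divergence reports raw and JC distances", {
  ltr <- rand_dna(200, seed = 33)
  expect_equal(ltr_divergence(ltr, ltr)$p_distance, 0)
  # plant 2 mismatches in 200 sites
  l2 <- ltr
  substr(l2, 10, 10) <- if (substr(ltr, 10, 10) == "A") "C" else "A"
  substr(l2, 100, 100) <- if (substr(ltr, 100, 100) == "G") "T" else "G"
  d <- ltr_divergence(ltr, l2)
  expect_equal(d$p_distance, 0.01)
  expect_equal(d$jc_distance, -0.75 * log(1 - 4 * 0.01 / 3), tolerance = 1e-9)
  expect_true(ltr_divergence("ACGTACGT", "ACGTACGT")$low_information)
})

test_that("simulated LTR pairs recover the insertion-age divergence", {
  devs <- vapply(1:8, function(i) {
    cfg <- evolution_config(seed = 40 + i,
                            duplication_events = seg_events(20000, 0.01),
                            te_insertions = data.frame(family = "Gypsy", copy = 1,
                                                       ltr_length = 2000,
                                                       post_branch = 0.046))
    tr <- simulate_family(cfg)
    ltr_divergence(tr$tes$ltr5, tr$tes$ltr3)$jc_distance
  }, 1.0)
  # two LTRs each evolving 0.046 expected subs/site diverge by 0.092;
  # JC corrects a K80 process with kappa=2 to a very close distance
  p_exp <- 1 - k80_expected(0.092, 2)$identity
  se_p <- sqrt(p_exp * (1 - p_exp) / 2000)
  se_jc <- se_p / (1 - 4 * p_exp / 3)
  expect_lt(abs(mean(devs) - 0.092), 3 * se_jc / sqrt(8) + 0.002)
})

test_that("TE fraction profile merges overlaps and conserves coverage", {
  # no TEs: all zero
  p0 <- te_fraction_profile(50000, tibble::tibble(start = integer(),
                                                  end = integer()),
                            window_sizes = 25000)
  expect_true(all(p0$te_fraction == 0))
  # a 12.5-kb TE centred in the first 25-kb window
  p1 <- te_fraction_profile(50000, tibble::tibble(start = 6250, end = 18750),
                            window_sizes = 25000)
  expect_equal(p1$te_fraction[1], 0.5)
  # overlapping TEs over the same 10 kb count once
  p2 <- te_fraction_profile(20000,
                            tibble::tibble(start = c(5000, 5000),
                                           end = c(15000, 15000)),
                            window_sizes = 20000)
  expect_equal(p2$te_fraction, 0.5)
  # window-weighted mean equals the whole-locus fraction
  te <- tibble::tibble(start = c(1000, 30000, 60000),
                       end = c(9000, 42000, 61000))
  prof <- te_fraction_profile(70000, te, window_sizes = 25000)
  whole <- sum(te$end - te$start) / 70000
  expect_equal(sum(prof$te_fraction * (prof$end - prof$start)) / 70000, whole)
  expect_warning(te_fraction_profile(10000, te[1, ], window_sizes = 20000),
                 "whole-locus")
})

test_that("flank conservation spans the full flank for whole-block duplicates", {
  cfg <- evolution_config(seed = 50,
                          duplication_events = seg_events(30000, 0.01),
                          branch_lengths = 0.002)
  tr <- simulate_family(cfg)
  g <- tr$copies
  fp <- flank_conservation(tr$locus,
                           list(start = g$gene_start[1], end = g$gene_end[1]),
                           list(start = g$gene_start[2], end = g$gene_end[2]),
                           flank = 2000)
  expect_true(all(fp$extent$extent == 2000))
})

test_that("flank conservation stops where the copied segment ends", {
  set.seed(51)
  anc <- rand_dna(30000)
  gene <- list(start = 12000, end = 13500)
  copyseg <- substr(anc, gene$start - 2000 + 1, gene$end + 2000)
  bg <- rand_dna(30000)
  genome_b <- paste0(substr(bg, 1, 10000), copyseg,
                     substr(bg, 10000 + nchar(copyseg) + 1, 30000))
  fp <- flank_conservation(
    setNames(c(anc, genome_b), c("s1", "s2")),
    list(start = gene$start, end = gene$end, seqid = "s1"),
    list(start = 12000, end = 13500, seqid = "s2"),
    flank = 5000)
  expect_true(all(abs(fp$extent$extent - 2000) <= 200))
})

test_that("unrelated genes show no conserved flank window", {
  fp <- flank_conservation(
    setNames(c(rand_dna(20000, seed = 52), rand_dna(20000, seed = 53)),
             c("s1", "s2")),
    list(start = 9000, end = 10000, seqid = "s1"),
    list(start = 9000, end = 10000, seqid = "s2"),
    flank = 3000)
  expect_true(all(fp$extent$extent == 0))
  expect_true(all(fp$profile$identity < 0.7))
})
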
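test_that("identical CDS align without gaps", {
  cds <- withr::with_seed(1, random_cds(50))
  aln <- protein_guided_codon_align(cds, cds)
  expect_identical(aln$a, cds)
  expect_identical(aln$b, cds)
})

test_that("a single inserted codon produces one in-frame 3-bp gap", {
  cds <- withr::with_seed(2, random_cds(10))
  cds2 <- paste0(substr(cds, 1, 15), "GAA", substr(cds, 16, 30))
  aln <- protein_guided_codon_align(cds, cds2)
  gaps <- gregexpr("-+", aln$a)[[1]]
  expect_equal(length(gaps), 1)
  expect_equal(attr(gaps, "match.length"), 3)
  expect_false(grepl("-", aln$b))
})

test_that("alignment identity equals a brute-force identity count", {
  cds <- withr::with_seed(3, random_cds(300))
  cds2 <- evolve_sequence(cds, 0.03, 2, coding = TRUE, seed = 4)
  aln <- protein_guided_codon_align(cds, cds2)
  a <- strsplit(aln$a, "")[[1]]; b <- strsplit(aln$b, "")[[1]]
  ident_aln <- mean(a == b)
  ident_direct <- mean(strsplit(cds, "")[[1]] == strsplit(cds2, "")[[1]])
  expect_equal(ident_aln, ident_direct)
})

test_that("4D-site eligibility follows the four-fold degeneracy rule", {
  # Gly family: one eligible site after the start codon
  aln1 <- protein_guided_codon_align("ATGGGA", "ATGGGT")
  s1 <- find_4d_sites(aln1)
  expect_equal(nrow(s1), 1)
  expect_equal(s1$column, 2L)
  # Met alone is not four-fold degenerate
  expect_equal(nrow(find_4d_sites(protein_guided_codon_align("ATG", "ATG"))), 0)
  # differing first-two positions are ineligible even in 4D families
  aln3 <- protein_guided_codon_align("ATGGGA", "ATGGCA")
  expect_equal(nrow(find_4d_sites(aln3)), 0)
})

test_that("fourdtv matches hand-computed toy values", {
  expect_equal(fourdtv("ATGGGAGGAGGAGGA", "ATGGGAGGAGGAGGA")$raw_4dtv, 0)
  expect_equal(fourdtv("ATGGGAGGAGGAGGA", "ATGGGAGGAGGAGGA")$corrected_4dtv, 0)
  # 4 eligible Gly sites, 1 transversion (A<->C)
  est <- fourdtv("ATGGGAGGAGGAGGA", "ATGGGCGGAGGAGGA")
  expect_equal(est$n_4d_sites, 4L)
  expect_equal(est$n_transversions, 1L)
  expect_equal(est$raw_4dtv, 0.25)
  expect_equal(est$corrected_4dtv, 0.34657, tolerance = 1e-4)
  expect_true(est$low_information)
})

test_that("saturation at raw >= 0.5 suppresses the corrected value", {
  # all four Gly sites transverted
  est <- fourdtv("ATGGGAGGAGGAGGA", "ATGGGCGGCGGCGGC")
  expect_true(est$saturated)
  expect_true(is.na(est$corrected_4dtv))
})

test_that("fourdtv equals the brute-force per-codon oracle on random alignments", {
  set.seed(42)
  for (i in 1:60) {
    n_cod <- sample(5:100, 1)
    a <- random_cds(n_cod)
    b <- evolve_sequence(a, runif(1, 0, 0.8), 2, coding = TRUE,
                         seed = 1000 + i)
    aln <- protein_guided_codon_align(a, b)
    est <- fourdtv(aln)
    orc <- oracle_fourdtv(aln$a, aln$b)
    expect_equal(est$n_4d_sites, orc$n_sites)
    expect_equal(est$n_transversions, orc$n_tv)
    expect_equal(est$raw_4dtv, orc$raw)
    if (!is.na(orc$corrected)) {
      expect_equal(est$corrected_4dtv, orc$corrected)
    }
  }
})

test_that("the multiple-transversion correction behaves analytically", {
  raws <- seq(0.005, 0.1, by = 0.005)
  corr <- -0.5 * log(1 - 2 * raws)
  # small-distance agreement: the excess over raw is quadratic, with the
  # leading Taylor term raw^2 (plus a positive cubic remainder)
  expect_true(all(corr - raws >= raws^2))
  expect_true(all(corr - raws <= 2 * raws^2))
  # strict monotonicity up to saturation
  grid <- seq(0, 0.49, by = 0.01)
  expect_true(all(diff(-0.5 * log(1 - 2 * grid)) > 0))
  expect_true(all(-0.5 * log(1 - 2 * grid) >= grid))
})

test_that("corrected 4DTV recovers the simulated transversion distance", {
  # expected transversion distance under kappa = 2 is t / 2
  for (t in c(0.05, 0.2)) {
    a <- withr::with_seed(7, random_cds(3000))
    b <- evolve_sequence(a, t, 2, coding = TRUE, seed = round(1000 * t))
    est <- fourdtv(a, b)
    q <- k80_expected(t, 2)$Q
    se_raw <- sqrt(q * (1 - q) / est$n_4d_sites)
    se_corr <- se_raw / (1 - 2 * est$raw_4dtv)
    expect_lt(abs(est$corrected_4dtv - t / 2), 3 * se_corr)
  }
})

test_that("two-taxon NJ splits the distance in half", {
  m <- matrix(c(0, 0.2, 0.2, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  out <- nj_tree(m)
  expect_equal(sort(out$tree$edge.length), c(0.1, 0.1))
})

test_that("NJ recovers an additive four-taxon tree exactly", {
  # tree ((A:1,B:2):1,(C:3,D:4)) with unit internal edge
  m <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, byrow = TRUE,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  out <- nj_tree(m)
  cd <- ape::cophenetic.phylo(out$tree)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(unname(cd), unname(m), tolerance = 1e-10)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2,
                              dimnames = list(c("a", "b"), c("a", "b")))),
               "symmetric")
})

test_that("4DTV matrix and NJ tree separate deep from shallow clades", {
  cfg <- evolution_config(
    seed = 23, ancestral_cds_length = 800,
    duplication_events = data.frame(type = "segmental",
                                    block_length = rep(15000, 3),
                                    time = c(0.05, 0.3, 0.31)),
    branch_lengths = 0.002)
  tr <- simulate_family(cfg)
  fd <- pairwise_fourdtv(tr$cds)
  expect_true(isSymmetric(fd$matrix))
  expect_equal(unname(diag(fd$matrix)), rep(0, 4))
  m <- fd$matrix
  # copy_2 budded off early; copies 3 and 4 are recent copies of the
  # ancestral lineage, so {1,3,4} form the shallow clade
  within <- c(m["copy_1", "copy_3"], m["copy_1", "copy_4"],
              m["copy_3", "copy_4"])
  between <- m["copy_2", c("copy_1", "copy_3", "copy_4")]
  expect_true(max(within) < min(between))
  tree <- ape::read.tree(text = suppressWarnings(nj_tree(fd))$newick)
  expect_true(ape::is.monophyletic(tree, c("copy_1", "copy_3", "copy_4")))
})

test_that("diagnostic residue comparison flags substitutions through the alignment", {
  aa <- c(ref = "MKLVNPQRST", g1 = "MKLVNPQRST", g2 = "MKIVNPQRST",
          g3 = "MK-VNPQRST")
  pos <- tibble::tibble(domain = c("CR1", "SRS6"), label = c("pos3", "pos8"),
                        reference_position = c(3L, 8L))
  out <- diagnostic_residues(aa, "ref", pos)
  expect_equal(nrow(out), 8)
  flagged <- out[out$substituted, ]
  expect_setequal(flagged$gene, c("g2", "g3"))
  expect_equal(unname(flagged$residue[flagged$gene == "g2"]), "I")
  expect_equal(unname(flagged$residue[flagged$gene == "g3"]), "-")
  expect_error(diagnostic_residues(aa, "missing", pos), "absent")
})
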
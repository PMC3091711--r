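test_that("a single SNP yields a selective primer family; identical copies none", {
  a <- rand_dna(600, seed = 80)
  b <- a
  substr(b, 300, 300) <- setdiff(c("A", "C", "G", "T"),
                                 substr(a, 300, 300))[1]
  pr <- design_copy_specific_primers(c(x = a, y = b), "x",
                                     amplicon_min = 50, amplicon_max = 400)
  expect_gt(nrow(pr), 0)
  # every selective primer's 3' terminus sits on the SNP column
  expect_true(all(pr$f_end[pr$selective == "forward"] == 300))
  expect_true(all(pr$r_start[pr$selective == "reverse"] == 299))
  # selectivity holds in silico: product on target, none on the paralogue
  p1 <- pr[1, ]
  expect_equal(nrow(insilico_pcr(a, p1$forward, p1$reverse,
                                 max_mismatch = 0)), 1)
  expect_equal(nrow(insilico_pcr(b, p1$forward, p1$reverse,
                                 max_mismatch = 0)), 0)
  ident <- design_copy_specific_primers(c(x = a, y = a), "x")
  expect_equal(nrow(ident), 0)
  expect_true(attr(ident, "indistinguishable"))
})

test_that("copies without discriminating sites are flagged, others assayable", {
  # four copies: two share identical sequence (indistinguishable), two
  # carry private SNPs -- mirrors a family where only a subset is assayable
  base <- rand_dna(500, seed = 81)
  v1 <- base; substr(v1, 100, 100) <- "A"; substr(v1, 101, 101) <- "A"
  v2 <- base; substr(v2, 400, 400) <- "C"; substr(v2, 401, 401) <- "C"
  seqs <- c(c1 = v1, c2 = v2, c3 = base, c4 = base)
  assayable <- vapply(names(seqs), function(tg) {
    nrow(design_copy_specific_primers(seqs, tg, amplicon_min = 50,
                                      amplicon_max = 450)) > 0
  }, TRUE)
  expect_true(assayable[["c1"]])
  expect_true(assayable[["c2"]])
  expect_false(assayable[["c3"]])
  expect_false(assayable[["c4"]])
})

test_that("in-silico PCR honours distance and 3'-terminal selectivity", {
  set.seed(82)
  templ <- rand_dna(3000)
  fwd <- substr(templ, 101, 120)
  rev <- paralogon:::revcomp(substr(templ, 481, 500))
  prods <- insilico_pcr(templ, fwd, rev)
  expect_equal(nrow(prods), 1)
  expect_equal(prods$length, 400)
  # a 3'-terminal mismatch on the reverse primer kills the product
  bad_rev <- rev
  substr(bad_rev, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                     substr(rev, 20, 20))[1]
  expect_equal(nrow(insilico_pcr(templ, fwd, bad_rev, max_mismatch = 0)), 0)
  # out-of-range pairs give no product
  expect_equal(nrow(insilico_pcr(templ, fwd, rev, max_len = 300)), 0)
})

test_that("spliced amplicon sizes subtract the intron", {
  set.seed(83)
  exon1 <- rand_dna(300); intron <- rand_dna(153); exon2 <- rand_dna(300)
  templ <- paste0(exon1, intron, exon2)
  gm <- gene_model("g", "t", "+", rbind(c(0, 300), c(453, 753)))
  fwd <- substr(templ, 201, 220)             # inside exon 1
  rev <- paralogon:::revcomp(substr(templ, 551, 570))  # inside exon 2
  prods <- insilico_pcr(templ, fwd, rev, model = gm)
  expect_equal(prods$length, 370)
  expect_equal(prods$spliced_length, 370 - 153)
})

test_that("standard-curve efficiency follows E = 10^(-1/slope)", {
  # perfect doubling
  d <- data.frame(dilution = 10^-(0:4), ct = 15 + 3.3219 * (0:4))
  e <- suppressWarnings(qpcr_efficiency(d))
  expect_equal(e$efficiency, 2, tolerance = 1e-4)
  expect_equal(e$percent, 100, tolerance = 0.05)
  expect_true(e$qc_pass)
  # slope -3.45
  d2 <- data.frame(dilution = 10^-(0:4), ct = 15 + 3.45 * (0:4))
  e2 <- suppressWarnings(qpcr_efficiency(d2))
  expect_equal(e2$efficiency, 10^(1 / 3.45), tolerance = 1e-6)
  expect_equal(e2$percent, 94.9, tolerance = 0.05)
  expect_true(e2$qc_pass)
  # a non-monotone curve is invalid
  d3 <- data.frame(dilution = 10^-(0:3), ct = c(20, 19, 18, 17))
  expect_error(qpcr_efficiency(d3), "slope")
  expect_error(qpcr_efficiency(data.frame(dilution = c(1, 0.1),
                                          ct = c(15, 18))), "3 dilution")
})

test_that("cross-genotype efficiency spread above 10 points fails QC", {
  mk <- function(slope, g) data.frame(genotype = g, dilution = 10^-(0:4),
                                      ct = 15 + slope * (0:4))
  curves <- rbind(mk(3.10, "g1"), mk(3.32, "g2"), mk(3.80, "g3"))
  e <- suppressWarnings(qpcr_efficiency(curves))
  expect_gt(attr(e, "sd_percent"), 10)
  expect_false(attr(e, "cross_genotype_pass"))
  tight <- rbind(mk(3.30, "g1"), mk(3.32, "g2"), mk(3.36, "g3"))
  expect_true(attr(suppressWarnings(qpcr_efficiency(tight)),
                   "cross_genotype_pass"))
})

test_that("ddCt arithmetic and the calibrator identity hold exactly", {
  ct <- tibble::tibble(
    copy = "c1", cultivar = "A",
    organ_or_stage = rep(c("cal", "s"), each = 2),
    bio_rep = 1, tech_rep = rep(1:2, 2),
    ct = c(27, 27, 25, 25), reference_ct = 20)
  r <- relative_expression(ct, calibrator = list(organ_or_stage = "cal"))
  expect_equal(r$expression[r$organ_or_stage == "cal"], 1)
  expect_equal(r$expression[r$organ_or_stage == "s"], 4)  # dCt 5 vs 7
  # technical spread beyond 1 Ct is flagged, not dropped
  ct$ct[1:2] <- c(26, 28)
  r2 <- relative_expression(ct, calibrator = list(organ_or_stage = "cal"))
  expect_true(r2$tech_spread_flag[r2$organ_or_stage == "cal"])
  expect_equal(nrow(r2), 2)
  ct$reference_ct[1] <- NA
  expect_error(relative_expression(ct, list(organ_or_stage = "cal")),
               "reference")
})

test_that("simulated Ct tables recover the generating fold changes", {
  design <- tidyr::expand_grid(copy = c("c1", "c2"), cultivar = "A",
                               organ_or_stage = c("s1", "s2"))
  design$fold <- c(1, 4, 2, 8)
  ct <- simulate_qpcr_ct(design, noise_sd = 0.05, seed = 84)
  r <- relative_expression(ct, calibrator = list(copy = "c1", cultivar = "A",
                                                 organ_or_stage = "s1"))
  est <- r |>
    dplyr::group_by(copy, organ_or_stage) |>
    dplyr::summarise(expression = mean(expression), .groups = "drop") |>
    dplyr::arrange(copy, organ_or_stage)
  expect_equal(est$expression, design$fold[order(design$copy,
                                                 design$organ_or_stage)],
               tolerance = 0.2)
})

test_that("cumulative and peak-relative profiles follow their contracts", {
  design <- tidyr::expand_grid(copy = c("c1", "c2"),
                               cultivar = c("cvA", "cvB"),
                               organ_or_stage = c("s1", "s2"))
  design$fold <- c(3, 6, 1, 2, 9, 18, 3, 6)
  ct <- simulate_qpcr_ct(design, noise_sd = 0, seed = 85)
  r <- relative_expression(ct, calibrator = list(copy = "c1",
                                                 cultivar = "cvA",
                                                 organ_or_stage = "s1"))
  prof <- expression_profiles(r)
  cum <- prof$cumulative
  # cultivar A fold totals are 3x cultivar B at every stage by construction
  for (s in c("s1", "s2")) {
    ra <- cum$total_expression[cum$cultivar == "cvA" &
                                 cum$organ_or_stage == s]
    rb <- cum$total_expression[cum$cultivar == "cvB" &
                                 cum$organ_or_stage == s]
    expect_equal(ra / rb, 3, tolerance = 1e-6)
  }
  # peak-relative series peak at exactly 1
  peaks <- prof$peak_relative |>
    dplyr::group_by(copy, cultivar) |>
    dplyr::summarise(m = max(peak_relative), .groups = "drop")
  expect_true(all(peaks$m == 1))
  # single copy: cumulative equals that copy
  r1 <- r[r$copy == "c1" & r$cultivar == "cvA", ]
  p1 <- expression_profiles(r1)
  means <- tapply(r1$expression, r1$organ_or_stage, mean)
  expect_equal(sort(p1$cumulative$total_expression), sort(as.vector(means)))
})

test_that("ANOVA sums of squares decompose exactly on balanced designs", {
  set.seed(86)
  d <- tidyr::expand_grid(copy = paste0("c", 1:3),
                          cultivar = c("A", "B"),
                          organ_or_stage = paste0("s", 1:4),
                          bio_rep = 1:3)
  d$expression <- rnorm(nrow(d), 10, 1) +
    2 * (d$copy == "c2") * (d$organ_or_stage == "s3")
  fit <- anova_snk(d, factors = c("copy", "cultivar", "organ_or_stage"))
  tab <- tidy(fit)
  ss_total <- tab$sumsq[tab$term == "Total"]
  expect_equal(sum(tab$sumsq[tab$term != "Total"]), ss_total,
               tolerance = 1e-8)
  direct_total <- sum((d$expression - mean(d$expression))^2)
  expect_equal(ss_total, direct_total, tolerance = 1e-8)
  expect_true(all(c("copy", "cultivar", "organ_or_stage",
                    "copy:cultivar:organ_or_stage") %in% tab$term))
})

test_that("unbalanced multi-factor designs are refused with a pointer", {
  d <- tidyr::expand_grid(copy = c("c1", "c2"), cultivar = c("A", "B"),
                          bio_rep = 1:3)
  d$expression <- rnorm(nrow(d))
  d <- d[-1, ]
  expect_error(anova_snk(d, factors = c("copy", "cultivar")), "one-way")
})

test_that("SNK separates a clearly distinct group and letters are consistent", {
  set.seed(3)
  d <- data.frame(g = rep(c("g1", "g2", "g3"), each = 3),
                  expression = c(rnorm(3, 0, 1), rnorm(3, 0, 1),
                                 rnorm(3, 10, 1)))
  fit <- anova_snk(d, factors = "g")
  snk <- fit$snk
  expect_false(snk$letters[snk$group == "g3"] %in%
                 snk$letters[snk$group != "g3"])
  expect_equal(snk$letters[snk$group == "g1"],
               snk$letters[snk$group == "g2"])
  # near-equal means share one letter
  d2 <- data.frame(g = rep(c("g1", "g2", "g3"), each = 3),
                   expression = rnorm(9, 5, 0.1))
  fit2 <- anova_snk(d2, factors = "g")
  expect_equal(length(unique(fit2$snk$letters)), 1)
  # transitive consistency: any two groups sharing a letter bracket only
  # groups that also carry it
  set.seed(88)
  d3 <- data.frame(g = rep(paste0("g", 1:5), each = 4),
                   expression = rnorm(20, rep(c(0, 1, 2, 6, 7), each = 4), 1))
  snk3 <- anova_snk(d3, factors = "g")$snk
  for (l in unique(unlist(strsplit(snk3$letters, "")))) {
    has <- grepl(l, snk3$letters)
    expect_true(all(diff(which(has)) == 1))
  }
})

test_that("an interaction planted in simulated Ct tables is detected", {
  design <- tidyr::expand_grid(copy = c("c1", "c2"),
                               cultivar = c("A", "B"),
                               organ_or_stage = paste0("s", 1:4))
  base <- 2^(as.integer(sub("s", "", design$organ_or_stage)) / 2)
  design$fold <- base * ifelse(design$copy == "c2" &
                                 design$organ_or_stage %in% c("s3", "s4"),
                               4, 1)
  hits <- vapply(1:20, function(i) {
    ct <- simulate_qpcr_ct(design, noise_sd = 0.1, seed = 900 + i)
    r <- relative_expression(ct, calibrator = list(copy = "c1",
                                                   cultivar = "A",
                                                   organ_or_stage = "s1"))
    fit <- anova_snk(r, factors = c("copy", "organ_or_stage"))
    tab <- tidy(fit)
    tab$p.value[tab$term == "copy:organ_or_stage"] < 0.001
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("noise-free Cts generated at a target efficiency recover it exactly", {
  # Ct drops by one cycle per doubling of input at 100% efficiency
  E <- 1.93
  dil <- 10^-(0:4)
  ct <- 25 - log(dil, base = E)
  e <- suppressWarnings(qpcr_efficiency(data.frame(dilution = dil, ct = ct)))
  expect_equal(e$efficiency, E, tolerance = 1e-9)
})
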
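# Shared fixtures and independent oracles for the test suite.

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

delete_segment <- function(s, from, to) {
  # remove 0-based half-open [from, to)
  paste0(substr(s, 1, from), substr(s, to + 1, nchar(s)))
}

# Independent brute-force 4DTV classifier: derives four-fold degeneracy
# directly from the standard genetic code, codon by codon, with no shared
# code with the package implementation.
oracle_fourdtv <- function(cds_a, cds_b) {
  gc_tab <- Biostrings::GENETIC_CODE
  n <- min(nchar(cds_a), nchar(cds_b)) %/% 3
  n_sites <- 0L
  n_tv <- 0L
  purines <- c("A", "G")
  for (i in seq_len(n)) {
    ca <- substr(cds_a, 3 * i - 2, 3 * i)
    cb <- substr(cds_b, 3 * i - 2, 3 * i)
    if (grepl("[^ACGT]", ca) || grepl("[^ACGT]", cb)) next
    if (substr(ca, 1, 2) != substr(cb, 1, 2)) next
    fourfold <- function(cod) {
      pre <- substr(cod, 1, 2)
      aas <- gc_tab[paste0(pre, c("A", "C", "G", "T"))]
      length(unique(aas)) == 1
    }
    if (!fourfold(ca) || !fourfold(cb)) next
    n_sites <- n_sites + 1L
    b1 <- substr(ca, 3, 3)
    b2 <- substr(cb, 3, 3)
    if (b1 != b2 && ((b1 %in% purines) != (b2 %in% purines))) n_tv <- n_tv + 1L
  }
  raw <- if (n_sites > 0) n_tv / n_sites else NA_real_
  corrected <- if (n_sites > 0 && raw < 0.5) -0.5 * log(1 - 2 * raw) else NA_real_
  list(n_sites = n_sites, n_tv = n_tv, raw = raw, corrected = corrected)
}

# Two tight parental groups plus an optional chimeric candidate; parents
# deep enough to leave a usable trail of diagnostic transversions.
make_parent_groups <- function(n_codons = 1500, t_parent = 0.1,
                               t_tip = 0.002, n_per_group = 3, seed = 9) {
  set.seed(seed)
  anc <- random_cds(n_codons)
  pa <- evolve_sequence(anc, t_parent, 2, coding = TRUE, seed = seed + 1)
  pb <- evolve_sequence(anc, t_parent, 2, coding = TRUE, seed = seed + 2)
  ga <- vapply(seq_len(n_per_group), function(i) {
    evolve_sequence(pa, t_tip, 2, coding = TRUE, seed = seed + 100 + i)
  }, "")
  gb <- vapply(seq_len(n_per_group), function(i) {
    evolve_sequence(pb, t_tip, 2, coding = TRUE, seed = seed + 200 + i)
  }, "")
  names(ga) <- paste0("a", seq_len(n_per_group))
  names(gb) <- paste0("b", seq_len(n_per_group))
  list(group_a = ga, group_b = gb)
}

# A promoter pair carrying the classic complementary-deletion construction:
# a 2-kb ancestor, one copy lacking [300,500), the other lacking
# [1200,1500). Bases flanking each deletion are pinned so that exact
# anchors cannot drift across a deletion boundary by chance.
deletion_promoter_pair <- function(seed = 5) {
  anc <- rand_dna(2000, seed = seed)
  fix <- function(s, pos1, base) {
    substr(s, pos1, pos1) <- base
    s
  }
  anc <- fix(anc, 301, "A"); anc <- fix(anc, 501, "C")
  anc <- fix(anc, 300, "A"); anc <- fix(anc, 500, "C")
  anc <- fix(anc, 1201, "A"); anc <- fix(anc, 1501, "C")
  anc <- fix(anc, 1200, "A"); anc <- fix(anc, 1500, "C")
  list(ancestor = anc,
       p1 = delete_segment(anc, 300, 500),
       p2 = delete_segment(anc, 1200, 1500))
}
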
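#' Protein-guided codon alignment of two CDS
#'
#' Translates both coding sequences (after truncating any incomplete
#' terminal codon), aligns the proteins globally with an affine-gap
#' BLOSUM62 alignment, and back-threads the gaps onto codons, so every gap
#' in the nucleotide alignment is a multiple of 3 and in frame.
#'
#' @param cds_a,cds_b coding sequences (character strings over `{A,C,G,T}`,
#'   IUPAC ambiguity allowed).
#' @param ids length-2 character vector of sequence identifiers.
#' @return An object of class `codon_alignment`: list with gapped nucleotide
#'   strings `a` and `b`, gapped protein strings `aa_a` and `aa_b`, and `ids`.
#' @export
protein_guided_codon_align <- function(cds_a, cds_b, ids = c("a", "b")) {
  trim <- function(x) substr(toupper(x), 1L, nchar(x) - nchar(x) %% 3L)
  cds_a <- trim(cds_a); cds_b <- trim(cds_b)
  aa_a <- translate_cds(cds_a); aa_b <- translate_cds(cds_b)
  if (nchar(aa_a) == 0 || nchar(aa_b) == 0) abort("untranslatable sequence")
  # terminal stop codons would break the protein alignment; drop them
  strip_stop <- function(aa, cds) {
    if (endsWith(aa, "*")) list(aa = substr(aa, 1, nchar(aa) - 1),
                                cds = substr(cds, 1, nchar(cds) - 3))
    else list(aa = aa, cds = cds)
  }
  sa <- strip_stop(aa_a, cds_a); sb <- strip_stop(aa_b, cds_b)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sa$aa), Biostrings::AAString(sb$aa),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  ga <- as.character(Biostrings::alignedPattern(pa))
  gb <- as.character(Biostrings::alignedSubject(pa))
  thread <- function(gapped_aa, cds) {
    chars <- strsplit(gapped_aa, "")[[1]]
    cods <- codons_of(cds)
    out <- character(length(chars))
    k <- 0L
    for (i in seq_along(chars)) {
      if (chars[i] == "-") out[i] <- "---"
      else { k <- k + 1L; out[i] <- cods[k] }
    }
    paste(out, collapse = "")
  }
  structure(list(a = thread(ga, sa$cds), b = thread(gb, sb$cds),
                 aa_a = ga, aa_b = gb, ids = ids),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("<codon_alignment> ", x$ids[1], " vs ", x$ids[2], ", ",
      nchar(x$a) %/% 3L, " codon columns\n", sep = "")
  invisible(x)
}

aln_codon_table <- function(aln) {
  n <- nchar(aln$a) %/% 3L
  tibble(
    column = seq_len(n),
    codon_a = codons_of(aln$a),
    codon_b = codons_of(aln$b)
  )
}

#' Locate four-fold degenerate third-codon sites in a pairwise alignment
#'
#' A third-codon column is eligible iff, in both sequences, the codon is
#' ungapped and unambiguous, both codons belong to a four-fold degenerate
#' family (third position free), and the first two codon positions are
#' identical between the sequences, so that any third-position change is
#' strictly synonymous in both directions.
#'
#' @param aln a [protein_guided_codon_align()] result.
#' @return A tibble with `column` (codon index in the alignment),
#'   `position` (1-based nucleotide position of the third codon base in the
#'   gapped alignment), `base_a`, `base_b`.
#' @export
find_4d_sites <- function(aln) {
  tab <- aln_codon_table(aln)
  pref_a <- substr(tab$codon_a, 1, 2)
  pref_b <- substr(tab$codon_b, 1, 2)
  b_a <- substr(tab$codon_a, 3, 3)
  b_b <- substr(tab$codon_b, 3, 3)
  clean <- function(x) grepl("^[ACGT]+$", x)
  ok <- clean(tab$codon_a) & clean(tab$codon_b) &
    pref_a == pref_b & pref_a %in% FOURFOLD_PREFIXES
  tibble(column = tab$column[ok],
         position = 3L * tab$column[ok],
         base_a = b_a[ok], base_b = b_b[ok])
}

is_transversion <- function(a, b) {
  pur <- c("A", "G")
  a != b & (a %in% pur) != (b %in% pur)
}

#' Four-fold degenerate transversion (4DTV) distance of a gene pair
#'
#' Counts transversion differences at eligible four-fold degenerate
#' third-codon sites and corrects for multiple transversions with
#' `corrected = -1/2 * log(1 - 2 * raw)`, the standard multiple-hit
#' correction for a two-state (purine/pyrimidine) character. Raw values at
#' or beyond 0.5 are saturated and carry no finite corrected distance.
#'
#' @param aln a [protein_guided_codon_align()] result, or a pair of CDS
#'   given as `fourdtv(cds_a, cds_b)`.
#' @param cds_b optional second CDS if `aln` is a raw sequence.
#' @param min_sites below this many eligible sites the estimate is flagged
#'   low-information (default 20).
#' @param ids sequence ids when raw CDS are given.
#' @return An object of class `fourdtv_estimate`: one-row tibble with
#'   `id_a`, `id_b`, `n_4d_sites`, `n_transversions`, `raw_4dtv`,
#'   `corrected_4dtv`, `saturated`, `low_information`, and the eligible site
#'   table in attribute `sites`.
#' @export
#' @examples
#' fourdtv("ATGGGAGGAGGT", "ATGGGTGGAGGT")
fourdtv <- function(aln, cds_b = NULL, min_sites = 20L, ids = c("a", "b")) {
  if (!inherits(aln, "codon_alignment")) {
    aln <- protein_guided_codon_align(aln, cds_b, ids = ids)
  }
  sites <- find_4d_sites(aln)
  n <- nrow(sites)
  tv <- sum(is_transversion(sites$base_a, sites$base_b))
  raw <- if (n > 0) tv / n else NA_real_
  saturated <- isTRUE(raw >= 0.5)
  corrected <- if (n == 0 || saturated) NA_real_ else -0.5 * log(1 - 2 * raw)
  out <- tibble(
    id_a = aln$ids[1], id_b = aln$ids[2],
    n_4d_sites = n, n_transversions = tv,
    raw_4dtv = raw, corrected_4dtv = corrected,
    saturated = saturated,
    low_information = n < min_sites
  )
  attr(out, "sites") <- sites
  class(out) <- c("fourdtv_estimate", class(out))
  out
}

#' All-pairs corrected 4DTV distance matrix
#'
#' @param cds named character vector of coding sequences (>= 2).
#' @param min_sites passed to [fourdtv()].
#' @return A list of class `fourdtv_matrix`: `pairs` (tidy per-pair tibble)
#'   and `matrix` (symmetric corrected-4DTV matrix, zero diagonal; saturated
#'   or empty pairs are `NA`).
#' @export
pairwise_fourdtv <- function(cds, min_sites = 20L) {
  stopifnot(length(cds) >= 2, !is.null(names(cds)))
  ids <- names(cds)
  pairs <- tidyr::expand_grid(i = seq_along(cds), j = seq_along(cds)) |>
    filter(.data$i < .data$j)
  ests <- purrr::map2(pairs$i, pairs$j, function(i, j) {
    fourdtv(cds[[i]], cds[[j]], min_sites = min_sites, ids = ids[c(i, j)])
  })
  tidy_pairs <- bind_rows(lapply(ests, as_tibble))
  m <- matrix(0, length(cds), length(cds), dimnames = list(ids, ids))
  for (k in seq_len(nrow(pairs))) {
    d <- tidy_pairs$corrected_4dtv[k]
    m[pairs$i[k], pairs$j[k]] <- d
    m[pairs$j[k], pairs$i[k]] <- d
  }
  structure(list(pairs = tidy_pairs, matrix = m), class = "fourdtv_matrix")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via \pkg{ape}), with taxa ordered
#' lexicographically before joining so ties resolve deterministically, and
#' negative branch lengths clamped to zero with a warning.
#'
#' @param m a symmetric distance matrix with row/column names, or a
#'   [pairwise_fourdtv()] result.
#' @return A list with `tree` (an \pkg{ape} `phylo`) and `newick` (text).
#' @export
nj_tree <- function(m) {
  if (inherits(m, "fourdtv_matrix")) m <- m$matrix
  if (!isSymmetric(unname(m))) abort("distance matrix must be symmetric")
  if (anyNA(m)) abort("distance matrix contains undefined (saturated) entries")
  ord <- order(rownames(m))
  m <- m[ord, ord]
  if (nrow(m) == 2) {
    d <- m[1, 2]
    nwk <- sprintf("(%s:%g,%s:%g);", rownames(m)[1], d / 2, rownames(m)[2], d / 2)
    return(list(tree = ape::read.tree(text = nwk), newick = nwk))
  }
  tr <- ape::nj(stats::as.dist(m))
  if (any(tr$edge.length < 0)) {
    warn("negative NJ branch lengths clamped to 0")
    tr$edge.length <- pmax(tr$edge.length, 0)
  }
  list(tree = tr, newick = ape::write.tree(tr))
}

#' Compare residues at labelled functional-domain positions
#'
#' Looks up each labelled position (given as a residue index in the
#' ungapped reference sequence) through a multiple protein alignment and
#' reports every gene's residue at that alignment column, flagging
#' substitutions relative to the reference.
#'
#' @param aln named character vector of equal-length gapped protein
#'   sequences (a multiple alignment).
#' @param reference name of the reference sequence; must be present.
#' @param positions tibble with columns `domain`, `label` and
#'   `reference_position` (1-based residue index in the ungapped reference).
#' @return A tidy tibble: one row per gene x position with `domain`,
#'   `label`, `column`, `gene`, `residue`, `reference_residue`,
#'   `substituted`.
#' @export
diagnostic_residues <- function(aln, reference, positions) {
  if (!reference %in% names(aln)) abort("reference sequence absent from alignment")
  widths <- nchar(aln)
  if (length(unique(widths)) != 1) abort("alignment rows differ in length")
  ref_chars <- strsplit(aln[[reference]], "")[[1]]
  ref_idx <- cumsum(ref_chars != "-")
  cols <- vapply(positions$reference_position, function(p) {
    w <- which(ref_idx == p & ref_chars != "-")
    if (length(w) == 0) NA_integer_ else w[1]
  }, 1L)
  if (anyNA(cols)) abort("a labelled position exceeds the reference length")
  tidyr::expand_grid(k = seq_len(nrow(positions)), gene = names(aln)) |>
    mutate(
      domain = positions$domain[.data$k],
      label = positions$label[.data$k],
      column = cols[.data$k],
      residue = substr(aln[.data$gene], .data$column, .data$column),
      reference_residue = ref_chars[.data$column],
      substituted = .data$residue != .data$reference_residue
    ) |>
    select(-"k")
}
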
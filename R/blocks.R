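#' Exact k-mer self-comparison of a locus (dot-plot matches)
#'
#' Returns every exact k-mer self-match of the locus excluding the trivial
#' main diagonal, as the raw material of a dot plot. Runs of assembly Ns are
#' masked. Only direct-orientation matches are reported by default, since
#' tandem arrays are direct repeats.
#'
#' @param locus a single nucleotide sequence.
#' @param k k-mer size; values below 8 are rejected as spurious-match bait.
#' @param both_strands also report reverse-complement matches.
#' @return A tibble of class `self_matches` with `pos_a` < `pos_b` (0-based
#'   starts), `diag = pos_b - pos_a` and `orientation`; attribute `k` and
#'   `locus_length` are retained for downstream chaining.
#' @export
self_match <- function(locus, k = 16L, both_strands = FALSE) {
  if (k < 8L) abort("k below 8 rejected: expected spurious matches")
  if (nchar(locus) < k) abort("locus shorter than k")
  m <- kmer_matches(locus, locus, k) |>
    filter(.data$pos_a < .data$pos_b) |>
    mutate(orientation = "+")
  if (both_strands) {
    rc <- kmer_matches(locus, revcomp(locus), k)
    n <- nchar(locus)
    rc <- rc |>
      mutate(pos_b = n - .data$pos_b - k) |>
      filter(.data$pos_a < .data$pos_b) |>
      mutate(diag = .data$pos_b - .data$pos_a, orientation = "-")
    m <- bind_rows(m, rc)
  }
  structure(m, k = as.integer(k), locus_length = nchar(locus),
            class = c("self_matches", class(m)))
}

#' Chain self-matches and delimit duplicate blocks
#'
#' Greedily chains co-diagonal matches (within `diag_tolerance`) whose gaps
#' do not exceed `max_gap` into diagonal segments, then derives block
#' boundaries from the clustered segment end points: each segment projects a
#' duplicated interval onto both axes, and the shared end points of those
#' projections tile the duplicated region into blocks. Blocks are classified
#' by the 10-kb rule: local duplications below 10 kb are tandem, larger ones
#' segmental.
#'
#' @param matches a [self_match()] result.
#' @param max_gap maximal within-chain gap in bp.
#' @param min_segment minimal chained-segment length in bp.
#' @param min_block blocks shorter than this are reported but flagged.
#' @param diag_tolerance co-diagonal binning width in bp.
#' @param boundary_tolerance cluster width when merging candidate block
#'   boundaries.
#' @param genes optional tibble (`id`, `start`, `end`) used to assign gene
#'   membership to blocks.
#' @return A list of class `duplicate_blocks`: `blocks` (label, start, end,
#'   length, class, n_genes, genes) and `segments` (chained diagonal
#'   segments).
#' @export
chain_and_delimit <- function(matches, max_gap = 2000L, min_segment = 500L,
                              min_block = 10000L, diag_tolerance = 50L,
                              boundary_tolerance = 2000L, genes = NULL) {
  k <- attr(matches, "k") %||% 16L
  empty <- list(
    blocks = tibble(label = character(), start = integer(), end = integer(),
                    length = integer(), class = character(),
                    n_genes = integer(), genes = character()),
    segments = tibble(start_a = integer(), start_b = integer(),
                      length = integer(), matched = integer(),
                      diag = integer())
  )
  if (nrow(matches) == 0L) {
    return(structure(empty, class = "duplicate_blocks"))
  }
  m <- filter(matches, .data$orientation == "+")
  # bin diagonals so slightly drifting chains still group together
  m <- mutate(m, diag_bin = as.integer(round(.data$diag / diag_tolerance)))
  runs <- m |>
    rename(true_diag = "diag") |>
    mutate(diag = .data$diag_bin) |>
    select("pos_a", "pos_b", "diag") |>
    exact_runs(k = k)
  segs <- chain_codiagonal(runs, max_gap = max_gap) |>
    filter(.data$length >= min_segment)
  if (nrow(segs) == 0L) {
    return(structure(empty, class = "duplicate_blocks"))
  }
  # candidate boundaries: projected segment starts on both axes (ends are
  # unreliable when partner blocks differ in length), plus the far end of
  # the duplicated region
  cand <- sort(c(segs$start_a, segs$start_b))
  cl <- cumsum(c(TRUE, diff(cand) > boundary_tolerance))
  bounds <- vapply(split(cand, cl), function(x) as.integer(round(median(x))), 1L)
  region_end <- max(segs$start_a + segs$length, segs$start_b + segs$length)
  bounds <- sort(unique(c(bounds, as.integer(region_end))))
  if (length(bounds) < 2L) {
    return(structure(empty, class = "duplicate_blocks"))
  }
  blocks <- tibble(
    start = bounds[-length(bounds)],
    end = bounds[-1]
  ) |>
    mutate(length = .data$end - .data$start,
           label = paste0("block_", row_number()),
           class = ifelse(.data$length < 10000L, "tandem", "segmental"),
           short = .data$length < min_block)
  if (!is.null(genes)) {
    blocks$genes <- vapply(seq_len(nrow(blocks)), function(i) {
      g <- genes$id[genes$start >= blocks$start[i] & genes$start < blocks$end[i]]
      paste(g, collapse = ",")
    }, "")
    blocks$n_genes <- lengths(strsplit(blocks$genes, ",")) -
      (blocks$genes == "")
  } else {
    blocks$genes <- NA_character_
    blocks$n_genes <- NA_integer_
  }
  structure(list(
    blocks = select(blocks, "label", "start", "end", "length", "class",
                    "n_genes", "genes"),
    segments = segs
  ), class = "duplicate_blocks")
}

#' @export
print.duplicate_blocks <- function(x, ...) {
  cat("<duplicate_blocks> ", nrow(x$blocks), " blocks from ",
      nrow(x$segments), " chained segments\n", sep = "")
  print(x$blocks)
  invisible(x)
}

#' Percent identity between two duplicate blocks
#'
#' Anchor-based identity: exact anchors are chained colinearly, identity is
#' counted directly inside each gapless chained segment, short gaps between
#' segments are aligned globally, and columns opposite unfilled gaps longer
#' than `gap_cap` (typically TE insertions private to one block) are
#' excluded from the denominator.
#'
#' @param block_a,block_b block sequences.
#' @param k anchor k-mer size.
#' @param max_gap co-diagonal bridge length.
#' @param gap_cap gaps longer than this are excluded, not penalised.
#' @return One-row tibble of class `block_pair`: `percent_identity`,
#'   `aligned_length`, `matches`, `n_segments`, `undefined` (no anchors).
#' @export
block_identity <- function(block_a, block_b, k = 16L, max_gap = 2000L,
                           gap_cap = 5000L) {
  stopifnot(nchar(block_a) > 0, nchar(block_b) > 0)
  runs <- exact_runs(kmer_matches(block_a, block_b, k), k = k)
  segs <- chain_codiagonal(runs, max_gap = max_gap)
  segs <- colinear_chain(segs)
  if (nrow(segs) == 0L) {
    out <- tibble(percent_identity = NA_real_, aligned_length = 0L,
                  matches = 0L, n_segments = 0L, undefined = TRUE)
    class(out) <- c("block_pair", class(out))
    return(out)
  }
  cols <- 0
  hits <- 0
  for (i in seq_len(nrow(segs))) {
    len <- segs$length[i]
    ident <- hamming_identity(block_a, segs$start_a[i], block_b,
                              segs$start_b[i], len)
    cols <- cols + len
    hits <- hits + round(ident * len)
    if (i < nrow(segs)) {
      ga_from <- segs$start_a[i] + len
      gb_from <- segs$start_b[i] + len
      ga <- segs$start_a[i + 1] - ga_from
      gb <- segs$start_b[i + 1] - gb_from
      if (ga < 0 || gb < 0) next
      if (min(ga, gb) == 0L) {
        g <- max(ga, gb)
        if (g <= gap_cap) cols <- cols + g  # short unfilled gap: count, no match
      } else if (max(ga, gb) <= gap_cap) {
        pa <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(substr(block_a, ga_from + 1L, ga_from + ga)),
          Biostrings::DNAString(substr(block_b, gb_from + 1L, gb_from + gb)),
          type = "global")
        cols <- cols + Biostrings::nchar(pa)
        hits <- hits + Biostrings::nmatch(pa)
      } else {
        # both sides long and dissimilar: align the shorter against nothing
        cols <- cols + min(ga, gb)
      }
    }
  }
  out <- tibble(percent_identity = 100 * hits / cols,
                aligned_length = as.integer(cols),
                matches = as.integer(hits),
                n_segments = nrow(segs), undefined = FALSE)
  class(out) <- c("block_pair", class(out))
  out
}

#' Divergence between the two LTRs of a retroelement
#'
#' The two long terminal repeats of a retrotransposon are identical at
#' insertion; their divergence clocks the insertion age. Reports the raw
#' p-distance and the Jukes-Cantor corrected distance, excluding gap
#' columns (the sources differ on whether such rates are raw or corrected,
#' so both are given).
#'
#' @param ltr5,ltr3 the two LTR sequences; aligned directly if equal
#'   length, otherwise pairwise-aligned first.
#' @return One-row tibble: `n_sites`, `n_differences`, `p_distance`,
#'   `jc_distance`, `low_information` (LTR under 50 bp).
#' @export
ltr_divergence <- function(ltr5, ltr3) {
  low <- nchar(ltr5) < 50L || nchar(ltr3) < 50L
  if (nchar(ltr5) == nchar(ltr3)) {
    a <- strsplit(toupper(ltr5), "")[[1]]
    b <- strsplit(toupper(ltr3), "")[[1]]
  } else {
    pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(toupper(ltr5)),
                                        Biostrings::DNAString(toupper(ltr3)),
                                        type = "global")
    a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  }
  keep <- a %in% DNA_BASES & b %in% DNA_BASES
  n <- sum(keep)
  d <- sum(a[keep] != b[keep])
  p <- d / n
  jc <- if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  tibble(n_sites = n, n_differences = d, p_distance = p, jc_distance = jc,
         low_information = low)
}

#' TE coverage fraction in windows along a locus
#'
#' Overlapping TE annotations are merged before counting, so co-located
#' elements are not double counted. Windows tile the locus (the last one may
#' be shorter), hence the window-length-weighted mean equals the whole-locus
#' TE fraction.
#'
#' @param locus_length locus length in bp.
#' @param te a tibble with `start`, `end` (0-based half-open) TE intervals.
#' @param window_sizes one or more window sizes in bp.
#' @return A tibble: `window_size`, `start`, `end`, `centre`, `te_fraction`.
#' @export
te_fraction_profile <- function(locus_length, te, window_sizes = c(25000L, 50000L)) {
  merged <- if (nrow(te) == 0L) {
    IRanges::IRanges()
  } else {
    IRanges::reduce(IRanges::IRanges(start = te$start + 1L, end = te$end))
  }
  purrr::map_dfr(window_sizes, function(w) {
    if (w > locus_length) {
      warn("window larger than locus: using a single whole-locus window")
      w <- locus_length
    }
    starts <- seq(0L, locus_length - 1L, by = w)
    ends <- pmin(starts + w, locus_length)
    covered <- vapply(seq_along(starts), function(i) {
      hit <- IRanges::restrict(merged, start = starts[i] + 1L, end = ends[i])
      sum(IRanges::width(hit))
    }, 1L)
    tibble(window_size = w, start = starts, end = ends,
           centre = (starts + ends) / 2,
           te_fraction = covered / (ends - starts))
  })
}

#' Flank conservation profile around two duplicate genes
#'
#' Chains exact anchors between the two genes' flanks and reports per-window
#' identity (computed gaplessly at the chained diagonal), plus how far from
#' the CDS the conservation stays at or above `min_identity`. Mirrors
#' global-alignment identity curves over +/- `flank` bp around each copy.
#'
#' @param genome a single locus sequence, or a named vector of two
#'   sequences when the genes live on different sequences.
#' @param gene_a,gene_b lists or one-row tibbles with `start`, `end`
#'   (0-based half-open gene coordinates) and optionally `seqid`.
#' @param flank bp examined on each side of the CDS.
#' @param window identity-window size in bp.
#' @param min_identity conservation threshold.
#' @return A list of class `flank_profile`: `profile` (side, offset,
#'   identity per window) and `extent` (per-side bp to the first window
#'   failing the threshold), plus a `truncated` flag when a flank ran past
#'   a sequence end.
#' @export
flank_conservation <- function(genome, gene_a, gene_b, flank = 10000L,
                               window = 100L, min_identity = 0.7) {
  get_seq <- function(g) {
    if (length(genome) == 1L) genome[[1]]
    else genome[[g$seqid %||% names(genome)[1]]]
  }
  sa <- get_seq(gene_a); sb <- get_seq(gene_b)
  cut_flank <- function(s, from, to) {
    substr(s, max(from, 0L) + 1L, min(to, nchar(s)))
  }
  truncated <- FALSE
  sides <- purrr::map_dfr(c("upstream", "downstream"), function(side) {
    if (side == "upstream") {
      fa <- cut_flank(sa, gene_a$start - flank, gene_a$start)
      fb <- cut_flank(sb, gene_b$start - flank, gene_b$start)
      if (nchar(fa) < flank || nchar(fb) < flank) truncated <<- TRUE
      # orient so offset 0 is adjacent to the CDS
      fa <- revcomp(fa); fb <- revcomp(fb)
    } else {
      fa <- cut_flank(sa, gene_a$end, gene_a$end + flank)
      fb <- cut_flank(sb, gene_b$end, gene_b$end + flank)
      if (nchar(fa) < flank || nchar(fb) < flank) truncated <<- TRUE
    }
    segs <- anchor_chain(fa, fb, min_anchor = 10L, max_gap = 200L,
                         min_identity = min_identity)
    n_win <- nchar(fa) %/% window
    if (n_win == 0L) return(tibble())
    ident <- vapply(seq_len(n_win), function(i) {
      w_from <- (i - 1L) * window
      mid <- w_from + window %/% 2L
      cover <- segs[segs$start_a <= mid & segs$start_a + segs$length > mid, ]
      if (nrow(cover) == 0L) return(0)
      d <- cover$diag[1]
      if (w_from + d < 0 || w_from + d + window > nchar(fb)) return(0)
      hamming_identity(fa, w_from, fb, w_from + d, window)
    }, 1.0)
    tibble(side = side, offset = (seq_len(n_win) - 1L) * window,
           identity = ident)
  })
  extent <- sides |>
    group_by(.data$side) |>
    summarise(extent = {
      fail <- which(.data$identity < min_identity)
      if (length(fail) == 0L) max(.data$offset) + window
      else (fail[1] - 1L) * window
    }, .groups = "drop")
  structure(list(profile = sides, extent = extent, truncated = truncated),
            class = "flank_profile")
}
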
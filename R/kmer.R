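# k-mer matching and anchor chaining: the shared machinery behind the
# dot-plot self-comparison, block identity scoring, promoter segmentation
# and flank conservation profiles. All coordinates 0-based half-open.

#' @importFrom data.table data.table
NULL

kmer_starts <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(integer())
  0:(n - k)
}

kmer_strings <- function(seq, k) {
  pos <- kmer_starts(seq, k)
  substring(seq, pos + 1L, pos + k)
}

# all exact k-mer matches between two sequences as (pos_a, pos_b) 0-based
kmer_matches <- function(seq_a, seq_b, k, drop_n = TRUE) {
  ka <- kmer_strings(seq_a, k)
  kb <- kmer_strings(seq_b, k)
  da <- data.table(kmer = ka, pos_a = kmer_starts(seq_a, k))
  db <- data.table(kmer = kb, pos_b = kmer_starts(seq_b, k))
  if (drop_n) {
    da <- da[!grepl("N", da$kmer, fixed = TRUE)]
    db <- db[!grepl("N", db$kmer, fixed = TRUE)]
  }
  # only k-mers present in both can match
  da <- da[da$kmer %in% db$kmer]
  db <- db[db$kmer %in% da$kmer]
  if (nrow(da) == 0L) {
    return(tibble(pos_a = integer(), pos_b = integer(), diag = integer()))
  }
  m <- merge(da, db, by = "kmer", allow.cartesian = TRUE)
  tibble(pos_a = m$pos_a, pos_b = m$pos_b, diag = m$pos_b - m$pos_a)
}

# merge co-diagonal k-mer matches into maximal exact runs
# returns (start_a, start_b, length, diag), length includes the k-mer width
exact_runs <- function(matches, k) {
  if (nrow(matches) == 0L) {
    return(tibble(start_a = integer(), start_b = integer(),
                  length = integer(), diag = integer()))
  }
  m <- arrange(matches, .data$diag, .data$pos_a)
  new_run <- c(TRUE, diff(m$pos_a) != 1L | diff(m$diag) != 0L)
  run_id <- cumsum(new_run)
  m |>
    mutate(run = run_id) |>
    group_by(.data$run) |>
    summarise(start_a = min(.data$pos_a), start_b = min(.data$pos_b),
              length = max(.data$pos_a) - min(.data$pos_a) + k,
              diag = .data$diag[1], .groups = "drop") |>
    select(-dplyr::any_of("run"))
}

hamming_identity <- function(seq_a, from_a, seq_b, from_b, len) {
  if (len <= 0) return(1)
  a <- strsplit(substr(seq_a, from_a + 1L, from_a + len), "")[[1]]
  b <- strsplit(substr(seq_b, from_b + 1L, from_b + len), "")[[1]]
  mean(a == b)
}

# chain co-diagonal runs separated by gaps <= max_gap into gapless segments.
# If check_identity, a gap is only bridged when identity over a window
# centred on it (gap plus anchored context, >= `window` bp) passes
# min_identity: a short substitution cluster bridges, unrelated interior
# sequence does not.
chain_codiagonal <- function(runs, seq_a = NULL, seq_b = NULL,
                             max_gap = 2000, check_identity = FALSE,
                             min_identity = 0.7, window = 100L) {
  if (nrow(runs) == 0L) {
    return(mutate(runs, matched = integer()))
  }
  r <- arrange(runs, .data$diag, .data$start_a)
  gap <- c(Inf, r$start_a[-1] - (r$start_a[-nrow(r)] + r$length[-nrow(r)]))
  gap[c(TRUE, diff(r$diag) != 0L)] <- Inf
  bridge <- gap <= max_gap
  if (check_identity && any(bridge)) {
    idx <- which(bridge & gap > 0)
    for (i in idx) {
      g_from <- r$start_a[i - 1] + r$length[i - 1]
      g_len <- r$start_a[i] - g_from
      pad <- max(0L, ceiling((window - g_len) / 2))
      from <- max(g_from - pad, 0L)
      len <- min(g_len + 2 * pad, nchar(seq_a) - from,
                 nchar(seq_b) - from - r$diag[i])
      ident <- hamming_identity(seq_a, from, seq_b, from + r$diag[i], len)
      if (ident < min_identity) bridge[i] <- FALSE
    }
  }
  seg_id <- cumsum(!bridge)
  r |>
    mutate(seg = seg_id) |>
    group_by(.data$seg) |>
    summarise(s_a = min(.data$start_a),
              s_b = min(.data$start_b),
              e_a = max(.data$start_a + .data$length),
              matched = sum(.data$length),
              d = .data$diag[1], .groups = "drop") |>
    dplyr::transmute(start_a = .data$s_a, start_b = .data$s_b,
                     length = .data$e_a - .data$s_a,
                     matched = .data$matched, diag = .data$d)
}

# weighted colinear chaining (longest increasing subsequence on start_b,
# weighted by matched bases); m is small after co-diagonal merging
colinear_chain <- function(segs) {
  m <- nrow(segs)
  if (m <= 1L) return(segs)
  s <- arrange(segs, .data$start_a, .data$start_b)
  best <- s$matched
  prev <- rep(NA_integer_, m)
  for (i in seq_len(m)[-1]) {
    for (j in seq_len(i - 1)) {
      ok <- s$start_a[j] + s$length[j] <= s$start_a[i] + 10 &&
        s$start_b[j] + s$length[j] <= s$start_b[i] + 10
      if (ok && best[j] + s$matched[i] > best[i]) {
        best[i] <- best[j] + s$matched[i]
        prev[i] <- j
      }
    }
  }
  i <- which.max(best)
  keep <- integer()
  while (!is.na(i)) {
    keep <- c(i, keep)
    i <- prev[i]
  }
  s[keep, ]
}

#' Colinear chain of exact anchors between two sequences
#'
#' Finds all maximal exact matches of at least `min_anchor` bp, merges
#' co-diagonal anchors whose gap interiors pass `min_identity`, and keeps
#' the best colinear chain by total matched bases. This is the anchor
#' machinery behind promoter segmentation, flank conservation and block
#' identity scoring.
#'
#' @param seq_a,seq_b nucleotide sequences.
#' @param min_anchor minimal exact-anchor length in bp (default 10).
#' @param max_gap maximal gap bridged between co-diagonal anchors.
#' @param min_identity identity a bridged gap must reach.
#' @param window context width (bp) over which gap identity is assessed.
#' @return A tibble of chained gapless segments: `start_a`, `start_b`
#'   (0-based), `length`, `matched` (exact bases), `diag`, `identity`
#'   (direct per-base identity of the segment).
#' @export
anchor_chain <- function(seq_a, seq_b, min_anchor = 10L, max_gap = 200L,
                         min_identity = 0.7, window = 100L) {
  if (min_anchor < 8L) abort("min_anchor below 8 invites spurious anchors")
  runs <- exact_runs(kmer_matches(seq_a, seq_b, k = min_anchor), k = min_anchor)
  runs <- filter(runs, .data$length >= min_anchor)
  segs <- chain_codiagonal(runs, seq_a, seq_b, max_gap = max_gap,
                           check_identity = TRUE, min_identity = min_identity,
                           window = window)
  segs <- colinear_chain(segs)
  if (nrow(segs) == 0L) {
    return(mutate(segs, identity = double()))
  }
  segs$identity <- vapply(seq_len(nrow(segs)), function(i) {
    hamming_identity(seq_a, segs$start_a[i], seq_b, segs$start_b[i],
                     segs$length[i])
  }, 1.0)
  segs
}
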
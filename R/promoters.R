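#' Segment duplicate promoters into conserved and copy-unique regions
#'
#' Chains exact anchors (at least `min_anchor` bp, the classic minimum HSP
#' length for promoter-scale alignment) colinearly between the two
#' promoters; chained regions whose identity passes `min_identity` become
#' conserved segments, and everything else is unique to the copy that
#' carries it. Segments tile each promoter without overlap, so conserved
#' plus unique lengths sum to each promoter's length. The complementarity
#' score is the fraction of the segment union private to exactly one copy:
#' 0 for identical promoters, approaching 1 for unrelated ones -- the
#' quantity the duplication-degeneration-complementation (DDC) model
#' predicts to grow as duplicates partition ancestral regulatory modules.
#'
#' @param promoter_a,promoter_b promoter sequences (conventionally the
#'   2,000 bp upstream of the translation start).
#' @param ids copy identifiers.
#' @param min_anchor minimal exact anchor (default 10 bp).
#' @param max_gap co-diagonal bridge length between anchors.
#' @param min_identity identity required of conserved segments (and of
#'   bridged gap interiors).
#' @return A list of class `promoter_comparison`: `segments` (status,
#'   owner, start/end per owner), `score` (complementarity in [0,1]),
#'   `no_anchors` flag, and the input ids.
#' @export
segment_promoters <- function(promoter_a, promoter_b, ids = c("a", "b"),
                              min_anchor = 10L, max_gap = 200L,
                              min_identity = 0.7) {
  stopifnot(nchar(promoter_a) > 0, nchar(promoter_b) > 0)
  na <- nchar(promoter_a); nb <- nchar(promoter_b)
  segs <- anchor_chain(promoter_a, promoter_b, min_anchor = min_anchor,
                       max_gap = max_gap, min_identity = min_identity)
  segs <- filter(segs, .data$identity >= min_identity,
                 .data$length >= min_anchor)
  if (nrow(segs) == 0L) {
    out <- list(
      segments = tibble(
        status = "unique", owner = ids,
        start = c(0L, 0L), end = c(na, nb),
        start_other = NA_integer_, end_other = NA_integer_,
        length = c(na, nb)
      ),
      score = 1, no_anchors = TRUE, ids = ids
    )
    return(structure(out, class = "promoter_comparison"))
  }
  conserved <- tibble(
    status = "conserved", owner = paste(ids, collapse = "+"),
    start = segs$start_a, end = segs$start_a + segs$length,
    start_other = segs$start_b, end_other = segs$start_b + segs$length,
    length = segs$length
  )
  gaps_of <- function(spans, total) {
    edges <- c(0L, as.vector(t(spans)), total)
    s <- edges[seq(1, length(edges), by = 2)]
    e <- edges[seq(2, length(edges), by = 2)]
    keep <- e > s
    tibble(start = s[keep], end = e[keep])
  }
  ua <- gaps_of(cbind(segs$start_a, segs$start_a + segs$length), na) |>
    mutate(status = "unique", owner = ids[1],
           start_other = NA_integer_, end_other = NA_integer_,
           length = .data$end - .data$start)
  ub <- gaps_of(cbind(segs$start_b, segs$start_b + segs$length), nb) |>
    mutate(status = "unique", owner = ids[2],
           start_other = NA_integer_, end_other = NA_integer_,
           length = .data$end - .data$start)
  segments <- bind_rows(conserved, ua, ub) |>
    select("status", "owner", "start", "end", "start_other", "end_other",
           "length") |>
    arrange(dplyr::desc(.data$status == "conserved"), .data$owner, .data$start)
  unique_total <- sum(segments$length[segments$status == "unique"])
  union_total <- sum(conserved$length) + unique_total
  structure(list(segments = segments,
                 score = unique_total / union_total,
                 no_anchors = FALSE, ids = ids),
            class = "promoter_comparison")
}

#' @export
print.promoter_comparison <- function(x, ...) {
  cat("<promoter_comparison> ", paste(x$ids, collapse = " vs "),
      ", complementarity score ", round(x$score, 3), "\n", sep = "")
  print(x$segments)
  invisible(x)
}

#' Presence patterns and deletion polarity across a promoter triplet
#'
#' For three duplicate promoters, labels each segment by its presence
#' pattern: present in all three, present in exactly two (a parsimony-
#' inferred deletion in the third copy), or unique to one. Under a
#' deletion-only history, two-present segments should outnumber one-present
#' segments -- the signature of progressive degeneration of an ancestral
#' promoter rather than copy-and-paste insertion.
#'
#' @param promoters named character vector of exactly three promoters.
#' @param min_segment ignore presence runs shorter than this.
#' @param ... passed to [segment_promoters()].
#' @return A list of class `triplet_polarity`: `segments` (owner, start,
#'   end, pattern, deleted_in), `counts` (`n_present2`, `n_present1`) and
#'   `polarity` (`"deletion-dominated"` or `"insertion-dominated"`).
#' @export
triplet_polarity <- function(promoters, min_segment = 20L, ...) {
  stopifnot(length(promoters) == 3L, !is.null(names(promoters)))
  ids <- names(promoters)
  pairs <- utils::combn(3L, 2L)
  # conserved coverage masks: cov[[i]][[j]] = positions of promoter i
  # conserved with promoter j
  cov <- lapply(seq_len(3), function(i) {
    lapply(seq_len(3), function(j) logical(nchar(promoters[[i]])))
  })
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    cmp <- segment_promoters(promoters[[i]], promoters[[j]],
                             ids = ids[c(i, j)], ...)
    cons <- filter(cmp$segments, .data$status == "conserved")
    for (r in seq_len(nrow(cons))) {
      cov[[i]][[j]][seq(cons$start[r] + 1L, cons$end[r])] <- TRUE
      cov[[j]][[i]][seq(cons$start_other[r] + 1L, cons$end_other[r])] <- TRUE
    }
  }
  seg_rows <- purrr::map_dfr(seq_len(3), function(i) {
    others <- setdiff(seq_len(3), i)
    with1 <- cov[[i]][[others[1]]]
    with2 <- cov[[i]][[others[2]]]
    pat <- dplyr::case_when(with1 & with2 ~ "present_in_3",
                            with1 ~ paste0("present_in_2_missing_", ids[others[2]]),
                            with2 ~ paste0("present_in_2_missing_", ids[others[1]]),
                            TRUE ~ "unique")
    r <- rle(pat)
    ends <- cumsum(r$lengths)
    tibble(owner = ids[i],
           start = c(0L, head(ends, -1)), end = ends,
           length = r$lengths, pattern = r$values)
  }) |>
    filter(.data$length >= min_segment)
  # a 2-present physical segment appears as one run in each of its two
  # owners, so halve the run count to count each event once
  p2 <- seg_rows |>
    filter(startsWith(.data$pattern, "present_in_2")) |>
    mutate(deleted_in = sub("present_in_2_missing_", "", .data$pattern)) |>
    group_by(.data$deleted_in) |>
    summarise(events = n() / 2, .groups = "drop")
  n_present2 <- sum(ceiling(p2$events))
  n_present1 <- sum(seg_rows$pattern == "unique")
  structure(list(
    segments = seg_rows |>
      mutate(deleted_in = ifelse(startsWith(.data$pattern, "present_in_2"),
                                 sub("present_in_2_missing_", "", .data$pattern),
                                 NA_character_)),
    counts = tibble(n_present2 = n_present2, n_present1 = n_present1),
    polarity = if (n_present2 >= n_present1) "deletion-dominated"
               else "insertion-dominated"
  ), class = "triplet_polarity")
}

#' Bundled cis-element consensus library
#'
#' Reads the consensus motif table shipped with the package: IUPAC consensi
#' for the motif categories relevant to anthocyanin-pathway promoters
#' (Myb-binding, light-responsive, drought MBS, ABA-responsive,
#' MeJA-responsive, heat stress) plus common core elements marked "other".
#' The TSV is editable; [scan_motifs()] accepts any table with the same
#' columns.
#'
#' @return A tibble: `name`, `category`, `consensus`.
#' @export
motif_library <- function() {
  path <- system.file("extdata", "motif_library.tsv", package = "paralogon")
  as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Scan sequences for IUPAC consensus motifs
#'
#' Both strands are scanned; overlapping hits are all reported.
#'
#' @param seqs named character vector of sequences (e.g. promoter segments).
#' @param library a motif table as from [motif_library()].
#' @return A tibble of hits: `seq_id`, `motif`, `category`, `start`
#'   (0-based), `end`, `strand`, `match`.
#' @export
scan_motifs <- function(seqs, library = motif_library()) {
  stopifnot(all(c("name", "category", "consensus") %in% names(library)))
  bad <- !grepl("^[ACGTRYSWKMBDHVN]+$", library$consensus)
  if (any(bad)) {
    abort(paste0("malformed IUPAC consensus: ",
                 paste(library$name[bad], collapse = ", ")))
  }
  purrr::map_dfr(names(seqs), function(id) {
    s <- seqs[[id]]
    if (nchar(s) == 0L) return(tibble())
    subj <- Biostrings::DNAString(s)
    purrr::map_dfr(seq_len(nrow(library)), function(r) {
      pat <- library$consensus[r]
      hit_one <- function(pattern, strand) {
        if (nchar(s) < nchar(pattern)) return(tibble())
        m <- Biostrings::matchPattern(Biostrings::DNAString(pattern), subj,
                                      fixed = FALSE)
        if (length(m) == 0L) return(tibble())
        tibble(seq_id = id, motif = library$name[r],
               category = library$category[r],
               start = Biostrings::start(m) - 1L,
               end = Biostrings::end(m),
               strand = strand,
               match = as.character(m))
      }
      bind_rows(hit_one(pat, "+"), hit_one(revcomp(pat), "-"))
    })
  })
}
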
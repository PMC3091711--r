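#' Classify diagnostic 4D sites of a candidate recombinant
#'
#' At every four-fold degenerate third-codon site shared by the candidate
#' and two groups of paralogues, the candidate is compared with the strict-
#' majority consensus of each group. Sites where the consensuses differ by
#' a transversion assign the candidate to one parental group; sites
#' polymorphic within a group are reported separately (the "long ticks" of
#' a diagnostic-site plot), as are sites where the candidate is a
#' transversion away from both groups ("short ticks").
#'
#' @param candidate a single CDS (character).
#' @param group_a,group_b named character vectors of CDS, each internally
#'   consistent: all within-group corrected 4DTV at or below
#'   `within_ceiling`.
#' @param within_ceiling maximal within-group corrected 4DTV (default 0.01).
#' @param candidate_id identifier for reporting.
#' @return A tibble of class `site_classification` with `column` (codon),
#'   `position` (bp along the candidate CDS), `class`, `base_candidate`,
#'   `consensus_a`, `consensus_b`; candidate-vs-group corrected 4DTV means
#'   are kept in attributes `dist_to_a` and `dist_to_b`.
#' @export
classify_sites <- function(candidate, group_a, group_b,
                           within_ceiling = 0.01, candidate_id = "candidate") {
  stopifnot(length(group_a) >= 1, length(group_b) >= 1)
  all_seqs <- c(candidate = candidate, group_a, group_b)
  lens <- nchar(all_seqs)
  if (length(unique(lens)) != 1L) {
    abort("all sequences must be pre-aligned to equal length (no indels)")
  }
  check_group <- function(g, label) {
    if (length(g) < 2) return(invisible())
    for (i in seq_along(g)[-length(g)]) for (j in (i + 1):length(g)) {
      est <- fourdtv(g[[i]], g[[j]])
      if (is.na(est$corrected_4dtv) || est$corrected_4dtv > within_ceiling) {
        abort(paste0("group ", label, " is not internally consistent: ",
                     "within-group 4DTV exceeds ", within_ceiling))
      }
    }
  }
  check_group(group_a, "A")
  check_group(group_b, "B")
  n_cod <- lens[1] %/% 3L
  cods <- lapply(all_seqs, codons_of)
  cand <- cods[[1]]
  mat <- do.call(rbind, cods)
  pref <- substr(mat, 1, 2)
  dim(pref) <- dim(mat)
  third <- substr(mat, 3, 3)
  dim(third) <- dim(mat)
  ia <- 1L + seq_along(group_a)
  ib <- 1L + length(group_a) + seq_along(group_b)
  strict_majority <- function(x) {
    tb <- sort(table(x), decreasing = TRUE)
    if (length(tb) > 1 && tb[1] == tb[2]) NA_character_ else names(tb)[1]
  }
  rows <- purrr::map_dfr(seq_len(n_cod), function(cc) {
    col_pref <- pref[, cc]
    if (length(unique(col_pref)) != 1L) return(tibble())
    if (!col_pref[1] %in% FOURFOLD_PREFIXES) return(tibble())
    b <- third[, cc]
    if (!all(b %in% DNA_BASES)) return(tibble())
    ca <- strict_majority(b[ia])
    cb <- strict_majority(b[ib])
    var_within <- length(unique(b[ia])) > 1 || length(unique(b[ib])) > 1 ||
      is.na(ca) || is.na(cb)
    bc <- b[1]
    cls <- if (var_within) {
      "variable-within-group"
    } else if (is_transversion(ca, cb)) {
      if (bc == ca) "matches-group-A"
      else if (bc == cb) "matches-group-B"
      else if (is_transversion(bc, ca) && is_transversion(bc, cb)) {
        "transversion-to-both"
      } else NA_character_
    } else if (!is.na(ca) && !is.na(cb) && bc != ca && bc != cb &&
               is_transversion(bc, ca) && is_transversion(bc, cb)) {
      "transversion-to-both"
    } else {
      NA_character_
    }
    if (is.na(cls)) return(tibble())
    tibble(column = cc, position = 3L * cc, class = cls,
           base_candidate = bc,
           consensus_a = ca %||% NA_character_,
           consensus_b = cb %||% NA_character_)
  })
  if (nrow(rows) == 0L) {
    warn("no informative sites between candidate and groups")
  }
  mean_dist <- function(g) {
    mean(vapply(g, function(s) fourdtv(candidate, s)$corrected_4dtv, 1.0))
  }
  structure(rows, candidate_id = candidate_id,
            dist_to_a = mean_dist(group_a), dist_to_b = mean_dist(group_b),
            class = c("site_classification", class(rows)))
}

max_excursion_stat <- function(lab) {
  # lab: +1 for group-A sites, -1 for group-B sites, in positional order
  w <- cumsum(lab)
  k <- which.max(abs(w))
  list(stat = abs(w[k]), argmax = k)
}

#' Detect a chimeric paralogue from classified diagnostic sites
#'
#' Orders the group-assigned sites along the candidate, walks +1 for each
#' group-A site and -1 for each group-B site, and takes the maximal
#' absolute excursion of the walk as the asymmetry statistic; the
#' breakpoint estimate is the site at the extremum. Significance comes from
#' permuting the site labels: exhaustively over all label arrangements when
#' their number is small, otherwise by seeded Monte Carlo.
#'
#' @param classifications a [classify_sites()] result.
#' @param n_perm Monte Carlo permutations (default 10,000).
#' @param seed integer seed for the permutation draw.
#' @param exact_limit enumerate all arrangements exhaustively when
#'   `choose(n, nA)` does not exceed this (default 20,000).
#' @return A list of class `chimera_report`: class counts, candidate-to-
#'   group corrected 4DTV, `statistic`, `breakpoint` (bp along candidate,
#'   last site of the A-dominant side), `breakpoint_site` (index among
#'   informative sites), `p_value`, `method` ("exact" or "permutation").
#' @export
detect_chimera <- function(classifications, n_perm = 10000L, seed = 1L,
                           exact_limit = 20000L) {
  cl <- classifications
  inf <- filter(cl, .data$class %in% c("matches-group-A", "matches-group-B")) |>
    arrange(.data$position)
  n <- nrow(inf)
  if (n < 6L) abort("fewer than 6 informative sites: cannot test for chimerism")
  lab <- ifelse(inf$class == "matches-group-A", 1L, -1L)
  obs <- max_excursion_stat(lab)
  n_a <- sum(lab == 1L)
  n_arr <- choose(n, n_a)
  if (n_arr <= exact_limit) {
    combs <- utils::combn(n, n_a)
    stats <- apply(combs, 2, function(ix) {
      l <- rep(-1L, n); l[ix] <- 1L
      max_excursion_stat(l)$stat
    })
    p <- mean(stats >= obs$stat)
    method <- "exact"
  } else {
    p <- with_substream(seed, "chimera_perm", {
      ge <- 0L
      for (b in seq_len(n_perm)) {
        l <- sample(lab)
        if (max_excursion_stat(l)$stat >= obs$stat) ge <- ge + 1L
      }
      (ge + 1) / (n_perm + 1)
    })
    method <- "permutation"
  }
  structure(list(
    candidate = attr(cl, "candidate_id"),
    counts = dplyr::count(as_tibble(cl), .data$class),
    dist_to_a = attr(cl, "dist_to_a"),
    dist_to_b = attr(cl, "dist_to_b"),
    statistic = obs$stat,
    breakpoint_site = obs$argmax,
    breakpoint = inf$position[obs$argmax],
    n_informative = n,
    p_value = p,
    method = method
  ), class = "chimera_report")
}

#' @export
print.chimera_report <- function(x, ...) {
  cat("<chimera_report> ", x$candidate, ": max excursion ", x$statistic,
      " over ", x$n_informative, " informative sites\n",
      "breakpoint ~", x$breakpoint, " bp; p = ", format.pval(x$p_value),
      " (", x$method, ")\n", sep = "")
  invisible(x)
}
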
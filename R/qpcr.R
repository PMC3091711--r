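#' Design copy-specific primers on a paralogue alignment
#'
#' Enumerates candidate primer sites whose 3'-terminal base sits on a
#' position that discriminates the target copy from every other paralogue,
#' the classic design for selective amplification within a highly similar
#' gene family. Forward primers end on the discriminating base; reverse
#' primers are the reverse complement of a window starting on it. Each
#' candidate is validated against all paralogues: a perfect 3'-terminal
#' match to the target and at least a 3'-terminal mismatch to every
#' non-target.
#'
#' @param seqs named character vector of equal-length aligned paralogue
#'   sequences (gaps `-` allowed).
#' @param target name of the copy to amplify.
#' @param primer_length primer length in nt (default 20).
#' @param amplicon_min,amplicon_max admissible product size range in bp.
#' @return A tibble of validated primer pairs: `forward`, `reverse`,
#'   `f_start`, `f_end`, `r_start`, `r_end` (0-based on the target),
#'   `product_length`, `target`. Zero rows with attribute
#'   `indistinguishable = TRUE` when no discriminating site exists.
#' @export
design_copy_specific_primers <- function(seqs, target, primer_length = 20L,
                                         amplicon_min = 100L,
                                         amplicon_max = 1000L) {
  stopifnot(target %in% names(seqs), length(seqs) >= 2)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) abort("paralogues must be aligned to equal length")
  chars <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(chars) <- names(seqs)
  t_row <- chars[target, ]
  others <- chars[setdiff(names(seqs), target), , drop = FALSE]
  # discriminating columns: target base differs from every other copy
  disc <- which(vapply(seq_len(ncol(chars)), function(c) {
    t_row[c] %in% DNA_BASES && all(others[, c] != t_row[c])
  }, TRUE))
  empty <- tibble(forward = character(), reverse = character(),
                  f_start = integer(), f_end = integer(),
                  r_start = integer(), r_end = integer(),
                  product_length = integer(), target = character())
  if (length(disc) == 0L) {
    attr(empty, "indistinguishable") <- TRUE
    message("paralogues are indistinguishable: no discriminating site")
    return(empty)
  }
  tgt_seq <- paste(t_row, collapse = "")
  n <- nchar(tgt_seq)
  clean <- function(x) grepl("^[ACGT]+$", x)
  # the selectivity of a pair comes from one selective primer whose 3'
  # terminus sits on a discriminating base; its partner may be generic
  sel_fwd <- purrr::map_dfr(disc[disc >= primer_length], function(c) {
    p <- substr(tgt_seq, c - primer_length + 1L, c)
    if (!clean(p)) return(tibble())
    tibble(forward = p, f_start = c - primer_length, f_end = c)
  })
  sel_rev <- purrr::map_dfr(disc[disc <= n - primer_length + 1L], function(c) {
    w <- substr(tgt_seq, c, c + primer_length - 1L)
    if (!clean(w)) return(tibble())
    tibble(reverse = revcomp(w), r_start = c - 1L, r_end = c + primer_length - 1L)
  })
  generic_window <- function(from) {
    # 0-based window start; returns NA for dirty windows
    w <- substr(tgt_seq, from + 1L, from + primer_length)
    if (nchar(w) < primer_length || !clean(w)) NA_character_ else w
  }
  pairs <- bind_rows(
    purrr::map_dfr(seq_len(nrow(sel_fwd)), function(i) {
      f <- sel_fwd[i, ]
      r_ends <- seq(f$f_start + amplicon_min, min(f$f_start + amplicon_max, n),
                    by = max(primer_length, 25L))
      purrr::map_dfr(r_ends[r_ends - primer_length >= f$f_end], function(re) {
        w <- generic_window(re - primer_length)
        if (is.na(w)) return(tibble())
        dplyr::bind_cols(f, tibble(reverse = revcomp(w),
                                   r_start = re - primer_length, r_end = re,
                                   selective = "forward"))
      })
    }),
    purrr::map_dfr(seq_len(nrow(sel_rev)), function(i) {
      r <- sel_rev[i, ]
      f_starts <- seq(max(r$r_end - amplicon_max, 0L), r$r_end - amplicon_min,
                      by = max(primer_length, 25L))
      purrr::map_dfr(f_starts[f_starts + primer_length <= r$r_start],
                     function(fs) {
        w <- generic_window(fs)
        if (is.na(w)) return(tibble())
        dplyr::bind_cols(tibble(forward = w, f_start = fs,
                                f_end = fs + primer_length),
                         r, tibble(selective = "reverse"))
      })
    })
  )
  if (nrow(pairs) == 0L) {
    attr(empty, "indistinguishable") <- FALSE
    return(empty)
  }
  pairs |>
    mutate(product_length = .data$r_end - .data$f_start, target = target) |>
    filter(.data$product_length >= amplicon_min,
           .data$product_length <= amplicon_max) |>
    select("forward", "reverse", "f_start", "f_end", "r_start", "r_end",
           "selective", "product_length", "target")
}

primer_sites <- function(template, primer, max_mismatch) {
  # annealing sites on the + strand reading 5'->3' with the primer
  m <- Biostrings::matchPattern(Biostrings::DNAString(primer),
                                Biostrings::DNAString(template),
                                max.mismatch = max_mismatch)
  if (length(m) == 0L) return(tibble(start = integer(), end = integer()))
  keep <- substr(rep(template, length(m)), Biostrings::end(m),
                 Biostrings::end(m)) ==
    substr(primer, nchar(primer), nchar(primer))
  tibble(start = Biostrings::start(m)[keep] - 1L,
         end = Biostrings::end(m)[keep])
}

#' In-silico PCR with 3'-terminal selectivity
#'
#' Finds all primer-pair products on a template: the forward primer must
#' anneal on the plus strand and the reverse primer on the minus strand,
#' each with at most `max_mismatch` internal mismatches but a perfectly
#' matched 3'-terminal base (the selectivity rule of copy-specific assays).
#' When a gene model is supplied, the spliced (cDNA) product size is
#' reported alongside the genomic one.
#'
#' @param template template sequence.
#' @param forward,reverse primer sequences, 5'->3', at least 15 nt.
#' @param max_len maximal product length (default 5,000 bp).
#' @param max_mismatch internal mismatches tolerated per primer.
#' @param model optional [gene_model()] whose exons (on `template`
#'   coordinates) define the spliced product.
#' @return A tibble of products: `start`, `end` (0-based half-open),
#'   `length`, `spliced_length` (`NA` without a model). Zero rows is a
#'   valid "no product" result.
#' @export
insilico_pcr <- function(template, forward, reverse, max_len = 5000L,
                         max_mismatch = 2L, model = NULL) {
  stopifnot(nchar(forward) >= 15L, nchar(reverse) >= 15L)
  template <- toupper(template)
  f <- primer_sites(template, forward, max_mismatch)
  # reverse primer anneals to the minus strand: its site on the plus strand
  # is revcomp(reverse), whose first base carries the primer's 3' terminus
  rc <- revcomp(reverse)
  m <- Biostrings::matchPattern(Biostrings::DNAString(rc),
                                Biostrings::DNAString(template),
                                max.mismatch = max_mismatch)
  r <- if (length(m) == 0L) {
    tibble(start = integer(), end = integer())
  } else {
    keep <- substr(rep(template, length(m)), Biostrings::start(m),
                   Biostrings::start(m)) == substr(rc, 1L, 1L)
    tibble(start = Biostrings::start(m)[keep] - 1L,
           end = Biostrings::end(m)[keep])
  }
  if (nrow(f) == 0L || nrow(r) == 0L) {
    return(tibble(start = integer(), end = integer(), length = integer(),
                  spliced_length = integer()))
  }
  prods <- tidyr::expand_grid(f_start = f$start, f_end = f$end) |>
    distinct() |>
    tidyr::expand_grid(tibble(r_start = r$start, r_end = r$end)) |>
    filter(.data$r_start >= .data$f_end,
           .data$r_end - .data$f_start <= max_len) |>
    dplyr::transmute(start = .data$f_start, end = .data$r_end,
                     length = .data$r_end - .data$f_start)
  prods$spliced_length <- if (is.null(model)) {
    NA_integer_
  } else {
    ex <- model$exons
    vapply(seq_len(nrow(prods)), function(i) {
      amp <- IRanges::IRanges(prods$start[i] + 1L, prods$end[i])
      exr <- IRanges::IRanges(ex[, 1] + 1L, ex[, 2])
      as.integer(sum(IRanges::width(IRanges::intersect(amp, exr))))
    }, 1L)
  }
  prods
}

#' qPCR standard curve and efficiency QC
#'
#' Fits the least-squares slope of Ct against log10 input amount over a
#' dilution series and converts it to amplification efficiency
#' `E = 10^(-1/slope)`; a perfect doubling gives slope -3.3219 and 100%.
#' Curves pass QC when percent efficiency lies in `[90, 110]`. When curves
#' from several genotypes are supplied, the cross-genotype rule is also
#' applied: the standard deviation of percent efficiencies must stay below
#' 10 percentage points.
#'
#' @param data tibble with columns `dilution` (relative input amount, e.g.
#'   `10^-(0:4)`), `ct`, and optionally `genotype`.
#' @return An object of class `standard_curve`: per-genotype tibble with
#'   `slope`, `efficiency` (fold per cycle), `percent` ((E-1)*100),
#'   `r_squared`, `qc_pass`; attributes `sd_percent` and `cross_genotype_pass`.
#' @export
qpcr_efficiency <- function(data) {
  stopifnot(all(c("dilution", "ct") %in% names(data)))
  d <- as_tibble(data)
  if (!"genotype" %in% names(d)) d$genotype <- "reference"
  fit_curve <- function(dilution, ct) {
    if (length(unique(dilution)) < 3) abort("need at least 3 dilution points")
    fit <- lm(ct ~ lg, data = data.frame(ct = ct, lg = log10(dilution)))
    slope <- unname(coef(fit)[2])
    if (!is.finite(slope) || slope >= 0) {
      abort("invalid standard curve: slope must be negative")
    }
    E <- 10^(-1 / slope)
    tibble(slope = slope, efficiency = E, percent = (E - 1) * 100,
           r_squared = summary(fit)$r.squared,
           qc_pass = (E - 1) * 100 >= 90 & (E - 1) * 100 <= 110)
  }
  res <- d |>
    group_by(.data$genotype) |>
    summarise(fit_curve(.data$dilution, .data$ct), .groups = "drop")
  sd_pct <- if (nrow(res) > 1) sd(res$percent) else NA_real_
  structure(res, sd_percent = sd_pct,
            cross_genotype_pass = is.na(sd_pct) || sd_pct < 10,
            class = c("standard_curve", class(res)))
}

#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged on the Ct scale after the 1-Ct
#' repeatability check (spreads beyond 1 Ct are flagged, never dropped);
#' `dCt = Ct_target - Ct_reference`; `ddCt = dCt - dCt_calibrator`;
#' relative expression is `2^-ddCt`, exactly 1 for the calibrator sample.
#'
#' @param data tidy Ct table: `copy`, `cultivar`, `organ_or_stage`,
#'   `bio_rep`, `tech_rep`, `ct`, `reference_ct`.
#' @param calibrator named list selecting the calibrator sample, e.g.
#'   `list(copy = "copy_1", cultivar = "A", organ_or_stage = "stage_1")`;
#'   its mean dCt over biological replicates is the baseline.
#' @return A tibble with one row per biological replicate:
#'   `copy`, `cultivar`, `organ_or_stage`, `bio_rep`, `ct`, `reference_ct`,
#'   `delta_ct`, `delta_delta_ct`, `expression`, `tech_spread_flag`.
#' @export
relative_expression <- function(data, calibrator) {
  need <- c("copy", "cultivar", "organ_or_stage", "bio_rep", "ct", "reference_ct")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  }
  if (any(is.na(data$reference_ct))) {
    abort("reference gene must be measured in every sample")
  }
  recs <- as_tibble(data) |>
    group_by(.data$copy, .data$cultivar, .data$organ_or_stage, .data$bio_rep) |>
    summarise(
      tech_spread_flag = (max(.data$ct) - min(.data$ct)) > 1,
      ct = mean(.data$ct),
      reference_ct = mean(.data$reference_ct),
      .groups = "drop"
    ) |>
    mutate(delta_ct = .data$ct - .data$reference_ct)
  sel <- rep(TRUE, nrow(recs))
  for (f in names(calibrator)) sel <- sel & recs[[f]] == calibrator[[f]]
  if (!any(sel)) abort("calibrator sample not found in the data")
  cal_dct <- mean(recs$delta_ct[sel])
  recs |>
    mutate(delta_delta_ct = .data$delta_ct - cal_dct,
           expression = 2^(-.data$delta_delta_ct)) |>
    select("copy", "cultivar", "organ_or_stage", "bio_rep", "ct",
           "reference_ct", "delta_ct", "delta_delta_ct", "expression",
           "tech_spread_flag")
}

#' Cumulative family totals and peak-relative series
#'
#' `cumulative`: total normalised expression of the family per cultivar and
#' stage (mean over biological replicates, then summed over copies).
#' `peak_relative`: each copy x cultivar series divided by its maximum over
#' stages, so the peak is exactly 1; all-zero series are flagged undefined.
#'
#' @param records a [relative_expression()] result.
#' @return A list of class `expression_profiles` with tibbles `cumulative`
#'   and `peak_relative`.
#' @export
expression_profiles <- function(records) {
  means <- records |>
    group_by(.data$copy, .data$cultivar, .data$organ_or_stage) |>
    summarise(expression = mean(.data$expression), .groups = "drop")
  cumulative <- means |>
    group_by(.data$cultivar, .data$organ_or_stage) |>
    summarise(total_expression = sum(.data$expression), .groups = "drop")
  peak <- means |>
    group_by(.data$copy, .data$cultivar) |>
    mutate(peak = max(.data$expression),
           undefined = .data$peak <= 0,
           peak_relative = ifelse(.data$undefined, NA_real_,
                                  .data$expression / .data$peak)) |>
    ungroup() |>
    select("copy", "cultivar", "organ_or_stage", "expression",
           "peak_relative", "undefined")
  structure(list(cumulative = cumulative, peak_relative = peak),
            class = "expression_profiles")
}

snk_letters <- function(means, n, mse, df_error, alpha = 0.05) {
  # means: named group means; n: replicates per group (balanced)
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  k <- length(m)
  se <- sqrt(mse / n)
  nonsig <- matrix(FALSE, k, k)
  diag(nonsig) <- TRUE
  # stepwise: widest ranges first; a non-significant range protects all
  # ranges it contains
  for (span in seq(k - 1, 1)) {
    for (i in seq_len(k - span)) {
      j <- i + span
      if (nonsig[i, j]) next
      contained <- FALSE
      if (span < k - 1) {
        for (a in seq_len(i)) for (b in j:k) {
          if ((a < i || b > j) && nonsig[a, b]) contained <- TRUE
        }
      }
      if (contained) {
        nonsig[i, j] <- TRUE
      } else {
        q_obs <- (m[i] - m[j]) / se
        crit <- qtukey(1 - alpha, span + 1, df_error)
        if (q_obs < crit) nonsig[i, j] <- TRUE
      }
      nonsig[j, i] <- nonsig[i, j]
    }
  }
  # letters: maximal runs of mutually non-significant ordered means
  spans <- list()
  i <- 1
  for (i in seq_len(k)) {
    j <- i
    while (j < k && nonsig[i, j + 1]) j <- j + 1
    spans[[length(spans) + 1]] <- c(i, j)
  }
  spans <- Filter(Negate(is.null), spans)
  keep <- rep(TRUE, length(spans))
  for (a in seq_along(spans)) for (b in seq_along(spans)) {
    if (a != b && keep[a] &&
        spans[[b]][1] <= spans[[a]][1] && spans[[b]][2] >= spans[[a]][2] &&
        !identical(spans[[a]], spans[[b]])) keep[a] <- FALSE
  }
  spans <- spans[keep]
  spans <- unique(spans)
  lett <- rep("", k)
  for (s in seq_along(spans)) {
    rng <- spans[[s]][1]:spans[[s]][2]
    lett[rng] <- paste0(lett[rng], letters[s])
  }
  tibble(group = names(m), mean = unname(m), letters = lett)
}

#' Fixed-effects ANOVA with Student-Newman-Keuls letter grouping
#'
#' Fits a fully crossed fixed-effects ANOVA over the requested factors
#' (balanced complete designs only for two or more factors; unbalanced
#' multi-factor data raise an error pointing to per-level one-way
#' analysis), then separates the means of `snk_factor` with the stepwise
#' Student-Newman-Keuls studentized-range procedure at `alpha`, assigning
#' letters so that means that do not differ significantly share a letter.
#'
#' @param records data frame containing `response` and the factor columns.
#' @param response name of the response column (default `"expression"`).
#' @param factors character vector of factor column names (1 to 3).
#' @param snk_factor factor whose level means receive letters (default the
#'   first factor).
#' @param alpha significance level for SNK (default 0.05).
#' @return An object of class `paralogon_anova`: `table` (term, df, sumsq,
#'   meansq, statistic, p.value, including Residuals and Total), `snk`
#'   (group, mean, letters) and the call parameters.
#' @export
anova_snk <- function(records, response = "expression", factors,
                      snk_factor = factors[1], alpha = 0.05) {
  stopifnot(length(factors) >= 1, length(factors) <= 3,
            all(c(response, factors) %in% names(records)))
  d <- as_tibble(records)
  d[factors] <- lapply(d[factors], factor)
  counts <- dplyr::count(d, across(dplyr::all_of(factors)))
  balanced <- dplyr::n_distinct(counts$n) == 1 &&
    nrow(counts) == prod(vapply(d[factors], dplyr::n_distinct, 1L))
  if (length(factors) > 1 && !balanced) {
    abort(paste("unbalanced design for a multi-way decomposition;",
                "analyse each level separately with a one-way ANOVA"))
  }
  fml <- stats::as.formula(paste(response, "~", paste(factors, collapse = "*")))
  fit <- aov(fml, data = d)
  at <- as.data.frame(anova(fit))
  tab <- tibble(
    term = trimws(rownames(at)), df = at$Df, sumsq = at$`Sum Sq`,
    meansq = at$`Mean Sq`, statistic = at$`F value`, p.value = at$`Pr(>F)`
  )
  tab <- bind_rows(tab, tibble(term = "Total", df = sum(tab$df),
                               sumsq = sum(tab$sumsq), meansq = NA_real_,
                               statistic = NA_real_, p.value = NA_real_))
  res_row <- tab[tab$term == "Residuals", ]
  mse <- res_row$meansq
  df_error <- res_row$df
  grp_means <- tapply(d[[response]], d[[snk_factor]], mean)
  n_per <- nrow(d) / length(grp_means)
  snk <- if (is.finite(mse) && mse > 0 && df_error > 0) {
    snk_letters(grp_means, n_per, mse, df_error, alpha)
  } else {
    warn("zero residual variance: SNK grouping undefined")
    tibble(group = names(grp_means), mean = as.numeric(grp_means),
           letters = NA_character_)
  }
  structure(list(table = tab, snk = snk, response = response,
                 factors = factors, snk_factor = snk_factor, alpha = alpha),
            class = "paralogon_anova")
}

#' @export
print.paralogon_anova <- function(x, ...) {
  cat("<paralogon_anova> ", x$response, " ~ ",
      paste(x$factors, collapse = " * "), "\n", sep = "")
  print(x$table)
  cat("SNK grouping of", x$snk_factor, "at alpha =", x$alpha, "\n")
  print(x$snk)
  invisible(x)
}

#' Simulate a tidy qPCR Ct table from known fold changes
#'
#' Generates technical-replicate Ct values consistent with given true
#' relative expressions: the reference gene cycles around `ref_ct`, and the
#' target's dCt is `-log2(fold)` plus the calibrator baseline, with
#' Gaussian Ct noise. Useful as ground truth for the ddCt pipeline.
#'
#' @param design tibble with columns `copy`, `cultivar`, `organ_or_stage`
#'   and `fold` (true expression relative to the calibrator sample).
#' @param n_bio,n_tech biological and technical replicates per cell.
#' @param ref_ct mean reference-gene Ct.
#' @param base_delta_ct calibrator dCt baseline.
#' @param noise_sd Gaussian sd added to each Ct.
#' @param seed integer seed.
#' @return A tidy Ct tibble suitable for [relative_expression()].
#' @export
simulate_qpcr_ct <- function(design, n_bio = 3L, n_tech = 2L, ref_ct = 20,
                             base_delta_ct = 5, noise_sd = 0.15, seed = 1L) {
  stopifnot(all(c("copy", "cultivar", "organ_or_stage", "fold") %in%
                  names(design)))
  with_substream(seed, "qpcr_ct", {
    tidyr::expand_grid(design, bio_rep = seq_len(n_bio),
                       tech_rep = seq_len(n_tech)) |>
      group_by(.data$copy, .data$cultivar, .data$organ_or_stage,
               .data$bio_rep) |>
      mutate(bio_shift = stats::rnorm(1, 0, noise_sd)) |>
      ungroup() |>
      mutate(
        reference_ct = ref_ct + stats::rnorm(n(), 0, noise_sd),
        ct = .data$reference_ct + base_delta_ct - log2(.data$fold) +
          .data$bio_shift + stats::rnorm(n(), 0, noise_sd)
      ) |>
      select("copy", "cultivar", "organ_or_stage", "bio_rep", "tech_rep",
             "ct", "reference_ct")
  })
}
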
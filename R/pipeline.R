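#' Run the full analysis pipeline on a simulated family
#'
#' Orchestrates every stage against a simulated family with known truth:
#' simulation, pairwise 4DTV dating and NJ tree, dot-plot self-comparison
#' and block delimitation, LTR dating of simulated retroelements, chimera
#' detection (when the configuration includes one), promoter segmentation
#' and motif scanning, and a ddCt + ANOVA/SNK expression analysis of a
#' Ct table simulated from stage-structured fold changes. All outputs are
#' plain text (FASTA/GFF3/TSV/JSON); no stage mutates another stage's
#' files, and a run manifest (config echo + seed) accompanies the outputs.
#'
#' @param config an [evolution_config()].
#' @param out_dir output directory; created if needed. `NULL` skips writing.
#' @param seed root seed for the expression-table simulation and the
#'   chimera permutation draw.
#' @param quiet suppress stage messages.
#' @return A list of class `paralogon_run` with elements `truth`,
#'   `fourdtv`, `tree`, `blocks`, `ltr`, `chimera`, `promoters`, `qpcr`.
#' @export
run_full_analysis <- function(config, out_dir = NULL, seed = config$seed,
                              quiet = FALSE) {
  say <- function(...) if (!quiet) message("[paralogon] ", ...)
  say("simulate: generating family")
  truth <- simulate_family(config)
  if (!is.null(out_dir)) write_family(truth, file.path(out_dir, "simulate"))

  say("4dtv: pairwise dating of ", length(truth$cds), " copies")
  ids <- truth$copies$copy[truth$copies$copy != "chimera"]
  fd <- pairwise_fourdtv(truth$cds[ids])
  tree <- nj_tree(fd)

  say("blocks: self-comparison and delimitation")
  sm <- self_match(truth$locus, k = 16L)
  genes <- truth$copies |>
    dplyr::transmute(id = .data$copy, start = .data$gene_start,
                     end = .data$gene_end)
  blocks <- chain_and_delimit(sm, genes = genes)

  ltr <- if (nrow(truth$tes) > 0) {
    say("ltr: dating ", nrow(truth$tes), " elements")
    purrr::map_dfr(seq_len(nrow(truth$tes)), function(i) {
      dplyr::bind_cols(
        tibble(copy = truth$tes$copy[i], family = truth$tes$family[i]),
        ltr_divergence(truth$tes$ltr5[i], truth$tes$ltr3[i])
      )
    })
  }

  chim <- NULL
  if (!is.null(truth$chimera)) {
    say("chimera: diagnostic-site scan")
    ch <- truth$chimera
    cls <- classify_sites(truth$cds[["chimera"]],
                          truth$cds[ch$parent_a],
                          truth$cds[ch$parent_b],
                          within_ceiling = Inf,
                          candidate_id = "chimera")
    chim <- tryCatch(detect_chimera(cls, seed = seed), error = function(e) {
      say("chimera: ", conditionMessage(e))
      structure(list(candidate = "chimera", sites = cls,
                     error = conditionMessage(e)), class = "chimera_skipped")
    })
  }

  say("promoters: segmentation and motif scan")
  pids <- head(ids, 3)
  prom_pair <- segment_promoters(truth$promoters[[pids[1]]],
                                 truth$promoters[[pids[2]]],
                                 ids = pids[1:2])
  prom_trip <- if (length(pids) >= 3) {
    triplet_polarity(truth$promoters[pids])
  }
  motifs <- scan_motifs(truth$promoters[pids])

  say("qpcr: simulated expression table, ddCt and ANOVA/SNK")
  design <- tidyr::expand_grid(
    copy = head(ids, 4),
    cultivar = c("cv_dark", "cv_light"),
    organ_or_stage = paste0("stage_", 1:4)
  ) |>
    mutate(stage_i = as.integer(sub("stage_", "", .data$organ_or_stage)),
           copy_i = as.integer(factor(.data$copy)),
           fold = 2^((.data$stage_i - 1) *
                       ifelse(.data$cultivar == "cv_dark", 1, 0.25) +
                     .data$copy_i / 2)) |>
    select(-"stage_i", -"copy_i")
  ct <- simulate_qpcr_ct(design, seed = substream_seed(seed, "pipeline_ct"))
  recs <- relative_expression(
    ct, calibrator = list(copy = design$copy[1], cultivar = "cv_dark",
                          organ_or_stage = "stage_1"))
  profiles <- expression_profiles(recs)
  fit <- anova_snk(recs, factors = c("copy", "cultivar", "organ_or_stage"))

  out <- structure(list(
    truth = truth, fourdtv = fd, tree = tree, blocks = blocks, ltr = ltr,
    chimera = chim,
    promoters = list(pair = prom_pair, triplet = prom_trip, motifs = motifs),
    qpcr = list(records = recs, profiles = profiles, anova = fit)
  ), class = "paralogon_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    w(fd$pairs, "fourdtv_pairs.tsv")
    writeLines(tree$newick, file.path(out_dir, "nj_tree.nwk"))
    w(blocks$blocks, "blocks.tsv")
    if (!is.null(ltr)) w(ltr, "ltr_divergence.tsv")
    if (inherits(chim, "chimera_report")) {
      jsonlite::write_json(glance(chim), file.path(out_dir, "chimera.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    w(prom_pair$segments, "promoter_segments.tsv")
    w(motifs, "motif_hits.tsv")
    w(recs, "expression_records.tsv")
    w(tidy(fit), "anova.tsv")
    w(fit$snk, "snk.tsv")
    manifest <- list(seed = seed,
                     package_version = as.character(utils::packageVersion("paralogon")),
                     config = unclass(config)[setdiff(names(config), "duplication_events")],
                     duplication_events = as.data.frame(config$duplication_events))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}

#' @export
print.paralogon_run <- function(x, ...) {
  cat("<paralogon_run>\n  copies: ", nrow(x$truth$copies),
      "\n  blocks detected: ", nrow(x$blocks$blocks),
      "\n  chimera: ", if (is.null(x$chimera)) "none" else
        format.pval(x$chimera$p_value), "\n", sep = "")
  invisible(x)
}
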
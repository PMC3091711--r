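#' Configuration for a simulated sequence-family history
#'
#' Describes an ancestral gene plus promoter that expands through tandem and
#' segmental duplications, accumulates substitutions under a two-parameter
#' model, acquires TE insertions with initially identical LTR pairs, loses
#' copy-specific promoter segments, and optionally produces one recombinant
#' (chimeric) copy. The defaults mirror a recently expanded plant gene array:
#' a ~510-codon cytochrome-P450-sized gene, a 2-kb promoter, and segmental
#' blocks of tens of kilobases.
#'
#' @param seed integer root seed; all randomness derives from it.
#' @param ancestral_cds_length length of the ancestral CDS in codons.
#' @param promoter_length promoter length in bp (the window upstream of the
#'   translation start).
#' @param duplication_events a data frame with columns `type` ("tandem" or
#'   "segmental"), `block_length` (bp copied; tandem < 10 kb, segmental
#'   >= 10 kb) and `time` (expected substitutions/site since the ancestor,
#'   strictly increasing). Each event copies the leading `block_length` bp of
#'   the ancestral block and appends the copy after the current last block.
#' @param branch_lengths terminal branch length (substitutions/site) applied
#'   independently to every copy's block after the last duplication; a single
#'   value or one per copy.
#' @param kappa transition/transversion rate ratio; default 2.
#' @param te_insertions optional data frame with columns `family` (Gypsy,
#'   Copia, CACTA, hAT, Mutator), `copy` (1-based copy index), `ltr_length`
#'   (bp) and `post_branch` (substitutions/site accumulated by each LTR after
#'   insertion). DNA-type families (CACTA, hAT, Mutator) get short terminal
#'   inverted repeats instead of LTRs and are not datable.
#' @param promoter_deletions optional data frame with columns `copy`,
#'   `offset` and `length`: segments of the ancestral promoter (offset from
#'   its 5' end) deleted in that copy.
#' @param chimera optional list with `parent_a`, `parent_b` (copy indices)
#'   and `breakpoint_fraction` strictly inside (0, 1): an extra copy whose
#'   CDS is parent A up to the breakpoint and parent B after it.
#' @param flank_length bp of unrelated sequence added on each side of the
#'   block array.
#' @return An object of class `evolution_config` (a validated list).
#' @export
evolution_config <- function(seed = 1L,
                             ancestral_cds_length = 510L,
                             promoter_length = 2000L,
                             duplication_events = data.frame(
                               type = "segmental", block_length = 40000L, time = 0.02
                             ),
                             branch_lengths = 0.005,
                             kappa = 2,
                             te_insertions = NULL,
                             promoter_deletions = NULL,
                             chimera = NULL,
                             flank_length = 5000L) {
  ev <- as_tibble(duplication_events)
  stopifnot(all(c("type", "block_length", "time") %in% names(ev)),
            all(ev$type %in% c("tandem", "segmental")),
            all(ev$time >= 0), kappa > 0, all(branch_lengths >= 0),
            ancestral_cds_length >= 10, promoter_length >= 100)
  if (is.unsorted(ev$time, strictly = FALSE)) {
    abort("duplication event times must be non-decreasing")
  }
  bad <- (ev$type == "tandem" & ev$block_length >= 10000) |
    (ev$type == "segmental" & ev$block_length < 10000)
  if (any(bad)) abort("tandem events must copy < 10 kb and segmental events >= 10 kb")
  gene_span <- promoter_length + 3L * ancestral_cds_length
  if (any(ev$block_length < gene_span + 200L)) {
    abort("every duplicated block must contain the promoter and the gene")
  }
  if (!is.null(chimera)) {
    stopifnot(is.list(chimera),
              chimera$breakpoint_fraction > 0, chimera$breakpoint_fraction < 1)
  }
  if (!is.null(te_insertions)) {
    te_insertions <- as_tibble(te_insertions)
    stopifnot(all(te_insertions$family %in%
                    c("Gypsy", "Copia", "CACTA", "hAT", "Mutator")),
              all(te_insertions$ltr_length >= 50),
              all(te_insertions$post_branch >= 0))
  }
  if (!is.null(promoter_deletions)) {
    promoter_deletions <- as_tibble(promoter_deletions)
    stopifnot(all(promoter_deletions$offset >= 0),
              all(promoter_deletions$offset + promoter_deletions$length <=
                    promoter_length))
  }
  structure(list(
    seed = as.integer(seed),
    ancestral_cds_length = as.integer(ancestral_cds_length),
    promoter_length = as.integer(promoter_length),
    duplication_events = ev,
    branch_lengths = branch_lengths,
    kappa = kappa,
    te_insertions = te_insertions,
    promoter_deletions = promoter_deletions,
    chimera = chimera,
    flank_length = as.integer(flank_length)
  ), class = "evolution_config")
}

#' Splice a chimeric (recombinant) sequence from two aligned parents
#'
#' @param parent_a,parent_b equal-length aligned nucleotide sequences.
#' @param breakpoint 1-based position of the last base taken from parent A;
#'   must lie strictly inside the sequence.
#' @return The chimera: `parent_a[1..breakpoint] + parent_b[(breakpoint+1)..n]`.
#' @export
#' @examples
#' make_chimera("AAAAAA", "CCCCCC", 2) # "AACCCC"
make_chimera <- function(parent_a, parent_b, breakpoint) {
  if (nchar(parent_a) != nchar(parent_b)) {
    abort("parents must be equal-length aligned sequences")
  }
  n <- nchar(parent_a)
  if (breakpoint <= 0 || breakpoint >= n) abort("breakpoint out of range")
  paste0(substr(parent_a, 1L, breakpoint), substr(parent_b, breakpoint + 1L, n))
}

te_internal_length <- function(family) {
  if (family %in% c("Gypsy", "Copia")) 1200L else 600L
}

#' Simulate a gene-family expansion with full ground truth
#'
#' Applies the duplication events of an [evolution_config()] in time order:
#' the locus evolves between events, each event appends a copy of the leading
#' block, terminal branches then differentiate every copy, and structural
#' mutations (TE insertions with initially identical LTR pairs, copy-specific
#' promoter deletions, an optional chimeric copy) are applied last. Every
#' emitted sequence and every truth table is reproducible from the
#' configuration alone.
#'
#' @param config an [evolution_config()].
#' @return An object of class `family_truth`: a list with the locus sequence,
#'   tibbles `copies`, `blocks`, `distances`, `tes`, `promoter_deletions`,
#'   named character vectors `cds` and `promoters`, the `chimera` truth
#'   (or `NULL`) and the echoed `config`.
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "evolution_config"))
  cfg <- config
  seed <- cfg$seed
  ev <- cfg$duplication_events
  n_copies <- nrow(ev) + 1L
  pl <- cfg$promoter_length
  cds_len <- 3L * cfg$ancestral_cds_length

  anc_cds <- with_substream(seed, "ancestral_cds", random_cds(cfg$ancestral_cds_length))
  anc_prom <- with_substream(seed, "ancestral_promoter", random_dna(pl))
  b1_len <- max(ev$block_length)
  filler <- with_substream(seed, "ancestral_filler",
                           random_dna(b1_len - pl - cds_len))
  block1 <- paste0(anc_prom, anc_cds, filler)

  # evolve the ancestral block through time, appending copies at each event
  blocks <- list(block1)
  created <- 0 # time at which each copy split from the ancestral lineage
  t_now <- 0
  for (i in seq_len(nrow(ev))) {
    dt <- ev$time[i] - t_now
    blocks <- lapply(seq_along(blocks), function(j) {
      evolve_sequence(blocks[[j]], dt, cfg$kappa,
                      seed = substream_seed(seed, paste0("inter_event_", i, "_", j)))
    })
    t_now <- ev$time[i]
    blocks[[length(blocks) + 1L]] <- substr(blocks[[1L]], 1L, ev$block_length[i])
    created <- c(created, t_now)
  }
  t_end <- t_now

  br <- rep_len(cfg$branch_lengths, n_copies)
  blocks <- lapply(seq_len(n_copies), function(j) {
    evolve_sequence(blocks[[j]], br[j], cfg$kappa,
                    seed = substream_seed(seed, paste0("terminal_", j)))
  })

  # expected pairwise distances: shared history until the younger non-ancestral
  # copy budded off the ancestral lineage
  dist_tbl <- tidyr::expand_grid(a = seq_len(n_copies), b = seq_len(n_copies)) |>
    filter(.data$a < .data$b) |>
    mutate(
      t_split = purrr::map2_dbl(.data$a, .data$b, function(i, j) {
        if (i == 1L) created[j] else min(created[i], created[j])
      }),
      t_expected = 2 * (t_end - .data$t_split) + br[.data$a] + br[.data$b]
    )

  copy_ids <- paste0("copy_", seq_len(n_copies))
  blk_lens <- vapply(blocks, nchar, 1L)

  # structural phase: per-copy promoter deletions, then TE insertions,
  # tracked as offsets within each block
  prom_del <- cfg$promoter_deletions
  del_truth <- tibble(copy = character(), offset = integer(), length = integer())
  if (!is.null(prom_del)) {
    prom_del <- arrange(prom_del, .data$copy, dplyr::desc(.data$offset))
    for (r in seq_len(nrow(prom_del))) {
      j <- prom_del$copy[r]
      off <- prom_del$offset[r]
      len <- prom_del$length[r]
      s <- blocks[[j]]
      blocks[[j]] <- paste0(substr(s, 1L, off), substr(s, off + len + 1L, nchar(s)))
      del_truth <- bind_rows(del_truth, tibble(
        copy = copy_ids[j], offset = as.integer(off), length = as.integer(len)
      ))
    }
  }
  # gene start within each block after deletions
  n_del <- vapply(seq_len(n_copies), function(j) {
    if (is.null(prom_del)) 0L else
      as.integer(sum(prom_del$length[prom_del$copy == j]))
  }, 1L)
  gene_off <- pl - n_del # 0-based offset of ATG within the block

  te_truth <- tibble(copy = character(), family = character(),
                     start = integer(), end = integer(),
                     ltr_length = integer(), post_branch = double(),
                     expected_ltr_divergence = double(),
                     ltr5 = character(), ltr3 = character())
  if (!is.null(cfg$te_insertions)) {
    tes <- cfg$te_insertions
    for (r in seq_len(nrow(tes))) {
      j <- tes$copy[r]
      fam <- tes$family[r]
      ll <- as.integer(tes$ltr_length[r])
      pb <- tes$post_branch[r]
      ltr <- with_substream(seed, paste0("te_ltr_", r), random_dna(ll))
      internal <- with_substream(seed, paste0("te_internal_", r),
                                 random_dna(te_internal_length(fam)))
      ltr5 <- evolve_sequence(ltr, pb, cfg$kappa,
                              seed = substream_seed(seed, paste0("te_post5_", r)))
      ltr3 <- evolve_sequence(ltr, pb, cfg$kappa,
                              seed = substream_seed(seed, paste0("te_post3_", r)))
      elem <- paste0(ltr5, internal, ltr3)
      s <- blocks[[j]]
      # insert midway through the filler downstream of the gene
      ins <- gene_off[j] + cds_len +
        (nchar(s) - gene_off[j] - cds_len) %/% 2L
      blocks[[j]] <- paste0(substr(s, 1L, ins), elem,
                            substr(s, ins + 1L, nchar(s)))
      te_truth <- bind_rows(te_truth, tibble(
        copy = copy_ids[j], family = fam,
        start = as.integer(ins), end = as.integer(ins + nchar(elem)),
        ltr_length = ll, post_branch = pb,
        expected_ltr_divergence = 2 * pb, ltr5 = ltr5, ltr3 = ltr3
      ))
    }
  }
  blk_lens <- vapply(blocks, nchar, 1L)

  # optional chimeric copy: appended as a short tandem-style block
  chim_truth <- NULL
  if (!is.null(cfg$chimera)) {
    pa <- cfg$chimera$parent_a
    pb <- cfg$chimera$parent_b
    cds_a <- substr(blocks[[pa]], gene_off[pa] + 1L, gene_off[pa] + cds_len)
    cds_b <- substr(blocks[[pb]], gene_off[pb] + 1L, gene_off[pb] + cds_len)
    bp <- as.integer(round(cfg$chimera$breakpoint_fraction * cds_len))
    chim_cds <- make_chimera(cds_a, cds_b, bp)
    prom_a_start <- max(gene_off[pa] - pl, 0L)
    chim_block <- paste0(substr(blocks[[pa]], prom_a_start + 1L, gene_off[pa]),
                         chim_cds,
                         with_substream(seed, "chimera_filler", random_dna(500L)))
    blocks[[length(blocks) + 1L]] <- chim_block
    n_all <- length(blocks)
    copy_ids <- c(copy_ids, "chimera")
    gene_off <- c(gene_off, gene_off[pa] - prom_a_start)
    blk_lens <- vapply(blocks, nchar, 1L)
    chim_truth <- list(copy = "chimera",
                       parent_a = copy_ids[pa], parent_b = copy_ids[pb],
                       breakpoint_cds_bp = bp)
  }
  n_all <- length(blocks)

  left <- with_substream(seed, "left_flank", random_dna(cfg$flank_length))
  right <- with_substream(seed, "right_flank", random_dna(cfg$flank_length))
  locus <- paste0(left, paste(unlist(blocks), collapse = ""), right)

  starts <- cfg$flank_length + c(0L, cumsum(blk_lens))[seq_len(n_all)]
  classes <- c("ancestral", ev$type)
  if (!is.null(chim_truth)) classes <- c(classes, "tandem")
  blocks_tbl <- tibble(
    label = copy_ids,
    start = as.integer(starts),
    end = as.integer(starts + blk_lens),
    length = as.integer(blk_lens),
    class = ifelse(blk_lens < 10000L, "tandem", "segmental"),
    event_type = classes
  )
  copies_tbl <- tibble(
    copy = copy_ids,
    block_start = blocks_tbl$start,
    block_end = blocks_tbl$end,
    gene_start = as.integer(starts + gene_off),
    gene_end = as.integer(starts + gene_off + cds_len),
    strand = "+",
    terminal_branch = c(br, if (!is.null(chim_truth)) NA_real_)
  )
  cds_v <- setNames(vapply(seq_len(n_all), function(j) {
    substr(blocks[[j]], gene_off[j] + 1L, gene_off[j] + cds_len)
  }, ""), copy_ids)
  prom_v <- setNames(vapply(seq_len(n_all), function(j) {
    substr(blocks[[j]], 1L, gene_off[j])
  }, ""), copy_ids)

  structure(list(
    locus = locus,
    copies = copies_tbl,
    blocks = blocks_tbl,
    distances = dist_tbl |>
      mutate(copy_a = copy_ids[.data$a], copy_b = copy_ids[.data$b]) |>
      select("copy_a", "copy_b", "t_split", "t_expected"),
    cds = cds_v,
    promoters = prom_v,
    tes = te_truth,
    promoter_deletions = del_truth,
    chimera = chim_truth,
    config = cfg
  ), class = "family_truth")
}

#' @export
print.family_truth <- function(x, ...) {
  cat("<family_truth> ", nrow(x$copies), " copies, locus ",
      nchar(x$locus), " bp\n", sep = "")
  print(x$blocks)
  invisible(x)
}

#' Write a simulated family to disk
#'
#' Emits one FASTA of the locus plus per-copy CDS/promoter/block records, a
#' GFF3 of true gene and TE features, truth tables as TSV and the
#' configuration echo as JSON.
#'
#' @param truth a [simulate_family()] result.
#' @param dir output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_family <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- c(setNames(truth$locus, "locus"),
            setNames(truth$cds, paste0(names(truth$cds), "_cds")),
            setNames(truth$promoters, paste0(names(truth$promoters), "_promoter")))
  f_fa <- file.path(dir, "family.fasta")
  write_fasta(seqs, f_fa)
  feats <- bind_rows(
    truth$copies |>
      dplyr::transmute(seqid = "locus", source = "paralogon", type = "gene",
                       start = .data$gene_start, end = .data$gene_end,
                       strand = .data$strand, id = .data$copy, class = NA_character_),
    if (nrow(truth$tes) > 0) {
      truth$tes |>
        left_join(truth$copies, by = "copy") |>
        dplyr::transmute(seqid = "locus", source = "paralogon",
                         type = "transposable_element",
                         start = .data$block_start + .data$start,
                         end = .data$block_start + .data$end,
                         strand = "+",
                         id = paste0("te_", dplyr::row_number()),
                         class = .data$family)
    }
  )
  f_gff <- file.path(dir, "family.gff3")
  write_gff3(feats, f_gff)
  f_blocks <- file.path(dir, "blocks.tsv")
  utils::write.table(truth$blocks, f_blocks, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  f_dist <- file.path(dir, "distances.tsv")
  utils::write.table(truth$distances, f_dist, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  f_cfg <- file.path(dir, "config.json")
  cfg <- truth$config
  cfg$duplication_events <- as.data.frame(cfg$duplication_events)
  jsonlite::write_json(unclass(cfg), f_cfg, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(f_fa, f_gff, f_blocks, f_dist, f_cfg))
}
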
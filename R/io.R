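#' Read and write FASTA files
#'
#' Thin wrappers around Biostrings that present sequences as named,
#' upper-cased character vectors. A write/read round trip is lossless.
#'
#' @param path file path.
#' @return `read_fasta()`: a named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(setNames(toupper(seqs), names(seqs))), path)
  invisible(path)
}

#' Read a GFF3 annotation into a tidy feature table
#'
#' Coordinates are converted from the GFF3 1-based inclusive convention to
#' the package-internal 0-based half-open convention at this boundary (and
#' back on write), so `[101, 200]` in the file becomes `[100, 200)` in R.
#'
#' @param path GFF3 file path.
#' @return A tibble with columns `seqid`, `source`, `type`, `start`, `end`
#'   (0-based half-open), `score`, `strand`, `phase`, `id`, `parent`,
#'   `class` (the `class=` attribute, used for TE families).
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  rows <- which(keep)
  if (length(rows) == 0L) {
    return(tibble(seqid = character(), source = character(), type = character(),
                  start = integer(), end = integer(), score = double(),
                  strand = character(), phase = character(), id = character(),
                  parent = character(), class = character()))
  }
  parts <- strsplit(lines[rows], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 9L)) {
    abort(paste0("malformed GFF3 feature line ", rows[which(nf != 9L)[1]],
                 " in ", path, " (expected 9 tab-separated fields)"))
  }
  m <- do.call(rbind, parts)
  attr_get <- function(attrs, key) {
    val <- stringr::str_match(attrs, paste0("(?:^|;)", key, "=([^;]*)"))[, 2]
    val
  }
  start1 <- suppressWarnings(as.integer(m[, 4]))
  end1 <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(start1) | is.na(end1) | start1 < 1L | end1 < start1)
  if (length(bad) > 0L) {
    abort(paste0("malformed coordinates at GFF3 line ", rows[bad[1]], " in ", path))
  }
  tibble(
    seqid = m[, 1], source = m[, 2], type = m[, 3],
    start = start1 - 1L, end = end1,
    score = suppressWarnings(as.double(ifelse(m[, 6] == ".", NA, m[, 6]))),
    strand = m[, 7], phase = m[, 8],
    id = attr_get(m[, 9], "ID"),
    parent = attr_get(m[, 9], "Parent"),
    class = attr_get(m[, 9], "class")
  )
}

#' @rdname read_gff3
#' @param features a tibble with at least `seqid`, `type`, `start`, `end`
#'   (0-based half-open), `strand`, `id`; optional `source`, `score`,
#'   `phase`, `parent`, `class`.
#' @export
write_gff3 <- function(features, path) {
  f <- as_tibble(features)
  n <- nrow(f)
  col <- function(name, default) {
    if (name %in% names(f) && !all(is.na(f[[name]]))) f[[name]] else rep(default, n)
  }
  attrs <- paste0("ID=", f$id)
  if ("parent" %in% names(f)) {
    has <- !is.na(f$parent)
    attrs[has] <- paste0(attrs[has], ";Parent=", f$parent[has])
  }
  if ("class" %in% names(f)) {
    has <- !is.na(f$class)
    attrs[has] <- paste0(attrs[has], ";class=", f$class[has])
  }
  lines <- paste(f$seqid, col("source", "paralogon"), f$type,
                 f$start + 1L, f$end,
                 ifelse(is.na(col("score", NA_real_)), ".", col("score", NA_real_)),
                 col("strand", "+"), col("phase", "."), attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Build a gene model
#'
#' @param id gene identifier.
#' @param chromosome sequence name the gene lives on.
#' @param strand `"+"` or `"-"`.
#' @param exons a two-column matrix or data frame of 0-based half-open exon
#'   intervals, in genomic order; they must not overlap.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(id, chromosome, strand, exons) {
  ex <- as.matrix(as.data.frame(exons))
  if (nrow(ex) == 0L) abort("gene model needs at least one exon")
  ex <- ex[order(ex[, 1]), , drop = FALSE]
  if (any(ex[, 2] <= ex[, 1])) abort("empty or inverted exon interval")
  if (nrow(ex) > 1 && any(ex[-1, 1] < ex[-nrow(ex), 2])) {
    abort("exons overlap")
  }
  stopifnot(strand %in% c("+", "-"))
  structure(list(id = id, chromosome = chromosome, strand = strand,
                 exons = unname(ex)), class = "gene_model")
}

#' Extract and splice the CDS of a gene model
#'
#' Splices exons in transcription order and reverse-complements minus-strand
#' genes. A missing start codon or an internal stop does not fail: the
#' result carries a `truncated` attribute, mirroring pseudogenised copies
#' commonly found in expanded gene arrays.
#'
#' @param genome a single sequence (character) or a named vector containing
#'   the gene's chromosome.
#' @param model a [gene_model()].
#' @return The CDS as a character string with attributes `truncated`
#'   (logical) and `truncation_reason`.
#' @export
extract_cds <- function(genome, model) {
  stopifnot(inherits(model, "gene_model"))
  seq <- if (!is.null(names(genome)) && model$chromosome %in% names(genome)) {
    genome[[model$chromosome]]
  } else {
    genome[[1]]
  }
  if (any(model$exons[, 2] > nchar(seq)) || any(model$exons[, 1] < 0)) {
    abort("exon out of sequence bounds")
  }
  pieces <- apply(model$exons, 1, function(e) substr(seq, e[1] + 1L, e[2]))
  cds <- paste(pieces, collapse = "")
  if (model$strand == "-") cds <- revcomp(cds)
  reasons <- character()
  if (substr(cds, 1, 3) != "ATG") reasons <- c(reasons, "no start codon")
  if (nchar(cds) %% 3 != 0) reasons <- c(reasons, "length not divisible by 3")
  cods <- codons_of(cds)
  if (length(cods) > 1 && any(cods[-length(cods)] %in% STOP_CODONS)) {
    reasons <- c(reasons, "internal stop codon")
  }
  if (length(reasons) > 0) {
    warn(paste0("gene ", model$id, " flagged truncated: ",
                paste(reasons, collapse = "; ")))
  }
  structure(cds, truncated = length(reasons) > 0,
            truncation_reason = if (length(reasons)) paste(reasons, collapse = "; ")
            else NA_character_)
}

#' Convert gene-type GFF3 rows to gene models
#'
#' Groups exon rows under their parent gene (or treats a lone gene row as
#' single-exon) and returns one [gene_model()] per gene.
#'
#' @param features a [read_gff3()] tibble.
#' @return A named list of `gene_model` objects.
#' @export
gff3_gene_models <- function(features) {
  genes <- filter(features, .data$type == "gene")
  exons <- filter(features, .data$type == "exon")
  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    ex <- filter(exons, .data$parent == g$id)
    if (nrow(ex) == 0L) ex <- g
    gene_model(g$id, g$seqid, g$strand, cbind(ex$start, ex$end))
  })
  setNames(out, genes$id)
}
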
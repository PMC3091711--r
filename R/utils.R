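#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join rename n row_number distinct across
#' @importFrom stats lm coef setNames runif aov anova ptukey qtukey sd median
#' @importFrom utils head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

# transition partner of each base (A<->G, C<->T), indexed 1:4 over A,C,G,T
TS_PARTNER <- c(3L, 4L, 1L, 2L)
# the two transversion partners of each base
TV_PARTNERS <- matrix(c(2L, 4L, 1L, 3L, 2L, 4L, 1L, 3L), nrow = 4L, byrow = TRUE)

STOP_CODONS <- c("TAA", "TAG", "TGA")

# first-two-position prefixes of the eight four-fold degenerate codon families
FOURFOLD_PREFIXES <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")

seq_to_int <- function(x) {
  v <- match(strsplit(toupper(x), "", fixed = TRUE)[[1]], DNA_BASES)
  if (anyNA(v)) abort("sequence contains characters outside {A,C,G,T}")
  v
}

int_to_seq <- function(v) paste(DNA_BASES[v], collapse = "")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

translate_cds <- function(cds) {
  n <- nchar(cds) - nchar(cds) %% 3
  as.character(Biostrings::translate(Biostrings::DNAString(substr(cds, 1L, n)),
                                     if.fuzzy.codon = "X"))
}

codons_of <- function(x) {
  n <- nchar(x) %/% 3L
  substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Derive a reproducible sub-seed for a named stochastic step
#'
#' Every stochastic operation in the package draws from its own named
#' substream of the root seed, so adding a new simulation feature cannot
#' silently reorder the draws of existing ones.
#'
#' @param seed integer root seed.
#' @param name character label of the substream.
#' @return An integer in `[0, 2^31)` usable with [set.seed()].
#' @export
substream_seed <- function(seed, name) {
  h <- as.double(seed %% 2147483647L)
  for (c in utf8ToInt(name)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(substream_seed(seed, name))
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

#' Generate a random coding sequence
#'
#' Starts with ATG and contains no internal stop codon; no terminal stop codon
#' is appended.
#'
#' @param n_codons total codon count including the start codon.
#' @return A single character string of length `3 * n_codons`.
#' @export
random_cds <- function(n_codons) {
  stopifnot(n_codons >= 2)
  all_codons <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0), DNA_BASES, paste0))
  ok <- setdiff(all_codons, STOP_CODONS)
  paste0("ATG", paste(sample(ok, n_codons - 1L, replace = TRUE), collapse = ""))
}
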
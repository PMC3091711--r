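#' Closed-form transition and transversion probabilities under K80
#'
#' For a two-parameter (Kimura) substitution model with
#' transition/transversion rate ratio `kappa` and total branch length `t`
#' (expected substitutions per site), returns the probabilities that a site
#' shows a transition difference (`P`) or a transversion difference (`Q`)
#' between the two ends of the branch.
#'
#' @param t expected substitutions per site (non-negative).
#' @param kappa transition/transversion rate ratio (> 0).
#' @return A tibble with columns `t`, `P`, `Q` and `identity`
#'   (probability the site is identical, `1 - P - Q`).
#' @export
#' @examples
#' k80_expected(c(0, 0.1, 0.5), kappa = 2)
k80_expected <- function(t, kappa = 2) {
  stopifnot(all(t >= 0), kappa > 0)
  e1 <- exp(-4 * t / (kappa + 2))
  e2 <- exp(-2 * t * (kappa + 1) / (kappa + 2))
  P <- 0.25 + 0.25 * e1 - 0.5 * e2
  Q <- 0.5 - 0.5 * e1
  tibble(t = t, P = P, Q = Q, identity = 1 - P - Q)
}

#' Evolve a nucleotide sequence along a branch
#'
#' Mutates each site independently under a two-parameter (transition /
#' transversion) continuous-time substitution model. In coding mode, codons
#' that would become internal stop codons are redrawn from the ancestral
#' codon, and the initial ATG is preserved, so the result remains an open
#' reading frame.
#'
#' @param seq a single nucleotide sequence over `{A,C,G,T}`.
#' @param t branch length in expected substitutions per site.
#' @param kappa transition/transversion rate ratio; default 2.
#' @param coding if `TRUE`, reject internal stop codons and keep the start
#'   codon fixed (the sequence length must be divisible by 3).
#' @param seed optional integer; if supplied the call is reproducible and
#'   leaves the global RNG state untouched.
#' @return The evolved sequence (single character string).
#' @export
#' @examples
#' evolve_sequence("ATGGGATTTCCC", t = 0.1, kappa = 2, coding = TRUE, seed = 1)
evolve_sequence <- function(seq, t, kappa = 2, coding = FALSE, seed = NULL) {
  if (t < 0) abort("branch length t must be non-negative")
  if (t == 0) return(toupper(seq))
  run <- function() {
    v <- seq_to_int(seq)
    n <- length(v)
    if (coding && n %% 3L != 0L) abort("coding sequence length must be divisible by 3")
    pq <- k80_expected(t, kappa)
    v2 <- mutate_sites(v, pq$P, pq$Q)
    if (coding) {
      v2[1:3] <- seq_to_int("ATG")
      # redraw codons that became stops, starting again from the ancestor
      repeat {
        s <- int_to_seq(v2)
        cods <- codons_of(s)
        bad <- which(cods %in% STOP_CODONS)
        if (length(bad) == 0L) break
        for (b in bad) {
          idx <- (3L * b - 2L):(3L * b)
          v2[idx] <- mutate_sites(v[idx], pq$P, pq$Q)
        }
      }
    }
    int_to_seq(v2)
  }
  if (is.null(seed)) run() else with_substream(seed, "evolve", run())
}

mutate_sites <- function(v, P, Q) {
  n <- length(v)
  u <- runif(n)
  out <- v
  ts <- u < P
  tv1 <- !ts & u < P + Q / 2
  tv2 <- !ts & !tv1 & u < P + Q
  out[ts] <- TS_PARTNER[v[ts]]
  out[tv1] <- TV_PARTNERS[v[tv1], 1L]
  out[tv2] <- TV_PARTNERS[v[tv2], 2L]
  out
}
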
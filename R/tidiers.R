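#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an ANOVA-with-SNK fit
#'
#' @param x a [anova_snk()] result.
#' @param ... unused.
#' @return One row per model term with `df`, `sumsq`, `meansq`,
#'   `statistic`, `p.value`.
#' @method tidy paralogon_anova
#' @export
tidy.paralogon_anova <- function(x, ...) x$table

#' @rdname tidy.paralogon_anova
#' @method glance paralogon_anova
#' @export
glance.paralogon_anova <- function(x, ...) {
  res <- x$table[x$table$term == "Residuals", ]
  tot <- x$table[x$table$term == "Total", ]
  tibble(
    df_residual = res$df, mse = res$meansq,
    ss_total = tot$sumsq,
    r_squared = 1 - res$sumsq / tot$sumsq,
    n_terms = nrow(x$table) - 2L
  )
}

#' Tidy a standard-curve fit
#'
#' @param x a [qpcr_efficiency()] result.
#' @param ... unused.
#' @method tidy standard_curve
#' @export
tidy.standard_curve <- function(x, ...) as_tibble(unclass(x))

#' @rdname tidy.standard_curve
#' @method glance standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble(n_genotypes = nrow(x),
         sd_percent = attr(x, "sd_percent"),
         cross_genotype_pass = attr(x, "cross_genotype_pass"),
         all_qc_pass = all(x$qc_pass))
}

#' Tidy a chimera report
#'
#' @param x a [detect_chimera()] result.
#' @param ... unused.
#' @return The per-class site counts.
#' @method tidy chimera_report
#' @export
tidy.chimera_report <- function(x, ...) x$counts

#' @rdname tidy.chimera_report
#' @method glance chimera_report
#' @export
glance.chimera_report <- function(x, ...) {
  tibble(candidate = x$candidate, statistic = x$statistic,
         breakpoint = x$breakpoint, n_informative = x$n_informative,
         dist_to_a = x$dist_to_a, dist_to_b = x$dist_to_b,
         p_value = x$p_value, method = x$method)
}

#' Tidy a pairwise 4DTV result
#'
#' @param x a [pairwise_fourdtv()] result.
#' @param ... unused.
#' @method tidy fourdtv_matrix
#' @export
tidy.fourdtv_matrix <- function(x, ...) x$pairs
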
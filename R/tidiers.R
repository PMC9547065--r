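#' Tidy an enrichment result
#'
#' @param x An [enrichment_t()] result.
#' @param ... Unused.
#' @return One-row tibble with the observed value, random-set mean/sd, t,
#'   df, p and direction.
#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble(statistic = x$statistic, observed = x$observed,
         random_mean = x$random_mean, random_sd = x$random_sd,
         t = x$t, df = x$df, p = x$p, p_empirical = x$p_empirical,
         direction = x$direction)
}

#' @rdname tidy.enrichment_result
#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) tidy(x)

#' Tidy a super-enhancer call
#'
#' @param x An [rose_cutoff()] result.
#' @param ... Unused.
#' @return The ranked region table (rank, scaled rank `x`, scaled signal
#'   `y`, net signal, SE flag) without the constituent list-column.
#' @method tidy se_call
#' @export
tidy.se_call <- function(x, ...) {
  out <- as_tibble(x)[, c("region_id", "chrom", "start", "end",
                          "n_constituents", "net_signal", "rank", "x", "y",
                          "is_SE")]
  out
}

#' @rdname tidy.se_call
#' @return `glance()`: one row with region/SE counts and the cutoff.
#' @method glance se_call
#' @export
glance.se_call <- function(x, ...) {
  tibble(n_regions = nrow(x), n_se = sum(x$is_SE),
         cutoff_index = attr(x, "cutoff_index"),
         cutoff_signal = attr(x, "cutoff_signal"))
}

#' Tidy a compartment call
#'
#' @param x A [compartment_call()] result.
#' @param ... Unused.
#' @return The per-bin table (`bin`, coordinates, eigenvector value,
#'   label).
#' @method tidy compartment_call
#' @export
tidy.compartment_call <- function(x, ...) x$bins

#' @rdname tidy.compartment_call
#' @method glance compartment_call
#' @export
glance.compartment_call <- function(x, ...) {
  tibble(chrom = x$chrom, n_bins = nrow(x$bins),
         n_A = sum(x$bins$label == "A"), n_B = sum(x$bins$label == "B"),
         n_segments = nrow(x$segments))
}

#' Tidy a conservation summary
#'
#' @param x A [gene_pair_conservation()] result.
#' @param ... Unused.
#' @return One-row tibble with pair counts and conserved fractions.
#' @method tidy conservation_summary
#' @export
tidy.conservation_summary <- function(x, ...) {
  tibble(n_pairs_tad = x$n_pairs_tad_b,
         frac_tad_conserved = x$frac_tad_conserved,
         n_pairs_loop = x$n_pairs_loop_b,
         frac_loop_conserved = x$frac_loop_conserved)
}

#' @rdname tidy.conservation_summary
#' @method glance conservation_summary
#' @export
glance.conservation_summary <- function(x, ...) tidy(x)

#' @rdname se_summary
#' @param x An `se_summary`.
#' @param ... Unused.
#' @method glance se_summary
#' @export
glance.se_summary <- function(x, ...) {
  tibble(n_se = length(x$sizes), r2_size = x$r2_size, r2_genes = x$r2_genes,
         median_size = stats::median(x$sizes), flag = x$flag)
}
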
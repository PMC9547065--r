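#' Chromatin-state vocabulary
#'
#' The default 10-state vocabulary used by the state-segmentation inputs:
#' one promoter state, five active/poised enhancer states, one
#' heterochromatin state and three low-signal states.
#'
#' @return Character vector of state labels.
#' @export
state_vocabulary <- function() {
  c("promoter", paste0("enhancer_", 1:5), "heterochromatin", paste0("low_", 1:3))
}

#' Default active-state set
#'
#' The promoter state plus the five enhancer states: the states merged into
#' cis-regulatory elements (CREs).
#'
#' @return Character vector of state labels.
#' @export
active_states <- function() c("promoter", paste0("enhancer_", 1:5))

#' Merge active chromatin states into CREs
#'
#' Overlapping or directly adjacent (gap 0) segments carrying an active
#' state are merged into non-overlapping cis-regulatory elements. A CRE is
#' flagged `is_promoter_state` when any constituent segment carries the
#' promoter state.
#'
#' @param segments Interval table with a `state` column.
#' @param active_label_set States considered active; must be a subset of
#'   [state_vocabulary()].
#' @param vocabulary The declared state vocabulary.
#' @return CRE tibble: `chrom`, `start`, `end`, `is_promoter_state`,
#'   `source_labels`.
#' @export
merge_active_states <- function(segments, active_label_set = active_states(),
                                vocabulary = state_vocabulary()) {
  unknown <- setdiff(active_label_set, vocabulary)
  if (length(unknown)) {
    abort(sprintf("unknown state label '%s' in active set", unknown[1]))
  }
  check_intervals(segments, what = "state segments")
  act <- segments[segments$state %in% active_label_set, , drop = FALSE]
  if (nrow(act) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  is_promoter_state = logical(), source_labels = character()))
  }
  merged <- merge_intervals(act[, c("chrom", "start", "end")], gap = 0)
  hits <- join_overlaps(merged, act)
  lab <- vapply(seq_len(nrow(merged)), function(i) {
    states <- act$state[hits$b_idx[hits$a_idx == i]]
    paste(sort(unique(states)), collapse = ",")
  }, character(1))
  is_prom <- vapply(seq_len(nrow(merged)), function(i) {
    any(act$state[hits$b_idx[hits$a_idx == i]] == "promoter")
  }, logical(1))
  merged$is_promoter_state <- is_prom
  merged$source_labels <- lab
  merged
}

#' Promoter regions around gene TSS
#'
#' The half-open window `[tss - halfwidth, tss + halfwidth)` per gene,
#' clipped to chromosome bounds.
#'
#' @param genes Gene tibble.
#' @param halfwidth Promoter half-width in bp (default 2,500).
#' @param build Optional genome build for clipping.
#' @return Tibble: `gene_id`, `chrom`, `start`, `end`, `tss`.
#' @export
promoter_regions <- function(genes, halfwidth = 2500, build = NULL) {
  if (halfwidth <= 0) abort("halfwidth must be positive")
  s <- pmax(genes$tss - halfwidth, 0)
  e <- genes$tss + halfwidth
  if (!is.null(build)) {
    lens <- chrom_lengths(build)
    e <- pmin(e, lens[genes$chrom])
  }
  tibble(gene_id = genes$gene_id, chrom = genes$chrom,
         start = s, end = as.numeric(e), tss = genes$tss)
}

#' Remove TSS-proximal CREs
#'
#' Drops CREs fully contained within any promoter window; CREs only
#' partially overlapping a promoter window are retained. This reproduces
#' the removal of TSS loci before super-enhancer stitching.
#'
#' @param cres CRE tibble.
#' @param promoters Promoter windows from [promoter_regions()].
#' @return The surviving CREs.
#' @export
exclude_tss_cres <- function(cres, promoters) {
  if (nrow(cres) == 0 || nrow(promoters) == 0) return(cres)
  hits <- join_overlaps(cres, promoters)
  contained <- hits$a_idx[
    cres$start[hits$a_idx] >= promoters$start[hits$b_idx] &
      cres$end[hits$a_idx] <= promoters$end[hits$b_idx]]
  if (!length(contained)) return(cres)
  cres[-unique(contained), , drop = FALSE]
}

#' Stitch CREs into candidate super-enhancer regions
#'
#' ROSE-style stitching: CREs whose gap to the next CRE on the chromosome
#' is smaller than `stitch_distance` are chained into one region spanning
#' the first start to the last end; singletons are allowed. The default
#' 12,500 bp is the ROSE default.
#'
#' @param cres CRE tibble (any extra columns are carried into the
#'   constituent list).
#' @param stitch_distance Maximum gap (exclusive) chained over, in bp.
#' @return Tibble of stitched regions: `region_id`, `chrom`, `start`,
#'   `end`, `n_constituents`, and a `constituents` list-column of CRE
#'   sub-tibbles.
#' @export
stitch <- function(cres, stitch_distance = 12500) {
  if (stitch_distance < 0) abort("stitch_distance must be >= 0")
  check_intervals(cres, what = "CREs")
  if (nrow(cres) == 0) {
    return(tibble(region_id = character(), chrom = character(),
                  start = numeric(), end = numeric(),
                  n_constituents = integer(), constituents = list()))
  }
  cres <- cres[order(cres$chrom, cres$start, cres$end), , drop = FALSE]
  out <- vector("list", 0L)
  for (ch in unique(cres$chrom)) {
    xi <- cres[cres$chrom == ch, , drop = FALSE]
    gap_new <- if (nrow(xi) > 1) {
      xi$start[-1] - cummax(xi$end[-nrow(xi)]) >= stitch_distance
    } else logical(0)
    grp <- cumsum(c(1L, as.integer(gap_new)))
    for (g in unique(grp)) {
      sub <- xi[grp == g, , drop = FALSE]
      out[[length(out) + 1L]] <- tibble(
        chrom = ch, start = min(sub$start), end = max(sub$end),
        n_constituents = nrow(sub), constituents = list(sub))
    }
  }
  res <- bind_rows(out)
  res <- res[order(res$chrom, res$start), ]
  res$region_id <- sprintf("region_%04d", seq_len(nrow(res)))
  res[, c("region_id", "chrom", "start", "end", "n_constituents", "constituents")]
}

#' Case/control signal over stitched regions
#'
#' Sums per-bp coverage over the constituent CREs only (gaps between
#' constituents are excluded, the ROSE convention) for the case (H3K27Ac)
#' and control (input) tracks; the net signal is `max(case - control, 0)`.
#'
#' @param stitched Output of [stitch()].
#' @param case_track,control_track [signal_track()] objects on the same
#'   build.
#' @return `stitched` with `case_signal`, `control_signal`, `net_signal`
#'   columns added.
#' @export
region_signal <- function(stitched, case_track, control_track) {
  case_sig <- vapply(stitched$constituents, function(cc) {
    sum(track_sum(case_track, cc))
  }, numeric(1))
  ctrl_sig <- vapply(stitched$constituents, function(cc) {
    sum(track_sum(control_track, cc))
  }, numeric(1))
  stitched$case_signal <- case_sig
  stitched$control_signal <- ctrl_sig
  stitched$net_signal <- pmax(case_sig - ctrl_sig, 0)
  stitched
}

#' ROSE rank-curve elbow cutoff
#'
#' Regions are ranked by ascending net signal; both axes are min-max scaled
#' to \[0, 1\] (`x` = scaled rank, `y` = scaled signal) and the cutoff is
#' placed at `argmin(y - x)` - the discrete point where the tangent of a
#' convex rank curve has slope 1. Ties take the largest index (conservative:
#' fewer super-enhancers). Regions with net signal strictly above the
#' cutoff signal are flagged as super-enhancers.
#'
#' @param stitched Output of [region_signal()] (needs `net_signal`).
#' @return An object of class `se_call`: the ranked region table with
#'   `rank`, `x`, `y`, `is_SE` columns and `cutoff_index` /
#'   `cutoff_signal` attributes. See [tidy.se_call()], [se_regions()].
#' @export
rose_cutoff <- function(stitched) {
  if (!"net_signal" %in% names(stitched)) {
    abort("run region_signal() before rose_cutoff()")
  }
  n <- nrow(stitched)
  x <- stitched[order(stitched$net_signal, seq_len(n)), , drop = FALSE]
  s <- x$net_signal
  x$rank <- seq_len(n)
  if (n < 3 || length(unique(s)) < 2) {
    warn("fewer than 3 distinct signal values: no elbow, zero SEs flagged")
    x$x <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0
    x$y <- 0
    x$is_SE <- FALSE
    k <- n
  } else {
    x$x <- (seq_len(n) - 1) / (n - 1)
    x$y <- (s - min(s)) / (max(s) - min(s))
    d <- x$y - x$x
    k <- max(which(d == min(d)))
    x$is_SE <- s > s[k]
  }
  structure(x, cutoff_index = k,
            cutoff_signal = if (n) x$net_signal[k] else NA_real_,
            class = c("se_call", class(tibble())))
}

#' Super-enhancer regions from a call
#'
#' @param call An `se_call` from [rose_cutoff()].
#' @return The subset of regions flagged as super-enhancers.
#' @export
se_regions <- function(call) {
  out <- call[call$is_SE, , drop = FALSE]
  class(out) <- class(tibble())
  out
}

#' Per-chromosome super-enhancer summary
#'
#' Counts SEs per chromosome and reports the squared Pearson correlation
#' (r^2) of the count with chromosome size and with the number of expressed
#' genes per chromosome, plus the SE size distribution.
#'
#' @param call An `se_call`.
#' @param build Genome build.
#' @param genes Gene tibble with an `expression` column.
#' @param expressed_min Expression threshold (exclusive) defining an
#'   expressed gene.
#' @return An object of class `se_summary`: list with `per_chrom`,
#'   `r2_size`, `r2_genes`, `sizes`, `flag` fields.
#' @export
se_summary <- function(call, build, genes, expressed_min = 0) {
  ses <- se_regions(call)
  per_chrom <- tibble(chrom = build$chrom, size = build$length) |>
    left_join(ses |> group_by(.data$chrom) |> summarise(n_se = n()),
              by = "chrom") |>
    left_join(genes |> filter(.data$expression > expressed_min) |>
                group_by(.data$chrom) |> summarise(n_expressed = n()),
              by = "chrom") |>
    mutate(n_se = ifelse(is.na(.data$n_se), 0L, .data$n_se),
           n_expressed = ifelse(is.na(.data$n_expressed), 0L, .data$n_expressed))
  r2_of <- function(a, b) {
    if (length(a) < 3 || sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)^2
  }
  r2_size <- r2_of(per_chrom$n_se, per_chrom$size)
  r2_genes <- r2_of(per_chrom$n_se, per_chrom$n_expressed)
  structure(list(per_chrom = per_chrom,
                 r2_size = r2_size, r2_genes = r2_genes,
                 sizes = ses$end - ses$start,
                 flag = is.na(r2_size) || is.na(r2_genes)),
            class = "se_summary")
}

#' @export
print.se_summary <- function(x, ...) {
  cat(sprintf("<se_summary: %d SEs on %d chromosome(s); r2 size %.3f, r2 genes %.3f>\n",
              length(x$sizes), nrow(x$per_chrom),
              x$r2_size, x$r2_genes))
  invisible(x)
}
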
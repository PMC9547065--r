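#' Place regions within TADs
#'
#' Each region is assigned its host TAD (the TAD fully containing it, if
#' any), the minimum distance from the region to the host-TAD boundaries,
#' and a position class: `edge` (hosted, boundary distance below
#' `edge_threshold`), `non_edge` (hosted, farther), `spanning_boundary`
#' (overlaps a TAD without being contained, i.e. crosses a boundary), or
#' `outside_tad` (no TAD overlap). The 5 kb default threshold matches the
#' edge-SE definition (SEs < 5 kb from a TAD boundary).
#'
#' @param regions Interval table (e.g. SE regions; a `region_id` column is
#'   carried through, otherwise row indices are used).
#' @param tads Non-overlapping TAD intervals (error if overlapping).
#' @param edge_threshold Edge distance threshold in bp (default 5,000).
#' @return Tibble: `region_id`, `chrom`, `start`, `end`, `host_tad`
#'   (row index into `tads`, NA if none), `boundary_distance`,
#'   `position_class`.
#' @export
place_regions_in_tads <- function(regions, tads, edge_threshold = 5000) {
  check_tads_disjoint(tads)
  ids <- col_or(regions, "region_id") %||% sprintf("region_%04d", seq_len(nrow(regions)))
  hits <- join_overlaps(regions, tads)
  host <- rep(NA_integer_, nrow(regions))
  dist <- rep(NA_real_, nrow(regions))
  cls <- rep("outside_tad", nrow(regions))
  if (nrow(hits)) {
    contained <- regions$start[hits$a_idx] >= tads$start[hits$b_idx] &
      regions$end[hits$a_idx] <= tads$end[hits$b_idx]
    cls[unique(hits$a_idx)] <- "spanning_boundary"
    hc <- hits[contained, , drop = FALSE]
    host[hc$a_idx] <- hc$b_idx
    dist[hc$a_idx] <- pmin(regions$start[hc$a_idx] - tads$start[hc$b_idx],
                           tads$end[hc$b_idx] - regions$end[hc$a_idx])
    cls[hc$a_idx] <- ifelse(dist[hc$a_idx] < edge_threshold, "edge", "non_edge")
  }
  tibble(region_id = ids, chrom = regions$chrom, start = regions$start,
         end = regions$end, host_tad = host, boundary_distance = dist,
         position_class = cls)
}

check_tads_disjoint <- function(tads) {
  check_intervals(tads, what = "TADs")
  if (nrow(tads) < 2) return(invisible(tads))
  for (ch in unique(tads$chrom)) {
    xi <- tads[tads$chrom == ch, ]
    xi <- xi[order(xi$start), ]
    if (any(xi$start[-1] < xi$end[-nrow(xi)])) {
      abort(sprintf("TADs overlap on %s", ch))
    }
  }
  invisible(tads)
}

#' Classify TADs by compartment and hosted-SE position
#'
#' A TAD gets a compartment label only when every bp is covered by segments
#' of a single label; TADs straddling an A/B boundary are `unassigned`.
#' A-compartment TADs are subdivided by hosted-SE presence and, when SEs
#' are present, by the most-edge class among them (`edge` dominates
#' `non_edge`). Regions spanning a TAD boundary are counted as edge SEs of
#' the TADs they overlap when `spanning_as_edge = TRUE` (default: their
#' boundary distance is below any threshold by construction).
#'
#' @param tads Non-overlapping TAD intervals.
#' @param compartments Compartment segment table (`chrom`, `start`, `end`,
#'   `label`).
#' @param placements Output of [place_regions_in_tads()] for the SE set.
#' @param spanning_as_edge Count boundary-spanning SEs as edge SEs of the
#'   TADs they overlap.
#' @return Tibble: TAD coordinates plus `compartment` (`A`, `B` or NA) and
#'   `group` (`B_compartment`, `A_no_SE`, `A_nonedge_SE`, `A_edge_SE`,
#'   `unassigned`).
#' @export
classify_tads <- function(tads, compartments, placements,
                          spanning_as_edge = TRUE) {
  check_tads_disjoint(tads)
  seg <- compartments
  hits <- join_overlaps(tads, seg)
  comp <- rep(NA_character_, nrow(tads))
  for (i in unique(hits$a_idx)) {
    si <- hits$b_idx[hits$a_idx == i]
    labs <- unique(seg$label[si])
    if (length(labs) != 1) next
    cov <- merge_intervals(seg[si, c("chrom", "start", "end")])
    covered <- sum(pmin(cov$end, tads$end[i]) - pmax(cov$start, tads$start[i]))
    if (covered >= tads$end[i] - tads$start[i]) comp[i] <- labs
  }
  hosted_edge <- rep(FALSE, nrow(tads))
  hosted_any <- rep(FALSE, nrow(tads))
  hosted <- placements[!is.na(placements$host_tad), , drop = FALSE]
  if (nrow(hosted)) {
    hosted_any[unique(hosted$host_tad)] <- TRUE
    he <- hosted$host_tad[hosted$position_class == "edge"]
    hosted_edge[unique(he)] <- TRUE
  }
  if (spanning_as_edge) {
    sp <- placements[placements$position_class == "spanning_boundary", ,
                     drop = FALSE]
    if (nrow(sp)) {
      sp_hits <- join_overlaps(sp[, c("chrom", "start", "end")], tads)
      hosted_any[unique(sp_hits$b_idx)] <- TRUE
      hosted_edge[unique(sp_hits$b_idx)] <- TRUE
    }
  }
  group <- ifelse(is.na(comp), "unassigned",
           ifelse(comp == "B", "B_compartment",
           ifelse(!hosted_any, "A_no_SE",
           ifelse(hosted_edge, "A_edge_SE", "A_nonedge_SE"))))
  tibble(chrom = tads$chrom, start = tads$start, end = tads$end,
         compartment = comp, group = group)
}

#' Per-TAD loop contact statistics
#'
#' A loop is "in contact" with a TAD when at least one foot overlaps it and
#' "crosses the boundary" when exactly one foot overlaps it. A loop shared
#' by adjacent TADs is counted once per TAD it touches.
#'
#' @param tads Non-overlapping TAD intervals.
#' @param loops Loop table.
#' @return Tibble: TAD coordinates plus `n_loops`, `mean_loop_size`,
#'   `pct_crossing`.
#' @export
tad_loop_stats <- function(tads, loops) {
  check_tads_disjoint(tads)
  sizes <- loop_sizes(loops)
  ha <- join_overlaps(loop_feet(loops, "A"), tads)
  hb <- join_overlaps(loop_feet(loops, "B"), tads)
  key_a <- paste(ha$a_idx, ha$b_idx)
  key_b <- paste(hb$a_idx, hb$b_idx)
  touch <- unique(rbind(ha, hb))
  both <- key_a %in% key_b
  n_loops <- integer(nrow(tads))
  mean_size <- rep(NA_real_, nrow(tads))
  pct_cross <- rep(NA_real_, nrow(tads))
  if (nrow(touch)) {
    for (ti in unique(touch$b_idx)) {
      li <- unique(touch$a_idx[touch$b_idx == ti])
      n_loops[ti] <- length(li)
      mean_size[ti] <- mean(sizes[li])
      both_in <- paste(li, ti) %in% key_a & paste(li, ti) %in% key_b
      pct_cross[ti] <- 100 * mean(!both_in)
    }
  }
  tibble(chrom = tads$chrom, start = tads$start, end = tads$end,
         n_loops = n_loops, mean_loop_size = mean_size,
         pct_crossing = pct_cross)
}

#' Loop contacts per region
#'
#' Per region: the number of loops "touching" it (at least one foot
#' overlapping) and the number fully internal to it (both feet contained
#' within the region). Also returns the sizes of all loops touching any
#' region (the SE loop-size distribution).
#'
#' @param regions Interval table (SEs or one random-region set).
#' @param loops Loop table.
#' @return An object of class `region_loop_summary`: list with
#'   `per_region` tibble, `touching_sizes` numeric vector and
#'   `n_loops_touching` scalar.
#' @export
region_loop_summary <- function(regions, loops) {
  ids <- col_or(regions, "region_id") %||% sprintf("region_%04d", seq_len(nrow(regions)))
  ha <- join_overlaps(loop_feet(loops, "A"), regions)
  hb <- join_overlaps(loop_feet(loops, "B"), regions)
  feetA <- loop_feet(loops, "A"); feetB <- loop_feet(loops, "B")
  cont <- function(h, feet) {
    h[feet$start[h$a_idx] >= regions$start[h$b_idx] &
        feet$end[h$a_idx] <= regions$end[h$b_idx], , drop = FALSE]
  }
  ca <- cont(ha, feetA); cb <- cont(hb, feetB)
  touch_pairs <- unique(rbind(ha, hb))
  internal_pairs <- ca[paste(ca$a_idx, ca$b_idx) %in% paste(cb$a_idx, cb$b_idx), ,
                       drop = FALSE]
  n_touch <- tabulate(touch_pairs$b_idx, nbins = nrow(regions))
  n_internal <- tabulate(unique(internal_pairs)$b_idx, nbins = nrow(regions))
  touching_loops <- unique(touch_pairs$a_idx)
  structure(list(
    per_region = tibble(region_id = ids, n_touching = as.integer(n_touch),
                        n_internal = as.integer(n_internal)),
    touching_sizes = loop_sizes(loops)[touching_loops],
    touching_loop_idx = touching_loops,
    n_loops_touching = length(touching_loops)),
    class = "region_loop_summary")
}

#' @export
print.region_loop_summary <- function(x, ...) {
  cat(sprintf("<region_loop_summary: %d loops touching %d region(s)>\n",
              x$n_loops_touching, nrow(x$per_region)))
  invisible(x)
}

#' Unique features contacted by regions through loops
#'
#' For each region and each loop with exactly one foot overlapping that
#' region, the distal foot is intersected with CREs, gene TSS points, and
#' the region set itself; counts are of unique features contacted across
#' the whole set (a feature reached by several loops or regions counts
#' once).
#'
#' @param regions Interval table (e.g. SEs).
#' @param loops Loop table.
#' @param cres CRE intervals.
#' @param genes Gene tibble (TSS points are used).
#' @return List with `n_cres`, `n_tss`, `n_regions` unique counts and the
#'   underlying index/id sets.
#' @export
region_contact_features <- function(regions, loops, cres, genes) {
  feetA <- loop_feet(loops, "A"); feetB <- loop_feet(loops, "B")
  ha <- join_overlaps(feetA, regions)
  hb <- join_overlaps(feetB, regions)
  # per (loop, region): feet overlapping that region
  a_pairs <- paste(ha$a_idx, ha$b_idx)
  b_pairs <- paste(hb$a_idx, hb$b_idx)
  only_a <- ha[!(a_pairs %in% b_pairs), , drop = FALSE]  # distal foot = B
  only_b <- hb[!(b_pairs %in% a_pairs), , drop = FALSE]  # distal foot = A
  distal <- bind_rows(
    if (nrow(only_a)) feetB[only_a$a_idx, c("chrom", "start", "end")],
    if (nrow(only_b)) feetA[only_b$a_idx, c("chrom", "start", "end")])
  if (is.null(distal) || nrow(distal) == 0) {
    return(list(n_cres = 0L, n_tss = 0L, n_regions = 0L,
                cre_idx = integer(), tss_genes = character(),
                region_idx = integer()))
  }
  cre_idx <- unique(join_overlaps(distal, cres)$b_idx)
  tss <- point_intervals(genes$chrom, genes$tss)
  tss_idx <- unique(join_overlaps(distal, tss)$b_idx)
  reg_idx <- unique(join_overlaps(distal, regions)$b_idx)
  list(n_cres = length(cre_idx), n_tss = length(tss_idx),
       n_regions = length(reg_idx),
       cre_idx = cre_idx, tss_genes = genes$gene_id[tss_idx],
       region_idx = reg_idx)
}

#' Fraction of region-touching loops that cross TAD boundaries
#'
#' Among loops touching any region, the percentage whose two feet do not
#' share a TAD (including the case where a foot lies in no TAD).
#'
#' @param regions Interval table.
#' @param loops Loop table.
#' @param tads Non-overlapping TADs.
#' @return List with `pct_crossing` (NA and `flag` when no loop touches a
#'   region), `n_touching`, `n_crossing`.
#' @export
crossing_fraction <- function(regions, loops, tads) {
  ha <- join_overlaps(loop_feet(loops, "A"), regions)
  hb <- join_overlaps(loop_feet(loops, "B"), regions)
  touching <- sort(unique(c(ha$a_idx, hb$a_idx)))
  if (!length(touching)) {
    return(list(pct_crossing = NA_real_, n_touching = 0L, n_crossing = 0L,
                flag = TRUE))
  }
  sub <- loops[touching, , drop = FALSE]
  ta <- join_overlaps(loop_feet(sub, "A"), tads)
  tb <- join_overlaps(loop_feet(sub, "B"), tads)
  crossing <- vapply(seq_len(nrow(sub)), function(i) {
    sa <- ta$b_idx[ta$a_idx == i]
    sb <- tb$b_idx[tb$a_idx == i]
    length(intersect(sa, sb)) == 0
  }, logical(1))
  list(pct_crossing = 100 * mean(crossing), n_touching = length(touching),
       n_crossing = sum(crossing), flag = FALSE)
}

#' Mean expression of genes with a TSS inside a region set
#'
#' A gene is counted once even when several regions overlap its TSS.
#'
#' @param genes Gene tibble with `expression`.
#' @param regions Interval table.
#' @param exclude_regions Optional interval table; genes whose TSS also
#'   falls in these regions are excluded (e.g. to compare CRE-only genes
#'   against SE genes).
#' @return List with `mean_expression`, `n_genes`, `gene_ids`.
#' @export
mean_expression_in_regions <- function(genes, regions, exclude_regions = NULL) {
  tss <- point_intervals(genes$chrom, genes$tss)
  inside <- overlaps_any(tss, regions)
  if (!is.null(exclude_regions) && nrow(exclude_regions)) {
    inside <- inside & !overlaps_any(tss, exclude_regions)
  }
  ids <- unique(genes$gene_id[inside])
  expr <- genes$expression[match(ids, genes$gene_id)]
  list(mean_expression = if (length(expr)) mean(expr) else NA_real_,
       n_genes = length(ids), gene_ids = ids)
}

#' Expression fold-change between two region sets
#'
#' `mean(genes with TSS in a) / mean(genes with TSS in b)`; with
#' `exclusive = TRUE` (default) genes in both sets are assigned to `a`
#' only.
#'
#' @param genes Gene tibble.
#' @param regions_a,regions_b Interval tables.
#' @param exclusive Exclude `regions_a` genes from the `b` group.
#' @return List with `fold`, `mean_a`, `mean_b`, `n_a`, `n_b`, `flag`
#'   (TRUE when either group is empty and the fold is undefined).
#' @export
expression_fold <- function(genes, regions_a, regions_b, exclusive = TRUE) {
  a <- mean_expression_in_regions(genes, regions_a)
  b <- mean_expression_in_regions(genes, regions_b,
                                  exclude_regions = if (exclusive) regions_a)
  flag <- a$n_genes == 0 || b$n_genes == 0
  list(fold = if (flag) NA_real_ else a$mean_expression / b$mean_expression,
       mean_a = a$mean_expression, mean_b = b$mean_expression,
       n_a = a$n_genes, n_b = b$n_genes, flag = flag)
}

#' Per-random-set expression means
#'
#' The mean expression of genes with a TSS in each random region set, for
#' use with [enrichment_t()].
#'
#' @param genes Gene tibble.
#' @param random_regions Output of [sample_random_regions()].
#' @return Numeric vector, one mean per set (NA for sets capturing no TSS).
#' @export
random_set_expression_means <- function(genes, random_regions) {
  vapply(sort(unique(random_regions$set_index)), function(si) {
    mean_expression_in_regions(
      genes, random_regions[random_regions$set_index == si, ])$mean_expression
  }, numeric(1))
}

#' Percentage of a gene set with a TSS inside a region set
#'
#' @param genes Gene tibble (the gene set of interest).
#' @param regions Interval table.
#' @return Percentage in \[0, 100\].
#' @export
geneset_tss_overlap_fraction <- function(genes, regions) {
  if (nrow(genes) == 0) abort("gene set is empty")
  tss <- point_intervals(genes$chrom, genes$tss)
  100 * mean(overlaps_any(tss, regions))
}

#' Cross-species conservation of gene-pair topology
#'
#' Unordered gene pairs of species B (e.g. mouse) are called "sharing a
#' TAD" when both TSS lie in the same TAD and "loop-connected" when some
#' loop has one foot overlapping one gene's body and the other foot
#' overlapping the other's. The conserved fractions are the shares of
#' species-B pairs whose orthology-mapped species-A pairs satisfy the same
#' predicate.
#'
#' @param tads_a,loops_a,genes_a Topology of species A (e.g. human).
#' @param tads_b,loops_b,genes_b Topology of species B (e.g. mouse).
#' @param ortholog_map Tibble with columns `gene_b`, `gene_a`; must be
#'   one-to-one over the genes considered.
#' @return An object of class `conservation_summary`.
#' @export
gene_pair_conservation <- function(tads_a, loops_a, genes_a,
                                   tads_b, loops_b, genes_b, ortholog_map) {
  if (anyDuplicated(ortholog_map$gene_b) || anyDuplicated(ortholog_map$gene_a)) {
    abort("ortholog map must be one-to-one")
  }
  pairs_tad <- function(tads, genes) {
    tss <- point_intervals(genes$chrom, genes$tss)
    hits <- join_overlaps(tss, tads)
    out <- character(0)
    for (ti in unique(hits$b_idx)) {
      gi <- genes$gene_id[hits$a_idx[hits$b_idx == ti]]
      gi <- sort(unique(gi))
      if (length(gi) >= 2) {
        cmb <- utils::combn(gi, 2)
        out <- c(out, paste(cmb[1, ], cmb[2, ]))
      }
    }
    unique(out)
  }
  pairs_loop <- function(loops, genes) {
    bodies <- tibble(chrom = genes$chrom, start = genes$start, end = genes$end)
    ha <- join_overlaps(loop_feet(loops, "A"), bodies)
    hb <- join_overlaps(loop_feet(loops, "B"), bodies)
    out <- character(0)
    for (li in intersect(unique(ha$a_idx), unique(hb$a_idx))) {
      ga <- genes$gene_id[ha$b_idx[ha$a_idx == li]]
      gb <- genes$gene_id[hb$b_idx[hb$a_idx == li]]
      grid <- expand.grid(a = ga, b = gb, stringsAsFactors = FALSE)
      grid <- grid[grid$a != grid$b, , drop = FALSE]
      if (nrow(grid)) {
        key <- paste(pmin(grid$a, grid$b), pmax(grid$a, grid$b))
        out <- c(out, key)
      }
    }
    unique(out)
  }
  map_pair <- function(keys) {
    if (!length(keys)) return(character(0))
    parts <- strsplit(keys, " ", fixed = TRUE)
    g1 <- ortholog_map$gene_a[match(vapply(parts, `[[`, "", 1), ortholog_map$gene_b)]
    g2 <- ortholog_map$gene_a[match(vapply(parts, `[[`, "", 2), ortholog_map$gene_b)]
    ok <- !is.na(g1) & !is.na(g2)
    paste(pmin(g1[ok], g2[ok]), pmax(g1[ok], g2[ok]))
  }
  tad_b <- pairs_tad(tads_b, genes_b)
  tad_a <- pairs_tad(tads_a, genes_a)
  loop_b <- pairs_loop(loops_b, genes_b)
  loop_a <- pairs_loop(loops_a, genes_a)
  structure(list(
    n_pairs_tad_b = length(tad_b),
    frac_tad_conserved = if (length(tad_b)) mean(map_pair(tad_b) %in% tad_a) else NA_real_,
    n_pairs_loop_b = length(loop_b),
    frac_loop_conserved = if (length(loop_b)) mean(map_pair(loop_b) %in% loop_a) else NA_real_),
    class = "conservation_summary")
}

#' @export
print.conservation_summary <- function(x, ...) {
  cat(sprintf("<conservation: %.1f%% of %d TAD pairs, %.1f%% of %d loop pairs conserved>\n",
              100 * x$frac_tad_conserved, x$n_pairs_tad_b,
              100 * x$frac_loop_conserved, x$n_pairs_loop_b))
  invisible(x)
}
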
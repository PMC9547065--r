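#' Promoter/distal position class of eQTL variants
#'
#' A variant is a promoter eQTL when it lies within +/- `promoter_halfwidth`
#' of its eGene's TSS (boundary inclusive: a variant exactly 2,500 bp away
#' is promoter), otherwise distal. Variants on a different chromosome from
#' their eGene are annotated distal with a `trans` flag.
#'
#' @param eqtls eQTL tibble (`variant_id`, `chrom`, `pos` 0-based,
#'   `egene_id`).
#' @param genes Gene tibble.
#' @param promoter_halfwidth Promoter half-width in bp (default 2,500).
#' @return `eqtls` with `position_class` and `trans` columns added.
#' @export
classify_position <- function(eqtls, genes, promoter_halfwidth = 2500) {
  gi <- match(eqtls$egene_id, genes$gene_id)
  if (anyNA(gi)) {
    abort(sprintf("eGene '%s' not found in gene table",
                  eqtls$egene_id[which(is.na(gi))[1]]))
  }
  same_chrom <- eqtls$chrom == genes$chrom[gi]
  d <- abs(eqtls$pos - genes$tss[gi])
  eqtls$position_class <- ifelse(same_chrom & d <= promoter_halfwidth,
                                 "promoter", "distal")
  eqtls$trans <- !same_chrom
  eqtls
}

#' Compartment label of each variant
#'
#' The label of the compartment segment containing the variant position;
#' `none` when the position is not covered by any analyzed segment.
#'
#' @param eqtls eQTL tibble.
#' @param compartments Segment table (`chrom`, `start`, `end`, `label`).
#' @return `eqtls` with a `compartment` column added. Proportions over
#'   pairs are available via [eqtl_summary()].
#' @export
compartment_of_variants <- function(eqtls, compartments) {
  pts <- point_intervals(eqtls$chrom, eqtls$pos)
  hits <- join_overlaps(pts, compartments)
  lab <- rep("none", nrow(eqtls))
  lab[hits$a_idx] <- compartments$label[hits$b_idx]
  eqtls$compartment <- lab
  eqtls
}

#' Variant-eGene TAD co-residence and its enrichment over random TADs
#'
#' `same_tad` is TRUE when one TAD contains both the variant position and
#' the eGene TSS (trans pairs are FALSE). When random TAD sets are
#' supplied, the observed proportion is compared with the per-set
#' proportions by [enrichment_t()].
#'
#' @param eqtls eQTL tibble.
#' @param tads Non-overlapping TAD intervals.
#' @param genes Gene tibble.
#' @param random_tad_sets Optional output of [sample_random_tads()].
#' @return List: `records` (eqtls + `same_tad`), `observed_proportion`,
#'   `random_proportions`, `enrichment` (NULL without random sets).
#' @export
same_tad_analysis <- function(eqtls, tads, genes, random_tad_sets = NULL) {
  gi <- match(eqtls$egene_id, genes$gene_id)
  prop_in <- function(tad_tbl) {
    pts <- point_intervals(eqtls$chrom, eqtls$pos)
    hv <- join_overlaps(pts, tad_tbl)
    tssp <- point_intervals(genes$chrom[gi], genes$tss[gi])
    hg <- join_overlaps(tssp, tad_tbl)
    key_v <- paste(hv$a_idx, hv$b_idx)
    key_g <- paste(hg$a_idx, hg$b_idx)
    shared <- key_v %in% key_g
    res <- logical(nrow(eqtls))
    res[unique(hv$a_idx[shared])] <- TRUE
    res
  }
  same <- prop_in(tads)
  out <- list(records = mutate(eqtls, same_tad = same),
              observed_proportion = mean(same),
              random_proportions = NULL, enrichment = NULL)
  if (!is.null(random_tad_sets)) {
    rp <- vapply(sort(unique(random_tad_sets$set_index)), function(si) {
      mean(prop_in(random_tad_sets[random_tad_sets$set_index == si, ]))
    }, numeric(1))
    out$random_proportions <- rp
    out$enrichment <- enrichment_t(mean(same), rp, name = "same_tad_proportion")
  }
  out
}

#' pieQTL loop taxonomy
#'
#' For each variant, all loops with a foot overlapping the variant position
#' are collected and the opposite feet are intersected with the promoter
#' windows (TSS +/- `promoter_halfwidth`) of all genes. The class is
#' `egene_pieqtl` when any opposite foot hits the eGene's promoter,
#' otherwise `non_egene_pieqtl` when any promoter is hit, otherwise
#' `eqtl_only`; variants on no loop foot are `not_on_loop`. A variant on
#' the feet of several loops takes the highest class (eGene > non-eGene >
#' only).
#'
#' @param eqtls eQTL tibble.
#' @param loops Loop table.
#' @param genes Gene tibble.
#' @param promoter_halfwidth Promoter half-width in bp.
#' @return `eqtls` with a `loop_class` column added.
#' @export
pieqtl_classify <- function(eqtls, loops, genes, promoter_halfwidth = 2500) {
  pts <- point_intervals(eqtls$chrom, eqtls$pos)
  prom <- promoter_regions(genes, promoter_halfwidth)
  feetA <- loop_feet(loops, "A"); feetB <- loop_feet(loops, "B")
  ha <- join_overlaps(pts, feetA)  # variant on foot A -> opposite is B
  hb <- join_overlaps(pts, feetB)
  opp <- bind_rows(
    if (nrow(ha)) tibble(v = ha$a_idx, chrom = loops$chrom[ha$b_idx],
                         start = loops$startB[ha$b_idx], end = loops$endB[ha$b_idx]),
    if (nrow(hb)) tibble(v = hb$a_idx, chrom = loops$chrom[hb$b_idx],
                         start = loops$startA[hb$b_idx], end = loops$endA[hb$b_idx]))
  cls <- rep("not_on_loop", nrow(eqtls))
  if (!is.null(opp) && nrow(opp)) {
    cls[unique(opp$v)] <- "eqtl_only"
    hp <- join_overlaps(opp[, c("chrom", "start", "end")], prom)
    if (nrow(hp)) {
      v_of_hit <- opp$v[hp$a_idx]
      gene_of_hit <- prom$gene_id[hp$b_idx]
      cls[unique(v_of_hit)] <- "non_egene_pieqtl"
      is_egene <- gene_of_hit == eqtls$egene_id[v_of_hit]
      cls[unique(v_of_hit[is_egene])] <- "egene_pieqtl"
    }
  }
  eqtls$loop_class <- cls
  eqtls
}

#' Regulatory-element overlap of variants
#'
#' `regulatory_class` is `SE` when the variant lies in a super-enhancer
#' (SE takes precedence), else `CRE` when in a CRE, else `none`;
#' `region_overlaps_egene` is TRUE when a containing region overlaps the
#' eGene body.
#'
#' @param eqtls eQTL tibble.
#' @param cres CRE intervals.
#' @param ses SE intervals.
#' @param genes Gene tibble.
#' @return `eqtls` with `regulatory_class` and `region_overlaps_egene`
#'   columns added.
#' @export
regulatory_overlap <- function(eqtls, cres, ses, genes) {
  pts <- point_intervals(eqtls$chrom, eqtls$pos)
  gi <- match(eqtls$egene_id, genes$gene_id)
  bodies <- tibble(chrom = genes$chrom[gi], start = genes$start[gi],
                   end = genes$end[gi], .row = seq_len(nrow(eqtls)))
  cls <- rep("none", nrow(eqtls))
  h_cre <- join_overlaps(pts, cres)
  h_se <- join_overlaps(pts, ses)
  region_hits_egene <- function(h, regions) {
    out <- logical(nrow(eqtls))
    if (!nrow(h)) return(out)
    ok <- regions$chrom[h$b_idx] == bodies$chrom[h$a_idx] &
      regions$start[h$b_idx] < bodies$end[h$a_idx] &
      regions$end[h$b_idx] > bodies$start[h$a_idx]
    out[unique(h$a_idx[ok])] <- TRUE
    out
  }
  in_cre <- logical(nrow(eqtls)); in_cre[unique(h_cre$a_idx)] <- TRUE
  in_se <- logical(nrow(eqtls)); in_se[unique(h_se$a_idx)] <- TRUE
  cls[in_cre] <- "CRE"
  cls[in_se] <- "SE"
  eg_cre <- region_hits_egene(h_cre, cres)
  eg_se <- region_hits_egene(h_se, ses)
  over_egene <- ifelse(in_se, eg_se, ifelse(in_cre, eg_cre, FALSE))
  eqtls$regulatory_class <- cls
  eqtls$region_overlaps_egene <- over_egene
  eqtls
}

#' H3K27Ac context of variants and promoter-vs-distal Welch test
#'
#' Sums H3K27Ac coverage in the inclusive +/- `halfwidth` window around
#' each variant and, per regulatory-class stratum, compares distal against
#' promoter variants with a Welch two-sample t-test (Satterthwaite df;
#' distal group listed first, so a negative t means promoter variants carry
#' more signal).
#'
#' @param eqtls Annotated eQTL tibble (needs `position_class` and
#'   `regulatory_class`; run [classify_position()] and
#'   [regulatory_overlap()] first).
#' @param track H3K27Ac [signal_track()].
#' @param halfwidth Window half-width in bp (default 100).
#' @return List: `records` (eqtls + `h3k27ac`), `tests` tibble (stratum,
#'   t, df, p, group sizes; strata with fewer than 2 per group are
#'   skipped with a warning).
#' @export
h3k27ac_context <- function(eqtls, track, halfwidth = 100) {
  cov <- vapply(seq_len(nrow(eqtls)), function(i) {
    coverage_in_window(track, eqtls$chrom[i], eqtls$pos[i], halfwidth)
  }, numeric(1))
  eqtls$h3k27ac <- cov
  tests <- vector("list", 0L)
  for (stratum in intersect(c("CRE", "SE"), unique(eqtls$regulatory_class))) {
    sel <- eqtls$regulatory_class == stratum
    d <- cov[sel & eqtls$position_class == "distal"]
    p <- cov[sel & eqtls$position_class == "promoter"]
    if (length(d) < 2 || length(p) < 2 || (sd(d) == 0 && sd(p) == 0)) {
      warn(sprintf("stratum %s: too few records or zero variance, test skipped",
                   stratum))
      next
    }
    tt <- t.test(d, p)
    n_d <- length(d); n_p <- length(p)
    tests[[length(tests) + 1L]] <- tibble(
      stratum = stratum, t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value, n_distal = n_d, n_promoter = n_p)
  }
  list(records = eqtls,
       tests = if (length(tests)) bind_rows(tests) else
         tibble(stratum = character(), t = numeric(), df = numeric(),
                p = numeric(), n_distal = integer(), n_promoter = integer()))
}

#' Full topological annotation of eQTL variant-eGene pairs
#'
#' Convenience wrapper chaining [classify_position()],
#' [compartment_of_variants()], [same_tad_analysis()], [pieqtl_classify()],
#' [regulatory_overlap()] and (when a track is given) [h3k27ac_context()].
#'
#' @param eqtls eQTL tibble.
#' @param genes Gene tibble.
#' @param loops Loop table.
#' @param tads TAD intervals.
#' @param compartments Compartment segments.
#' @param cres,ses Regulatory element intervals.
#' @param track Optional H3K27Ac [signal_track()].
#' @param random_tad_sets Optional random TAD sets for the same-TAD
#'   enrichment.
#' @param promoter_halfwidth Promoter half-width in bp.
#' @return List: `records` (one fully annotated row per pair),
#'   `same_tad_enrichment`, `welch_tests`.
#' @export
annotate_eqtls <- function(eqtls, genes, loops, tads, compartments,
                           cres, ses, track = NULL, random_tad_sets = NULL,
                           promoter_halfwidth = 2500) {
  x <- classify_position(eqtls, genes, promoter_halfwidth)
  x <- compartment_of_variants(x, compartments)
  st <- same_tad_analysis(x, tads, genes, random_tad_sets)
  x <- st$records
  x <- pieqtl_classify(x, loops, genes, promoter_halfwidth)
  x <- regulatory_overlap(x, cres, ses, genes)
  welch <- NULL
  if (!is.null(track)) {
    hk <- h3k27ac_context(x, track)
    x <- hk$records
    welch <- hk$tests
  }
  list(records = x, same_tad_enrichment = st$enrichment,
       welch_tests = welch)
}

#' Summary counts of an annotated eQTL table
#'
#' Compartment proportions, loop-class counts, regulatory-class counts and
#' the same stratified by disease tag (a record with tag `t` contributes to
#' stratum `t`; strata are exact subsets of the global counts).
#'
#' @param records Annotated records from [annotate_eqtls()].
#' @return List of tibbles: `compartment`, `loop_class`,
#'   `regulatory_class`, `by_tag`.
#' @export
eqtl_summary <- function(records) {
  n <- nrow(records)
  comp <- records |> group_by(.data$compartment) |>
    summarise(n = n()) |> mutate(proportion = .data$n / !!n)
  lc <- records |> group_by(.data$loop_class) |> summarise(n = n())
  rc <- records |> group_by(.data$regulatory_class) |>
    summarise(n = n(), n_overlapping_egene = sum(.data$region_overlaps_egene))
  tags <- setdiff(unique(unlist(strsplit(records$tags, ","))), "")
  by_tag <- bind_rows(lapply(tags, function(tg) {
    sel <- vapply(strsplit(records$tags, ","), function(v) tg %in% v, logical(1))
    sub <- records[sel, ]
    tibble(tag = tg, n = nrow(sub),
           n_A = sum(sub$compartment == "A"),
           n_same_tad = if ("same_tad" %in% names(sub)) sum(sub$same_tad) else NA_integer_,
           n_pieqtl = sum(sub$loop_class %in% c("egene_pieqtl", "non_egene_pieqtl")),
           n_egene_pieqtl = sum(sub$loop_class == "egene_pieqtl"),
           n_cre = sum(sub$regulatory_class == "CRE"),
           n_se = sum(sub$regulatory_class == "SE"))
  }))
  list(compartment = comp, loop_class = lc, regulatory_class = rc,
       by_tag = by_tag)
}
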
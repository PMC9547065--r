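#' Filter LD variants on MAF and r-squared
#'
#' Keeps variants with `maf >= maf_min` AND `r2 >= r2_min`, both bounds
#' inclusive (the published filter: MAF >= 1% and r2 >= 0.7). Records with
#' missing MAF or r2 are dropped with a warning (or rejected with
#' `on_missing = "error"`). The filter is idempotent and order-preserving.
#'
#' @param ld_variants LD-variant tibble (`rsid`, `chrom`, `pos`,
#'   `lead_rsid`, `r2`, `maf`).
#' @param maf_min Minor-allele-frequency lower bound (default 0.01).
#' @param r2_min LD r-squared lower bound (default 0.7).
#' @param on_missing `"drop"` (default) or `"error"` for records with
#'   missing MAF/r2.
#' @return The filtered tibble.
#' @export
filter_ld <- function(ld_variants, maf_min = 0.01, r2_min = 0.7,
                      on_missing = c("drop", "error")) {
  on_missing <- match.arg(on_missing)
  miss <- is.na(ld_variants$maf) | is.na(ld_variants$r2)
  if (any(miss)) {
    if (on_missing == "error") {
      abort(sprintf("LD variant '%s' has missing MAF or r2",
                    ld_variants$rsid[which(miss)[1]]))
    }
    warn(sprintf("dropping %d LD variant(s) with missing MAF or r2", sum(miss)))
    ld_variants <- ld_variants[!miss, , drop = FALSE]
  }
  ld_variants[ld_variants$maf >= maf_min & ld_variants$r2 >= r2_min, ,
              drop = FALSE]
}

# Normalize a variant table (lead or LD) to rsid/chrom/pos/class.
variant_points <- function(variants) {
  cls <- col_or(variants, "variant_class") %||%
    if ("lead_rsid" %in% names(variants)) "filtered_LD" else "lead"
  tibble(rsid = variants$rsid, chrom = variants$chrom, pos = variants$pos,
         variant_class = cls,
         disease = col_or(variants, "disease", NA_character_),
         locus = col_or(variants, "locus", NA_character_))
}

#' Loop-mediated target genes of GWAS variants
#'
#' For each loop with one foot overlapping a variant position, the opposite
#' foot is intersected with gene bodies (mechanism `loop_to_body`) and TSS
#' points (`loop_to_tss`). One link is produced per (variant, gene,
#' mechanism, loop); deduplication happens in [locus_summary()].
#'
#' @param variants Lead or (filtered) LD variant tibble (0-based `pos`).
#' @param loops Loop table.
#' @param genes Gene tibble.
#' @return Link tibble: `rsid`, `variant_class`, `disease`, `locus`,
#'   `gene_id`, `mechanism`, `evidence` (loop id).
#' @export
loop_targets <- function(variants, loops, genes) {
  v <- variant_points(variants)
  pts <- point_intervals(v$chrom, v$pos)
  ha <- join_overlaps(pts, loop_feet(loops, "A"))
  hb <- join_overlaps(pts, loop_feet(loops, "B"))
  opp <- bind_rows(
    if (nrow(ha)) tibble(vi = ha$a_idx, li = ha$b_idx,
                         chrom = loops$chrom[ha$b_idx],
                         start = loops$startB[ha$b_idx],
                         end = loops$endB[ha$b_idx]),
    if (nrow(hb)) tibble(vi = hb$a_idx, li = hb$b_idx,
                         chrom = loops$chrom[hb$b_idx],
                         start = loops$startA[hb$b_idx],
                         end = loops$endA[hb$b_idx]))
  empty <- tibble(rsid = character(), variant_class = character(),
                  disease = character(), locus = character(),
                  gene_id = character(), mechanism = character(),
                  evidence = character())
  if (is.null(opp) || nrow(opp) == 0) return(empty)
  bodies <- tibble(chrom = genes$chrom, start = genes$start, end = genes$end)
  tss <- point_intervals(genes$chrom, genes$tss)
  mk <- function(hits, mech) {
    if (!nrow(hits)) return(NULL)
    tibble(rsid = v$rsid[opp$vi[hits$a_idx]],
           variant_class = v$variant_class[opp$vi[hits$a_idx]],
           disease = v$disease[opp$vi[hits$a_idx]],
           locus = v$locus[opp$vi[hits$a_idx]],
           gene_id = genes$gene_id[hits$b_idx],
           mechanism = mech,
           evidence = loops$loop_id[opp$li[hits$a_idx]])
  }
  out <- bind_rows(
    mk(join_overlaps(opp[, c("chrom", "start", "end")], bodies), "loop_to_body"),
    mk(join_overlaps(opp[, c("chrom", "start", "end")], tss), "loop_to_tss"))
  if (is.null(out) || nrow(out) == 0) return(empty)
  distinct(out)
}

#' Shared-regulatory-element target genes of GWAS variants
#'
#' For each CRE (or SE) containing a variant, every gene whose body or TSS
#' overlaps the same region yields a `cre_shared` (or `se_shared`) link.
#'
#' @param variants Variant tibble.
#' @param cres,ses Regulatory element intervals (either may be NULL).
#' @param genes Gene tibble.
#' @return Link tibble as in [loop_targets()]; `evidence` is the region
#'   coordinate string.
#' @export
regulatory_targets <- function(variants, cres, ses, genes) {
  v <- variant_points(variants)
  pts <- point_intervals(v$chrom, v$pos)
  bodies <- tibble(chrom = genes$chrom, start = genes$start, end = genes$end)
  tss <- point_intervals(genes$chrom, genes$tss)
  one_set <- function(regions, mech) {
    if (is.null(regions) || nrow(regions) == 0) return(NULL)
    hv <- join_overlaps(pts, regions)
    if (!nrow(hv)) return(NULL)
    hg_body <- join_overlaps(regions, bodies)
    hg_tss <- join_overlaps(regions, tss)
    hg <- unique(rbind(hg_body, hg_tss))
    m <- inner_join(hv, hg, by = c(b_idx = "a_idx"),
                    relationship = "many-to-many")
    if (!nrow(m)) return(NULL)
    tibble(rsid = v$rsid[m$a_idx],
           variant_class = v$variant_class[m$a_idx],
           disease = v$disease[m$a_idx],
           locus = v$locus[m$a_idx],
           gene_id = genes$gene_id[m$b_idx.y],
           mechanism = mech,
           evidence = sprintf("%s:%s-%s", regions$chrom[m$b_idx],
                              format_coord(regions$start[m$b_idx]),
                              format_coord(regions$end[m$b_idx])))
  }
  out <- bind_rows(one_set(cres, "cre_shared"), one_set(ses, "se_shared"))
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(rsid = character(), variant_class = character(),
                  disease = character(), locus = character(),
                  gene_id = character(), mechanism = character(),
                  evidence = character()))
  }
  distinct(out)
}

#' Closest gene per GWAS variant
#'
#' The nearest gene body (deterministic tie-breaks of [closest_feature()]),
#' mechanism `closest`.
#'
#' @param variants Variant tibble.
#' @param genes Gene tibble.
#' @return Link tibble with a `distance` column.
#' @export
closest_targets <- function(variants, genes) {
  v <- variant_points(variants)
  pts <- point_intervals(v$chrom, v$pos)
  bodies <- tibble(chrom = genes$chrom, start = genes$start, end = genes$end)
  cf <- closest_feature(pts, bodies)
  tibble(rsid = v$rsid, variant_class = v$variant_class,
         disease = v$disease, locus = v$locus,
         gene_id = ifelse(is.na(cf$feature_idx), NA_character_,
                          genes$gene_id[cf$feature_idx]),
         mechanism = "closest",
         evidence = NA_character_,
         distance = cf$distance)
}

#' Per-disease / per-locus GWAS summary counts
#'
#' Deduplicated variant counts per category: variants overlapping any loop
#' foot, variants in loop contact with a gene body or TSS, and variants
#' residing in CREs / SEs. A variant counts once per category regardless of
#' link multiplicity. A second loop set (e.g. another tissue) can be
#' supplied for side-by-side counts.
#'
#' @param variants Variant tibble (0-based `pos`).
#' @param links Link tibble from [loop_targets()] /
#'   [regulatory_targets()].
#' @param loops Loop table (for the "overlaps a loop" counts).
#' @param cres,ses Optional regulatory element intervals.
#' @param alt_loops Optional second loop table; adds `on_loop_alt` /
#'   `contacting_gene_alt` columns.
#' @param genes Gene table (needed when `alt_loops` is given).
#' @return List: `per_disease` and `per_locus` tibbles.
#' @export
locus_summary <- function(variants, links, loops, cres = NULL, ses = NULL,
                          alt_loops = NULL, genes = NULL) {
  v <- variant_points(variants)
  pts <- point_intervals(v$chrom, v$pos)
  on_loop <- overlaps_any(pts, loop_feet(loops, "both"))
  in_cre <- if (!is.null(cres)) overlaps_any(pts, cres) else rep(FALSE, nrow(v))
  in_se <- if (!is.null(ses)) overlaps_any(pts, ses) else rep(FALSE, nrow(v))
  loop_link_rsids <- unique(links$rsid[links$mechanism %in%
                                         c("loop_to_body", "loop_to_tss")])
  contacting <- v$rsid %in% loop_link_rsids
  base <- tibble(rsid = v$rsid, disease = v$disease, locus = v$locus,
                 variant_class = v$variant_class,
                 on_loop = on_loop, contacting_gene = contacting,
                 in_cre = in_cre, in_se = in_se)
  if (!is.null(alt_loops)) {
    base$on_loop_alt <- overlaps_any(pts, loop_feet(alt_loops, "both"))
    alt_links <- loop_targets(variants, alt_loops, genes)
    base$contacting_gene_alt <- base$rsid %in%
      unique(alt_links$rsid[alt_links$mechanism %in% c("loop_to_body", "loop_to_tss")])
  }
  dedup <- distinct(base, .data$disease, .data$variant_class, .data$rsid,
                    .keep_all = TRUE)
  summarise_cats <- function(d, keys) {
    d |> group_by(across(dplyr::all_of(keys))) |>
      summarise(n_variants = n(),
                n_on_loop = sum(.data$on_loop),
                n_contacting_gene = sum(.data$contacting_gene),
                n_in_cre = sum(.data$in_cre),
                n_in_se = sum(.data$in_se),
                across(dplyr::any_of(c("on_loop_alt", "contacting_gene_alt")),
                       sum, .names = "n_{.col}"),
                .groups = "drop")
  }
  list(per_disease = summarise_cats(dedup, c("disease", "variant_class")),
       per_locus = summarise_cats(dedup, c("disease", "locus", "variant_class")))
}

#' Re-check that every link's cited evidence satisfies its mechanism
#'
#' A consistency assertion: `loop_to_*` links must cite a loop with one
#' foot on the variant and the other on the gene body/TSS; `*_shared`
#' links must cite a region containing the variant and overlapping the
#' gene.
#'
#' @param links Link tibble.
#' @param variants Variant tibble.
#' @param loops Loop table.
#' @param genes Gene tibble.
#' @param cres,ses Regulatory element intervals.
#' @return TRUE invisibly, or an error naming the first bad link.
#' @export
check_links <- function(links, variants, loops, genes, cres = NULL, ses = NULL) {
  v <- variant_points(variants)
  for (i in seq_len(nrow(links))) {
    l <- links[i, ]
    vi <- which(v$rsid == l$rsid)[1]
    gi <- which(genes$gene_id == l$gene_id)[1]
    ok <- FALSE
    if (l$mechanism %in% c("loop_to_body", "loop_to_tss")) {
      lp <- loops[loops$loop_id == l$evidence, ]
      if (nrow(lp) != 1 || is.na(vi) || is.na(gi)) {
        abort(sprintf("link %d cites unknown loop/variant/gene", i))
      }
      onA <- lp$startA <= v$pos[vi] & v$pos[vi] < lp$endA & lp$chrom == v$chrom[vi]
      onB <- lp$startB <= v$pos[vi] & v$pos[vi] < lp$endB & lp$chrom == v$chrom[vi]
      tgt_s <- if (onA) lp$startB else lp$startA
      tgt_e <- if (onA) lp$endB else lp$endA
      ok <- (onA || onB) && lp$chrom == genes$chrom[gi] &&
        if (l$mechanism == "loop_to_body") {
          tgt_s < genes$end[gi] && tgt_e > genes$start[gi]
        } else {
          tgt_s <= genes$tss[gi] && genes$tss[gi] < tgt_e
        }
    } else if (l$mechanism %in% c("cre_shared", "se_shared")) {
      regions <- if (l$mechanism == "cre_shared") cres else ses
      m <- regmatches(l$evidence, regexec("^(.*):([0-9]+)-([0-9]+)$", l$evidence))[[1]]
      rs <- as.numeric(m[3]); re <- as.numeric(m[4])
      ok <- m[2] == v$chrom[vi] && rs <= v$pos[vi] && v$pos[vi] < re &&
        ((rs < genes$end[gi] && re > genes$start[gi]) ||
           (rs <= genes$tss[gi] && genes$tss[gi] < re))
    } else if (l$mechanism == "closest") {
      ok <- TRUE
    }
    if (!isTRUE(ok)) {
      abort(sprintf("link %d (%s -> %s via %s) fails its mechanism predicate",
                    i, l$rsid, l$gene_id, l$mechanism))
    }
  }
  invisible(TRUE)
}
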
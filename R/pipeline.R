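#' Default pipeline parameters
#'
#' The analysis defaults: promoter half-width 2,500 bp, SE edge threshold
#' 5,000 bp, stitch distance 12,500 bp, insulation window 100 kb,
#' compartment bin 100 kb, 100 random sets, LD filter MAF >= 0.01 and
#' r2 >= 0.7.
#'
#' @return Named list of parameters.
#' @export
pipeline_params <- function() {
  list(promoter_halfwidth = 2500, edge_threshold = 5000,
       stitch_distance = 12500, insulation_window = 1e5,
       compartment_bin = 1e5, n_random_sets = 100,
       maf_min = 0.01, r2_min = 0.7)
}

#' Run the integrated pipeline on a synthetic or loaded bundle
#'
#' Drives every stage end to end: CRE derivation and SE calling, diamond
#' insulation and compartment calls per chromosome, random-region and
#' random-TAD nulls, SE topology statistics with enrichment tests, eQTL
#' annotation, and GWAS variant-to-gene linking. Returns a machine-readable
#' run report; all randomness is governed by `seed`.
#'
#' @param bundle A [simulate_bundle()] result (or a list with the same
#'   elements loaded from files).
#' @param params Parameter list, see [pipeline_params()]; partial overrides
#'   are merged over the defaults.
#' @param seed RNG seed for the resampling nulls.
#' @return An object of class `chromhub_report` (a nested list; serialize
#'   with [write_report()]).
#' @export
run_pipeline <- function(bundle, params = list(), seed = 1) {
  p <- utils::modifyList(pipeline_params(), params)
  build <- bundle$build
  genes <- bundle$genes
  loops <- bundle$loops
  tads <- bundle$tads

  # --- regulatory elements and SE call -----------------------------------
  cres <- merge_active_states(bundle$states)
  proms <- promoter_regions(genes, p$promoter_halfwidth, build)
  cres_nontss <- exclude_tss_cres(cres, proms)
  stitched <- stitch(cres_nontss, p$stitch_distance)
  stitched <- region_signal(stitched, bundle$case_track, bundle$control_track)
  se_call <- rose_cutoff(stitched)
  ses <- se_regions(se_call)

  # --- matrix topology ----------------------------------------------------
  insulation <- NULL; compartments <- NULL
  if (!is.null(bundle$matrices)) {
    ins <- lapply(bundle$matrices, diamond_insulation, window_bp = p$insulation_window)
    insulation <- bind_rows(ins)
    class(insulation) <- class(ins[[1]])
    attr(insulation, "bin_size") <- attr(ins[[1]], "bin_size")
    calls <- lapply(bundle$matrices, compartment_call,
                    reference = bundle$case_track, bin_size = p$compartment_bin)
    compartments <- compartment_segments(calls)
  } else {
    compartments <- bundle$compartments
  }

  # --- nulls --------------------------------------------------------------
  med_len <- stats::median(ses$end - ses$start)
  rand_regions <- sample_random_regions(build, nrow(ses), med_len,
                                        n_sets = p$n_random_sets,
                                        seed = sub_seed(seed, 101))
  rand_tads <- sample_random_tads(build, tads, n_sets = p$n_random_sets,
                                  seed = sub_seed(seed, 102))

  # --- SE topology --------------------------------------------------------
  placements <- place_regions_in_tads(ses, tads, p$edge_threshold)
  tad_groups <- classify_tads(tads, compartments, placements)
  se_loops <- region_loop_summary(ses, loops)
  rand_loop_counts <- vapply(0:(p$n_random_sets - 1), function(si) {
    region_loop_summary(rand_regions[rand_regions$set_index == si, ],
                        loops)$n_loops_touching
  }, numeric(1))
  loop_enrich <- enrichment_t(se_loops$n_loops_touching, rand_loop_counts,
                              "loops_touching_regions")
  fold <- expression_fold(genes, ses, cres)
  rand_means <- random_set_expression_means(genes, rand_regions)
  se_mean <- mean_expression_in_regions(genes, ses)$mean_expression
  expr_enrich <- enrichment_t(se_mean, rand_means[!is.na(rand_means)],
                              "mean_expression_in_regions")

  # --- eQTL annotation ----------------------------------------------------
  eq <- annotate_eqtls(bundle$eqtls, genes, loops, tads, compartments,
                       cres, ses, track = bundle$case_track,
                       random_tad_sets = rand_tads,
                       promoter_halfwidth = p$promoter_halfwidth)
  eq_sum <- eqtl_summary(eq$records)

  # --- GWAS linking -------------------------------------------------------
  filtered_ld <- filter_ld(bundle$ld_variants, p$maf_min, p$r2_min)
  gwas_variants <- bind_rows(
    mutate(bundle$lead_variants, variant_class = "lead"),
    mutate(filtered_ld, variant_class = "filtered_LD"))
  links <- bind_rows(loop_targets(gwas_variants, loops, genes),
                     regulatory_targets(gwas_variants, cres, ses, genes))
  gwas_sum <- locus_summary(gwas_variants, links, loops, cres, ses)

  structure(list(
    params = p, seed = seed,
    counts = list(
      n_cres = nrow(cres), n_cres_nontss = nrow(cres_nontss),
      n_stitched = nrow(stitched), n_se = nrow(ses),
      n_tads = nrow(tads), n_loops = nrow(loops),
      n_genes = nrow(genes), n_eqtls = nrow(bundle$eqtls),
      n_lead_variants = nrow(bundle$lead_variants),
      n_ld_variants = nrow(bundle$ld_variants),
      n_filtered_ld = nrow(filtered_ld),
      n_gwas_links = nrow(links)),
    se_call = se_call, se_placements = placements, tad_groups = tad_groups,
    insulation = insulation, compartments = compartments,
    enrichment = list(loops_touching = loop_enrich,
                      expression = expr_enrich,
                      same_tad = eq$same_tad_enrichment),
    expression_fold = fold,
    eqtl = list(records = eq$records, summary = eq_sum,
                welch = eq$welch_tests),
    gwas = list(links = links, summary = gwas_sum)),
    class = "chromhub_report")
}

#' @export
print.chromhub_report <- function(x, ...) {
  cat("<chromhub_report>\n")
  for (nm in names(x$counts)) cat(sprintf("  %s: %s\n", nm, x$counts[[nm]]))
  invisible(x)
}

#' Serialize a run report to JSON
#'
#' Writes the counts, enrichment statistics and per-class summaries (not
#' the full per-record tables) as a JSON run report.
#'
#' @param report A `chromhub_report`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  enr <- lapply(report$enrichment, function(e) {
    if (is.null(e)) return(NULL)
    as.list(tidy(e))
  })
  out <- list(
    params = report$params, seed = report$seed, counts = report$counts,
    enrichment = enr,
    expression_fold = report$expression_fold[c("fold", "n_a", "n_b")],
    se_groups = as.list(table(report$tad_groups$group)),
    eqtl_loop_class = stats::setNames(as.list(report$eqtl$summary$loop_class$n),
                                      report$eqtl$summary$loop_class$loop_class),
    gwas_per_disease = report$gwas$summary$per_disease)
  jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
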
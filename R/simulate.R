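#' Configuration for the synthetic genome generator
#'
#' Defines the study conditions the generator emulates: a toy genome
#' (default two 10 Mb chromosomes binned at 5 kb) with planted TADs in
#' contiguous runs, A/B compartment blocks, chromatin loops, clustered
#' H3K27Ac constituents forming super-enhancers, genes with SE-boosted
#' expression, eQTLs planted in every topological class, and GWAS lead/LD
#' variants with loop-linked and loop-free (control) loci. Every planted
#' entity carries a machine-readable truth label.
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param bin_size Contact-matrix bin size (bp).
#' @param track_bin Signal-track bin size (bp).
#' @param tad_lengths TAD lengths sampled from (bp; multiples of 100 kb,
#'   mean 800 kb by default).
#' @param tads_per_run TADs per contiguous run (boundaries within a run are
#'   shared, giving well-defined insulation minima).
#' @param inter_run_gaps Unorganized gap lengths between runs (bp).
#' @param margin Chromosome-end margin left unorganized (bp).
#' @param decay_exponent Contact distance-decay power-law exponent.
#' @param base_level Expected contact count at zero separation.
#' @param tad_factor Intra-TAD contact enrichment.
#' @param compartment_factor Same-compartment contact enrichment.
#' @param loop_factor Contact enrichment at planted loop anchor pairs.
#' @param noise Count noise law (`poisson` or `nbinom`).
#' @param nb_size Negative-binomial size when `noise = "nbinom"`.
#' @param gene_spacing,gene_jitter,gene_length_range Gene layout (bp).
#' @param expression_meanlog,expression_sdlog Log-normal expression law.
#' @param se_boost Multiplicative expression boost of SE-hosted genes.
#' @param b_expression_factor Expression attenuation of B-compartment genes.
#' @param n_se Number of planted super-enhancers.
#' @param se_n_constituents,se_constituent_length,se_gap SE cluster layout.
#' @param frac_edge_se Fraction of SEs planted at TAD edges (< 5 kb).
#' @param edge_offset Distance of edge SEs from the TAD boundary (bp).
#' @param n_typical_enhancers Isolated typical enhancers.
#' @param enhancer_rate_range Typical-enhancer H3K27Ac rate range (per bp).
#' @param se_rate,promoter_rate,background_rate,control_rate H3K27Ac rates
#'   (per bp) of SE constituents, promoter states, background, and input.
#' @param loops_enabled Plant loops at all (disable for degenerate tests).
#' @param n_generic_loops_per_tad Generic intra-TAD loops per TAD.
#' @param eqtl_n_per_class Variants per planted loop-taxonomy class
#'   (eGene pieQTL, non-eGene pieQTL, eQTL-only, not-on-loop) and per
#'   promoter class.
#' @param eqtl_n_se,eqtl_n_cre Variants planted inside SEs / CREs.
#' @param same_tad_target Overall planted variant-eGene same-TAD fraction.
#' @param gwas_ld_per_locus LD variants per GWAS locus.
#' @param make_matrix Generate the contact matrices (disable for speed when
#'   only annotation layers are needed).
#' @return A config list (class `synthetic_config`).
#' @export
synthetic_config <- function(chrom_lengths = c(chr1 = 10e6, chr2 = 10e6),
                             bin_size = 5000,
                             track_bin = 100,
                             tad_lengths = seq(5e5, 1.1e6, by = 1e5),
                             tads_per_run = 3:5,
                             inter_run_gaps = c(8e5, 1e6),
                             margin = 2e5,
                             decay_exponent = 1.0,
                             base_level = 50,
                             tad_factor = 3,
                             compartment_factor = 1.5,
                             loop_factor = 4,
                             noise = c("poisson", "nbinom"),
                             nb_size = 10,
                             gene_spacing = 45000,
                             gene_jitter = 25000,
                             gene_length_range = c(5e3, 15e3),
                             expression_meanlog = 2,
                             expression_sdlog = 0.4,
                             se_boost = 2.0,
                             b_expression_factor = 0.3,
                             n_se = 20,
                             se_n_constituents = 4,
                             se_constituent_length = 1500,
                             se_gap = 7000,
                             frac_edge_se = 0.2,
                             edge_offset = 2000,
                             n_typical_enhancers = 80,
                             enhancer_rate_range = c(2, 8),
                             se_rate = 20,
                             promoter_rate = 12,
                             background_rate = 1,
                             control_rate = 1,
                             loops_enabled = TRUE,
                             n_generic_loops_per_tad = 2,
                             eqtl_n_per_class = 25,
                             eqtl_n_se = 15,
                             eqtl_n_cre = 15,
                             same_tad_target = 0.7,
                             gwas_ld_per_locus = 20,
                             make_matrix = TRUE) {
  cfg <- as.list(environment())
  cfg$noise <- match.arg(noise)
  structure(cfg, class = "synthetic_config")
}

# -- registry of occupied matrix bins (loop feet) -----------------------------
reg_new <- function() new.env(parent = emptyenv())
reg_has <- function(reg, chrom, bin) {
  v <- reg[[chrom]]
  !is.null(v) && bin %in% v
}
reg_add <- function(reg, chrom, bins) {
  reg[[chrom]] <- unique(c(reg[[chrom]], bins))
  invisible(reg)
}

bin_interval <- function(chrom, bin, bs) {
  tibble(chrom = chrom, start = bin * bs, end = (bin + 1) * bs)
}

overlaps_tbl <- function(chrom, start, end, tbl) {
  if (is.null(tbl) || nrow(tbl) == 0) return(FALSE)
  any(tbl$chrom == chrom & tbl$start < end & tbl$end > start)
}

#' Generate the synthetic bundle
#'
#' Emits every derived product the pipeline consumes - contact matrices
#' with distance decay and planted TAD/compartment/loop structure, H3K27Ac
#' case/input tracks with clustered SE constituents, a chromatin-state
#' segmentation consistent with the signal, a gene/TSS/expression table
#' with SE-boosted genes, TAD and loop truth files, eQTLs planted in each
#' topological class, and GWAS lead/LD variants with loop-linked and
#' control loci - together with a `truth` list of planted labels. Fully
#' deterministic under the seed, with independent sub-seeds per component.
#'
#' @param config A [synthetic_config()].
#' @param seed Master RNG seed (mandatory).
#' @return A bundle list (class `synthetic_bundle`) with elements `build`,
#'   `tads`, `compartments`, `genes`, `states`, `cres` implied by states,
#'   `case_track`, `control_track`, `loops`, `eqtls`, `lead_variants`,
#'   `ld_variants`, `matrices`, `truth`, `config`, `seed`.
#' @export
simulate_bundle <- function(config = synthetic_config(), seed) {
  if (missing(seed)) abort("a master seed is required")
  cfg <- config
  build <- genome_build(cfg$chrom_lengths)
  bs <- cfg$bin_size

  if (!cfg$loops_enabled && (cfg$eqtl_n_per_class > 0)) {
    abort(paste0("cannot plant promoter-interacting eQTL classes without ",
                 "loops; set eqtl_n_per_class = 0 or enable loops"))
  }

  # ---- TAD layout: contiguous runs separated by unorganized gaps ----------
  tads <- with_seed_(sub_seed(seed, 1), {
    out <- list(); bnd <- list()
    for (ch in build$chrom) {
      len <- chrom_lengths(build)[[ch]]
      cursor <- cfg$margin
      repeat {
        k <- sample(cfg$tads_per_run, 1)
        placed <- 0L
        for (j in seq_len(k)) {
          tl <- sample(cfg$tad_lengths, 1)
          if (cursor + tl > len - cfg$margin) break
          out[[length(out) + 1L]] <- tibble(chrom = ch, start = cursor,
                                            end = cursor + tl)
          if (placed > 0L) {
            bnd[[length(bnd) + 1L]] <- tibble(chrom = ch, pos = cursor)
          }
          cursor <- cursor + tl
          placed <- placed + 1L
        }
        if (placed < k) break
        cursor <- cursor + sample(cfg$inter_run_gaps, 1)
        if (cursor >= len - cfg$margin - min(cfg$tad_lengths)) break
      }
    }
    list(tads = bind_rows(out), boundaries = bind_rows(bnd))
  })
  shared_boundaries <- tads$boundaries
  tads <- tads$tads

  # ---- compartment labels per TAD; segments tile each chromosome ----------
  comp <- with_seed_(sub_seed(seed, 2), {
    lab <- character(nrow(tads))
    for (ch in build$chrom) {
      idx <- which(tads$chrom == ch)
      cur <- sample(c("A", "B"), 1)
      i <- 1
      while (i <= length(idx)) {
        run <- min(sample(1:2, 1), length(idx) - i + 1)
        lab[idx[i:(i + run - 1)]] <- cur
        cur <- if (cur == "A") "B" else "A"
        i <- i + run
      }
      # guarantee both labels on every chromosome
      if (length(unique(lab[idx])) == 1 && length(idx) > 1) {
        lab[idx[length(idx)]] <- setdiff(c("A", "B"), lab[idx[1]])
      }
    }
    lab
  })
  tads$label <- comp
  segments <- local({
    segs <- list()
    for (ch in build$chrom) {
      len <- chrom_lengths(build)[[ch]]
      ti <- tads[tads$chrom == ch, ]
      brk <- 0; labs <- character(); cur_lab <- ti$label[1]
      cuts <- numeric()
      if (nrow(ti) > 1) {
        for (i in 2:nrow(ti)) {
          if (ti$label[i] != cur_lab) {
            # change point: shared boundary or gap midpoint
            cut <- if (ti$start[i] == ti$end[i - 1]) ti$start[i] else
              (ti$end[i - 1] + ti$start[i]) / 2
            cuts <- c(cuts, cut); labs <- c(labs, cur_lab)
            cur_lab <- ti$label[i]
          }
        }
      }
      starts <- c(0, cuts); ends <- c(cuts, len); labs <- c(labs, cur_lab)
      segs[[length(segs) + 1L]] <- tibble(chrom = ch, start = starts,
                                          end = ends, label = labs)
    }
    bind_rows(segs)
  })

  # ---- super-enhancers and SE-hosted genes (placed before regular genes,
  # which are laid out around them) ----------------------------------------
  se_span <- cfg$se_n_constituents * cfg$se_constituent_length +
    (cfg$se_n_constituents - 1) * cfg$se_gap
  placed <- with_seed_(sub_seed(seed, 4), {
    a_tads <- which(tads$label == "A")
    if (!length(a_tads)) abort("no A-compartment TADs to host SEs")
    n_edge <- round(cfg$n_se * cfg$frac_edge_se)
    ses <- list(); se_genes <- list()
    make_se <- function(ch, s, tad_i, pos_class, k) {
      cons <- tibble(
        chrom = ch,
        start = s + (seq_len(cfg$se_n_constituents) - 1) *
          (cfg$se_constituent_length + cfg$se_gap),
        end = s + (seq_len(cfg$se_n_constituents) - 1) *
          (cfg$se_constituent_length + cfg$se_gap) + cfg$se_constituent_length)
      list(se = tibble(se_id = sprintf("SE%03d", k), chrom = ch, start = s,
                       end = s + se_span, host_tad = tad_i,
                       position_class = pos_class),
           constituents = cons)
    }
    k <- 0L
    se_spans_so_far <- function() {
      if (length(ses)) bind_rows(lapply(ses, `[[`, "se"))
    }
    slot_free <- function(ch, cand) {
      !overlaps_tbl(ch, cand - 15000, cand + se_span + 15000,
                    se_spans_so_far())
    }
    order_t <- rep(a_tads, length.out = cfg$n_se * 8)
    use_end <- FALSE
    for (tad_i in order_t) {
      if (k >= cfg$n_se) break
      ch <- tads$chrom[tad_i]
      want_edge <- k < n_edge
      cand <- NA
      if (want_edge) {
        c_start <- tads$start[tad_i] + cfg$edge_offset
        c_end <- tads$end[tad_i] - cfg$edge_offset - se_span
        cands <- if (use_end) c(c_end, c_start) else c(c_start, c_end)
        for (cc in cands) if (slot_free(ch, cc)) { cand <- cc; break }
        use_end <- !use_end
      } else {
        lo <- tads$start[tad_i] + 20000
        hi <- tads$end[tad_i] - 20000 - se_span
        if (hi > lo) {
          grid <- seq(lo, hi, by = 2000)
          free <- grid[vapply(grid, function(cc) slot_free(ch, cc), logical(1))]
          if (length(free)) cand <- free[sample.int(length(free), 1)]
        }
      }
      if (is.na(cand)) next
      k <- k + 1L
      se <- make_se(ch, cand, tad_i, if (want_edge) "edge" else "non_edge", k)
      ses[[k]] <- se
      # two SE-hosted genes, TSS at the centres of internal gaps 1 and 3
      for (gi in c(1, 3)) {
        gap_start <- cand + gi * cfg$se_constituent_length + (gi - 1) * cfg$se_gap
        tss <- gap_start + cfg$se_gap / 2
        se_genes[[length(se_genes) + 1L]] <- tibble(
          gene_id = sprintf("GSE%03d", length(se_genes) + 1L),
          symbol = sprintf("SEG%03d_%d", k, gi),
          chrom = ch, strand = "+", start = tss, end = tss + 3000, tss = tss,
          compartment = "A", se_id = se$se$se_id)
      }
    }
    if (k < cfg$n_se) {
      abort("could not place all SEs; enlarge the genome or reduce n_se")
    }
    se_tbl <- bind_rows(lapply(ses, `[[`, "se"))
    cons_tbl <- bind_rows(lapply(seq_along(ses), function(i) {
      x <- ses[[i]]$constituents
      x$se_id <- ses[[i]]$se$se_id
      x
    }))
    list(se = se_tbl, constituents = cons_tbl,
         se_genes = bind_rows(se_genes))
  })
  se_truth <- placed$se
  constituents <- placed$constituents
  se_gene_tbl <- placed$se_genes
  se_gene_map <- se_gene_tbl[, c("gene_id", "se_id")]

  # ---- regular genes, laid out around the SE spans ------------------------
  genes <- with_seed_(sub_seed(seed, 3), {
    se_pad <- tibble(chrom = se_truth$chrom, start = se_truth$start - 3000,
                     end = se_truth$end + 3000)
    out <- list(); gid <- 0L
    for (ch in build$chrom) {
      len <- chrom_lengths(build)[[ch]]
      cursor <- 1e5
      while (TRUE) {
        glen <- round(runif(1, cfg$gene_length_range[1], cfg$gene_length_range[2]) / 100) * 100
        if (cursor + glen > len - 1e5) break
        hit <- se_pad$chrom == ch & se_pad$start < cursor + glen & se_pad$end > cursor
        if (any(hit)) {
          cursor <- max(se_pad$end[hit])
          next
        }
        gid <- gid + 1L
        strand <- sample(c("+", "-"), 1)
        out[[length(out) + 1L]] <- tibble(
          gene_id = sprintf("G%04d", gid), symbol = sprintf("GENE%04d", gid),
          chrom = ch, strand = strand, start = cursor, end = cursor + glen,
          tss = if (strand == "+") cursor else cursor + glen - 1)
        cursor <- cursor + glen + cfg$gene_spacing + round(runif(1, 0, cfg$gene_jitter))
      }
    }
    bind_rows(out)
  })
  seg_label_at <- function(chrom, pos) {
    hit <- segments$chrom == chrom & segments$start <= pos & pos < segments$end
    if (any(hit)) segments$label[which(hit)[1]] else NA_character_
  }
  genes$compartment <- vapply(seq_len(nrow(genes)), function(i) {
    seg_label_at(genes$chrom[i], genes$tss[i])
  }, character(1))

  # ---- typical enhancers: isolated, in A TADs, away from genes and SEs ----
  enhancers <- with_seed_(sub_seed(seed, 15), {
    occupied <- bind_rows(
      tibble(chrom = genes$chrom, start = genes$start - 3000,
             end = genes$end + 3000),
      tibble(chrom = se_truth$chrom, start = se_truth$start - 15000,
             end = se_truth$end + 15000))
    a_idx <- which(tads$label == "A")
    enh <- list(); tries <- 0L
    while (length(enh) < cfg$n_typical_enhancers && tries < 20000L) {
      tries <- tries + 1L
      ti <- if (length(a_idx) == 1) a_idx else sample(a_idx, 1)
      ch <- tads$chrom[ti]
      elen <- round(runif(1, 1000, 2000) / 10) * 10
      s <- round(runif(1, tads$start[ti] + 10000, tads$end[ti] - 10000 - elen))
      prev <- if (length(enh)) bind_rows(enh)
      if (overlaps_tbl(ch, s - 3000, s + elen + 3000, occupied)) next
      if (!is.null(prev) && overlaps_tbl(ch, s - 13000, s + elen + 13000, prev)) next
      enh[[length(enh) + 1L]] <- tibble(chrom = ch, start = s, end = s + elen,
                                        rate = runif(1, cfg$enhancer_rate_range[1],
                                                     cfg$enhancer_rate_range[2]))
    }
    bind_rows(enh)
  })
  genes <- bind_rows(genes, se_gene_tbl[, setdiff(names(se_gene_tbl), "se_id")])

  # ---- dedicated intronic CRE (shared-CRE GWAS mechanism) ----------------
  intronic_cre <- with_seed_(sub_seed(seed, 10), {
    cand <- which(genes$compartment == "A" & genes$strand == "+" &
                    genes$end - genes$start >= 8000 &
                    !genes$gene_id %in% se_gene_map$gene_id)
    ok <- NULL
    for (gi in sample(cand)) {
      s <- genes$start[gi] + 3000
      near_se <- overlaps_tbl(genes$chrom[gi], s - 20000, s + 21500,
                              se_truth)
      near_enh <- overlaps_tbl(genes$chrom[gi], s - 13000, s + 13000 + 1500,
                               enhancers)
      if (!near_se && !near_enh) { ok <- gi; break }
    }
    if (is.null(ok)) abort("no host gene found for the intronic CRE")
    tibble(chrom = genes$chrom[ok], start = genes$start[ok] + 3000,
           end = genes$start[ok] + 4500, host_gene = genes$gene_id[ok])
  })

  # ---- chromatin states ---------------------------------------------------
  states <- with_seed_(sub_seed(seed, 5), {
    a_genes <- genes[genes$compartment %in% "A", ]
    prom <- tibble(chrom = a_genes$chrom, start = pmax(a_genes$tss - 500, 0),
                   end = a_genes$tss + 500, state = "promoter")
    cons_states <- tibble(chrom = constituents$chrom,
                          start = constituents$start, end = constituents$end,
                          state = sample(paste0("enhancer_", 1:5),
                                         nrow(constituents), replace = TRUE))
    enh_states <- tibble(chrom = enhancers$chrom, start = enhancers$start,
                         end = enhancers$end,
                         state = sample(paste0("enhancer_", 1:5),
                                        nrow(enhancers), replace = TRUE))
    icre_state <- tibble(chrom = intronic_cre$chrom, start = intronic_cre$start,
                         end = intronic_cre$end, state = "enhancer_1")
    het <- tads[tads$label == "B", c("chrom", "start", "end")]
    het$state <- "heterochromatin"
    bind_rows(prom, cons_states, enh_states, icre_state, het)
  })

  # ---- H3K27Ac case / control tracks --------------------------------------
  tracks <- with_seed_(sub_seed(seed, 6), {
    rate_case <- signal_track(build, cfg$track_bin)
    for (ch in build$chrom) {
      n <- length(rate_case$values[[ch]])
      rate_case$values[[ch]] <- rep(cfg$background_rate, n)
    }
    add_feature <- function(tr, tbl, rates) {
      for (ch in unique(tbl$chrom)) {
        sel <- tbl$chrom == ch
        tr <- track_add(tr, ch, tbl$start[sel], tbl$end[sel], rates[sel])
      }
      tr
    }
    a_genes <- genes[genes$compartment %in% "A", ]
    rate_case <- add_feature(rate_case,
                             tibble(chrom = a_genes$chrom,
                                    start = pmax(a_genes$tss - 500, 0),
                                    end = a_genes$tss + 500),
                             rep(cfg$promoter_rate, nrow(a_genes)))
    rate_case <- add_feature(rate_case, constituents,
                             rep(cfg$se_rate, nrow(constituents)))
    rate_case <- add_feature(rate_case, enhancers, enhancers$rate)
    rate_case <- add_feature(rate_case, intronic_cre,
                             rep(mean(cfg$enhancer_rate_range), nrow(intronic_cre)))
    case <- rate_case; ctrl <- signal_track(build, cfg$track_bin)
    for (ch in build$chrom) {
      lam <- rate_case$values[[ch]] * cfg$track_bin
      case$values[[ch]] <- rpois(length(lam), lam) / cfg$track_bin
      ctrl$values[[ch]] <- rpois(length(lam),
                                 cfg$control_rate * cfg$track_bin) / cfg$track_bin
    }
    list(case = case, control = ctrl)
  })

  # ---- loops (generic + SE), registry of occupied foot bins ---------------
  reg <- reg_new()
  loop_rows <- list()
  add_loop <- function(ch, binA, binB) {
    loop_rows[[length(loop_rows) + 1L]] <<- tibble(
      chrom = ch, startA = binA * bs, endA = (binA + 1) * bs,
      startB = binB * bs, endB = (binB + 1) * bs)
    reg_add(reg, ch, c(binA, binB))
  }
  if (cfg$loops_enabled) {
    with_seed_(sub_seed(seed, 7), {
      for (ti in seq_len(nrow(tads))) {
        ch <- tads$chrom[ti]
        b0 <- tads$start[ti] / bs; b1 <- tads$end[ti] / bs - 1
        for (j in seq_len(cfg$n_generic_loops_per_tad)) {
          repeat {
            bb <- sort(sample(b0:b1, 2))
            if (bb[2] - bb[1] >= 6) break
          }
          add_loop(ch, bb[1], bb[2])
        }
      }
      for (si in seq_len(nrow(se_truth))) {
        ch <- se_truth$chrom[si]
        ti <- se_truth$host_tad[si]
        binA <- floor(constituents$start[constituents$se_id == se_truth$se_id[si]][1] / bs)
        b0 <- tads$start[ti] / bs; b1 <- tads$end[ti] / bs - 1
        cand <- setdiff(b0:b1, (binA - 3):(binA + 3))
        binB <- sample(cand, 1)
        add_loop(ch, binA, binB)
      }
    })
  }

  # ---- eQTL planting ------------------------------------------------------
  prom_windows <- promoter_regions(genes, 2500, build)
  avoid_none <- bind_rows(
    se_truth[, c("chrom", "start", "end")],
    enhancers[, c("chrom", "start", "end")],
    intronic_cre[, c("chrom", "start", "end")],
    tibble(chrom = genes$chrom[genes$compartment %in% "A"],
           start = pmax(genes$tss[genes$compartment %in% "A"] - 600, 0),
           end = genes$tss[genes$compartment %in% "A"] + 600))
  tad_of_pos <- function(ch, pos) {
    hit <- which(tads$chrom == ch & tads$start <= pos & pos < tads$end)
    if (length(hit)) hit[1] else NA_integer_
  }
  eqtl <- with_seed_(sub_seed(seed, 8), {
    n_cls <- cfg$eqtl_n_per_class
    pool <- genes$gene_id[!genes$gene_id %in% se_gene_map$gene_id]
    picks <- sample(pool, 4 * n_cls + cfg$eqtl_n_cre)
    g_epi <- picks[seq_len(n_cls)]
    g_npi <- picks[n_cls + seq_len(n_cls)]
    g_only <- picks[2 * n_cls + seq_len(n_cls)]
    g_nol <- picks[3 * n_cls + seq_len(n_cls)]
    g_cre <- picks[4 * n_cls + seq_len(cfg$eqtl_n_cre)]
    # separate uniform draw for the promoter class
    g_prom <- sample(setdiff(pool, picks), n_cls)
    rows <- list(); truths <- list(); vid <- 0L
    lens <- chrom_lengths(build)
    fresh_bin <- function(ch, want_tad = NULL, forbid_tad = NA) {
      # a bin not used by any loop foot, outside regulatory regions
      for (try in 1:500) {
        b <- if (!is.null(want_tad)) {
          sample((tads$start[want_tad] / bs):(tads$end[want_tad] / bs - 1), 1)
        } else {
          sample(0:(lens[[ch]] / bs - 1), 1)
        }
        if (!is.na(forbid_tad)) {
          t_here <- tad_of_pos(ch, b * bs + bs / 2)
          if (!is.na(t_here) && t_here == forbid_tad) next
        }
        if (reg_has(reg, ch, b)) next
        if (overlaps_tbl(ch, b * bs, (b + 1) * bs, avoid_none)) next
        return(b)
      }
      abort("could not find a fresh bin for eQTL planting")
    }
    plant <- function(gene_id, loop_class, position_class, regulatory_class,
                      pos, same_tad, chrom = NULL,
                      overlaps_egene = regulatory_class == "SE") {
      vid <<- vid + 1L
      gi <- match(gene_id, genes$gene_id)
      ch <- chrom %||% genes$chrom[gi]
      # reserve the variant's bin so no later loop foot can land on it
      reg_add(reg, ch, floor(pos / bs))
      rows[[vid]] <<- tibble(variant_id = sprintf("var_%04d", vid),
                             chrom = ch, pos = pos,
                             egene_id = gene_id)
      truths[[vid]] <<- tibble(variant_id = sprintf("var_%04d", vid),
                               loop_class = loop_class,
                               position_class = position_class,
                               regulatory_class = regulatory_class,
                               same_tad = same_tad,
                               region_overlaps_egene = overlaps_egene)
    }
    # eGene pieQTLs: dedicated loop from a fresh bin to the eGene TSS bin
    for (g in g_epi) {
      gi <- match(g, genes$gene_id)
      ch <- genes$chrom[gi]
      tss_bin <- floor(genes$tss[gi] / bs)
      g_tad <- tad_of_pos(ch, genes$tss[gi])
      fa <- if (!is.na(g_tad)) fresh_bin(ch, want_tad = g_tad) else fresh_bin(ch)
      while (abs(fa - tss_bin) < 3) {
        fa <- if (!is.na(g_tad)) fresh_bin(ch, want_tad = g_tad) else fresh_bin(ch)
      }
      add_loop(ch, min(fa, tss_bin), max(fa, tss_bin))
      pos <- fa * bs + bs / 2
      plant(g, "egene_pieqtl", "distal", "none", pos,
            !is.na(g_tad) && identical(tad_of_pos(ch, pos), g_tad))
    }
    # non-eGene pieQTLs: loop to another gene's TSS bin, away from the eGene
    for (g in g_npi) {
      gi <- match(g, genes$gene_id)
      ch <- genes$chrom[gi]
      g_tad <- tad_of_pos(ch, genes$tss[gi])
      others <- which(genes$chrom == ch &
                        abs(genes$tss - genes$tss[gi]) > 20000 &
                        genes$gene_id != g)
      o <- others[sample.int(length(others), 1)]
      tss_bin <- floor(genes$tss[o] / bs)
      fa <- if (!is.na(g_tad)) fresh_bin(ch, want_tad = g_tad) else fresh_bin(ch)
      while (abs(fa - tss_bin) < 3 || abs(fa * bs + bs / 2 - genes$tss[gi]) <= 3000) {
        fa <- if (!is.na(g_tad)) fresh_bin(ch, want_tad = g_tad) else fresh_bin(ch)
      }
      add_loop(ch, min(fa, tss_bin), max(fa, tss_bin))
      pos <- fa * bs + bs / 2
      plant(g, "non_egene_pieqtl", "distal", "none", pos,
            !is.na(g_tad) && identical(tad_of_pos(ch, pos), g_tad))
    }
    # promoter eQTLs (variant within +/-2.5 kb of the eGene TSS)
    try_promoter_pos <- function(gi) {
      ch <- genes$chrom[gi]
      for (try in 1:100) {
        delta <- sample(c(-1, 1), 1) * round(runif(1, 700, 2400))
        cand <- genes$tss[gi] + delta
        if (cand < 0 || cand >= lens[[ch]]) next
        if (reg_has(reg, ch, floor(cand / bs))) next
        # outside every regulatory element (the +/-600 promoter-state pad
        # keeps the variant out of the promoter CRE while inside +/-2.5 kb)
        if (overlaps_tbl(ch, cand, cand + 1, avoid_none)) next
        return(cand)
      }
      NA
    }
    spares <- sample(setdiff(pool, c(picks, g_prom)))
    for (g in g_prom) {
      gi <- match(g, genes$gene_id)
      pos <- try_promoter_pos(gi)
      while (is.na(pos)) {
        if (!length(spares)) abort("could not place a promoter eQTL variant")
        g <- spares[1]; spares <- spares[-1]
        gi <- match(g, genes$gene_id)
        pos <- try_promoter_pos(gi)
      }
      ch <- genes$chrom[gi]
      g_tad <- tad_of_pos(ch, genes$tss[gi])
      plant(g, "not_on_loop", "promoter", "none", pos,
            !is.na(g_tad) && identical(tad_of_pos(ch, pos), g_tad))
    }
    # SE-overlapping eQTLs: variant in the central SE gap, eGene = hosted gene
    se_pick <- sample(se_truth$se_id, cfg$eqtl_n_se)
    for (sid in se_pick) {
      se <- se_truth[se_truth$se_id == sid, ]
      ch <- se$chrom
      gap2_start <- se$start + 2 * cfg$se_constituent_length + cfg$se_gap
      center <- gap2_start + cfg$se_gap / 2
      pos <- NA
      for (delta in c(0, 500, -500, 1000, -1000)) {
        cand <- center + delta
        if (!reg_has(reg, ch, floor(cand / bs))) { pos <- cand; break }
      }
      if (is.na(pos)) next
      host_gene <- se_gene_map$gene_id[se_gene_map$se_id == sid][1]
      plant(host_gene, "not_on_loop", "distal", "SE", pos, TRUE, chrom = ch)
    }
    # CRE-overlapping eQTLs: variant inside an isolated typical enhancer
    enh_order <- sample(seq_len(nrow(enhancers)))
    n_planted_cre <- 0L
    for (e in enh_order) {
      if (n_planted_cre >= cfg$eqtl_n_cre) break
      ch <- enhancers$chrom[e]
      pos <- floor((enhancers$start[e] + enhancers$end[e]) / 2)
      if (reg_has(reg, ch, floor(pos / bs))) next
      n_planted_cre <- n_planted_cre + 1L
      g <- g_cre[n_planted_cre]
      gi <- match(g, genes$gene_id)
      if (genes$chrom[gi] == ch && abs(pos - genes$tss[gi]) <= 2500) {
        # freak proximity: keep the variant distal by swapping eGene
        g <- sample(setdiff(c(g_epi, g_nol), g), 1)
        gi <- match(g, genes$gene_id)
      }
      g_tad <- if (genes$chrom[gi] == ch) tad_of_pos(ch, genes$tss[gi]) else NA
      same <- !is.na(g_tad) && identical(tad_of_pos(ch, pos), g_tad)
      plant(g, "not_on_loop", "distal", "CRE", pos, same, chrom = ch)
    }
    # promoter-CRE eQTLs: variant inside the eGene's promoter-state CRE,
    # giving the promoter stratum of the H3K27Ac context comparison
    g_pcre <- sample(setdiff(genes$gene_id[genes$compartment %in% "A" &
                                             !genes$gene_id %in% se_gene_map$gene_id],
                             c(picks, g_prom)), 10)
    for (g in g_pcre) {
      gi <- match(g, genes$gene_id)
      ch <- genes$chrom[gi]
      pos <- NA
      for (delta in c(300, -300, 450, -450, 150)) {
        cand <- genes$tss[gi] + delta
        if (cand < 0 || cand >= lens[[ch]]) next
        if (reg_has(reg, ch, floor(cand / bs))) next
        pos <- cand; break
      }
      if (is.na(pos)) next
      g_tad <- tad_of_pos(ch, genes$tss[gi])
      plant(g, "not_on_loop", "promoter", "CRE", pos,
            !is.na(g_tad) && identical(tad_of_pos(ch, pos), g_tad),
            overlaps_egene = TRUE)
    }
    # now top up same-TAD with the freely placeable classes
    total_planned <- vid + length(g_only) + length(g_nol)
    target_same <- round(cfg$same_tad_target * total_planned)
    realized_same <- sum(vapply(truths, function(t) t$same_tad, logical(1)))
    need <- target_same - realized_same
    in_tad <- function(g) {
      gi <- match(g, genes$gene_id)
      !is.na(tad_of_pos(genes$chrom[gi], genes$tss[gi]))
    }
    free_genes <- c(g_only, g_nol)
    free_class <- rep(c("eqtl_only", "not_on_loop"), c(length(g_only), length(g_nol)))
    can_true <- vapply(free_genes, in_tad, logical(1))
    want_true <- rep(FALSE, length(free_genes))
    idx_true <- which(can_true)
    if (need > 0) want_true[head(idx_true, need)] <- TRUE
    for (i in seq_along(free_genes)) {
      g <- free_genes[i]
      gi <- match(g, genes$gene_id)
      ch <- genes$chrom[gi]
      g_tad <- tad_of_pos(ch, genes$tss[gi])
      want <- want_true[i]
      if (free_class[i] == "eqtl_only") {
        fa <- if (want) fresh_bin(ch, want_tad = g_tad) else
          fresh_bin(ch, forbid_tad = if (!is.na(g_tad)) g_tad else NA)
        while (abs(fa * bs + bs / 2 - genes$tss[gi]) <= 3000) {
          fa <- if (want) fresh_bin(ch, want_tad = g_tad) else
            fresh_bin(ch, forbid_tad = if (!is.na(g_tad)) g_tad else NA)
        }
        # opposite foot: fresh bin clear of every promoter window
        fb <- NA
        for (try in 1:500) {
          cand <- fresh_bin(ch)
          pw <- prom_windows[prom_windows$chrom == ch, ]
          if (!any(pw$start < (cand + 1) * bs & pw$end > cand * bs) &&
              abs(cand - fa) >= 3) { fb <- cand; break }
        }
        if (is.na(fb)) abort("could not place an eQTL-only opposite foot")
        add_loop(ch, min(fa, fb), max(fa, fb))
        pos <- fa * bs + bs / 2
        plant(g, "eqtl_only", "distal", "none", pos,
              want && !is.na(g_tad))
      } else {
        b <- if (want) fresh_bin(ch, want_tad = g_tad) else
          fresh_bin(ch, forbid_tad = if (!is.na(g_tad)) g_tad else NA)
        while (abs(b * bs + bs / 2 - genes$tss[gi]) <= 3000) {
          b <- if (want) fresh_bin(ch, want_tad = g_tad) else
            fresh_bin(ch, forbid_tad = if (!is.na(g_tad)) g_tad else NA)
        }
        pos <- b * bs + bs / 2
        plant(g, "not_on_loop", "distal", "none", pos, want && !is.na(g_tad))
      }
    }
    list(records = bind_rows(rows), truth = bind_rows(truths))
  })
  eqtls <- eqtl$records
  eqtl_truth <- eqtl$truth

  # ---- disease tags inherited from eGene set labels -----------------------
  genes$set_labels <- ""
  tagged <- with_seed_(sub_seed(seed, 9), {
    egene_pool <- unique(eqtls$egene_id)
    tag_sets <- list(retinopathy = 20, `AMD-locus` = 8, `glaucoma-locus` = 8)
    taken <- character()
    out <- list()
    for (tg in names(tag_sets)) {
      avail <- setdiff(egene_pool, taken)
      n_pick <- min(tag_sets[[tg]], length(avail))
      if (n_pick == 0) next
      pick <- avail[sample.int(length(avail), n_pick)]
      taken <- c(taken, pick)
      out[[tg]] <- pick
    }
    out
  })
  for (tg in names(tagged)) {
    gi <- match(tagged[[tg]], genes$gene_id)
    genes$set_labels[gi] <- ifelse(genes$set_labels[gi] == "", tg,
                                   paste(genes$set_labels[gi], tg, sep = ","))
  }
  genes$set_labels[match(se_gene_map$gene_id, genes$gene_id)] <-
    ifelse(genes$set_labels[match(se_gene_map$gene_id, genes$gene_id)] == "",
           "retina-enriched",
           paste(genes$set_labels[match(se_gene_map$gene_id, genes$gene_id)],
                 "retina-enriched", sep = ","))
  eqtls$tags <- genes$set_labels[match(eqtls$egene_id, genes$gene_id)]

  # ---- GWAS loci ----------------------------------------------------------
  gwas <- with_seed_(sub_seed(seed, 11), {
    leads <- list(); lds <- list(); planted_links <- list()
    control_rsids <- character()
    rs_n <- 0L
    next_rsid <- function() { rs_n <<- rs_n + 1L; sprintf("rs%06d", rs_n) }
    lens <- chrom_lengths(build)
    fresh_variant_bin <- function(ch, region = NULL) {
      for (try in 1:1000) {
        b <- if (is.null(region)) sample(0:(lens[[ch]] / bs - 1), 1) else
          sample(floor(region[1] / bs):floor((region[2] - 1) / bs), 1)
        if (reg_has(reg, ch, b)) next
        if (overlaps_tbl(ch, b * bs, (b + 1) * bs, avoid_none)) next
        return(b)
      }
      abort("could not place a GWAS variant bin")
    }
    gene_links_of_foot <- function(ch, fs, fe) {
      sel <- genes$chrom == ch & genes$start < fe & genes$end > fs
      body_genes <- genes$gene_id[sel]
      tss_sel <- genes$chrom == ch & fs <= genes$tss & genes$tss < fe
      list(body = body_genes, tss = genes$gene_id[tss_sel])
    }
    ld_block <- function(lead_pos, ch, locus, disease, lead_rs, n, on_bin = NULL) {
      out <- list()
      n_linked <- if (is.null(on_bin)) 0L else 3L
      if (n_linked > 0) {
        offs <- c(-1500, -500, 1200)
        for (o in offs) {
          out[[length(out) + 1L]] <- tibble(
            rsid = next_rsid(), chrom = ch, pos = on_bin * bs + bs / 2 + o,
            lead_rsid = lead_rs, r2 = runif(1, 0.75, 1),
            maf = runif(1, 0.05, 0.4), disease = disease, locus = locus)
        }
      }
      while (length(out) < n) {
        cand <- lead_pos + round(runif(1, -150000, 150000))
        if (cand < 0 || cand >= lens[[ch]]) next
        b <- floor(cand / bs)
        if (reg_has(reg, ch, b)) next
        if (overlaps_tbl(ch, cand, cand + 1, avoid_none)) next
        reg_add(reg, ch, b)  # keep later loops off this variant
        out[[length(out) + 1L]] <- tibble(
          rsid = next_rsid(), chrom = ch, pos = cand, lead_rsid = lead_rs,
          r2 = runif(1, 0, 1), maf = runif(1, 0.001, 0.4),
          disease = disease, locus = locus)
      }
      bind_rows(out)
    }
    for (disease in c("AMD", "glaucoma")) {
      for (li in 1:4) {
        locus <- sprintf("%s_L%d", disease, li)
        if (li <= 2 && cfg$loops_enabled) {
          # loop locus: lead + 3 LD variants on a loop foot facing a gene
          tgt_pool <- which(!genes$gene_id %in% se_gene_map$gene_id)
          repeat {
            gi <- tgt_pool[sample.int(length(tgt_pool), 1)]
            ch <- genes$chrom[gi]
            fb <- if (li == 1) {
              floor((genes$start[gi] + genes$end[gi]) / 2 / bs)  # body foot
            } else {
              floor(genes$tss[gi] / bs)  # contains the TSS too
            }
            if (!reg_has(reg, ch, fb)) break
          }
          fa <- fresh_variant_bin(ch)
          while (abs(fa - fb) < 3) fa <- fresh_variant_bin(ch)
          add_loop(ch, min(fa, fb), max(fa, fb))
          lid <- length(loop_rows)  # loop index just added
          lead_rs <- next_rsid()
          lead_pos <- fa * bs + bs / 2
          leads[[length(leads) + 1L]] <- tibble(
            rsid = lead_rs, chrom = ch, pos = lead_pos, locus = locus,
            disease = disease)
          ld <- ld_block(lead_pos, ch, locus, disease, lead_rs,
                         cfg$gwas_ld_per_locus, on_bin = fa)
          lds[[length(lds) + 1L]] <- ld
          gl <- gene_links_of_foot(ch, fb * bs, (fb + 1) * bs)
          linked_rs <- c(lead_rs, ld$rsid[seq_len(3)])
          cls <- c("lead", rep("filtered_LD", 3))
          for (vi in seq_along(linked_rs)) {
            for (g in gl$body) {
              planted_links[[length(planted_links) + 1L]] <- tibble(
                rsid = linked_rs[vi], variant_class = cls[vi], gene_id = g,
                mechanism = "loop_to_body", loop_index = lid,
                disease = disease, locus = locus)
            }
            for (g in gl$tss) {
              planted_links[[length(planted_links) + 1L]] <- tibble(
                rsid = linked_rs[vi], variant_class = cls[vi], gene_id = g,
                mechanism = "loop_to_tss", loop_index = lid,
                disease = disease, locus = locus)
            }
          }
        } else if (li == 3) {
          # regulatory locus: AMD lead in an SE span, glaucoma lead in the
          # intronic CRE
          if (disease == "AMD") {
            lead_pos <- NA; sid <- NA; ch <- NA
            for (s_try in sample(se_truth$se_id)) {
              se <- se_truth[se_truth$se_id == s_try, ]
              gap1_start <- se$start + cfg$se_constituent_length
              for (off in c(1000, 200, 2500, 5500)) {
                cand <- gap1_start + off
                if (!reg_has(reg, se$chrom, floor(cand / bs))) {
                  lead_pos <- cand; sid <- s_try; ch <- se$chrom; break
                }
              }
              if (!is.na(lead_pos)) break
            }
            if (is.na(lead_pos)) abort("no SE slot for the regulatory GWAS lead")
            reg_add(reg, ch, floor(lead_pos / bs))
            lead_rs <- next_rsid()
            leads[[length(leads) + 1L]] <- tibble(
              rsid = lead_rs, chrom = ch, pos = lead_pos, locus = locus,
              disease = disease)
            for (g in se_gene_map$gene_id[se_gene_map$se_id == sid]) {
              planted_links[[length(planted_links) + 1L]] <- tibble(
                rsid = lead_rs, variant_class = "lead", gene_id = g,
                mechanism = "se_shared", loop_index = NA_integer_,
                disease = disease, locus = locus)
            }
            lds[[length(lds) + 1L]] <- ld_block(lead_pos, ch, locus, disease,
                                                lead_rs, cfg$gwas_ld_per_locus)
          } else {
            ch <- intronic_cre$chrom
            lead_pos <- floor((intronic_cre$start + intronic_cre$end) / 2)
            reg_add(reg, ch, floor(lead_pos / bs))
            lead_rs <- next_rsid()
            leads[[length(leads) + 1L]] <- tibble(
              rsid = lead_rs, chrom = ch, pos = lead_pos, locus = locus,
              disease = disease)
            planted_links[[length(planted_links) + 1L]] <- tibble(
              rsid = lead_rs, variant_class = "lead",
              gene_id = intronic_cre$host_gene,
              mechanism = "cre_shared", loop_index = NA_integer_,
              disease = disease, locus = locus)
            lds[[length(lds) + 1L]] <- ld_block(lead_pos, ch, locus, disease,
                                                lead_rs, cfg$gwas_ld_per_locus)
          }
        } else {
          # control locus: no variant touches any loop foot or element
          ch <- sample(build$chrom, 1)
          b <- fresh_variant_bin(ch)
          reg_add(reg, ch, b)
          lead_pos <- b * bs + bs / 2
          lead_rs <- next_rsid()
          leads[[length(leads) + 1L]] <- tibble(
            rsid = lead_rs, chrom = ch, pos = lead_pos, locus = locus,
            disease = disease)
          ld <- ld_block(lead_pos, ch, locus, disease, lead_rs,
                         cfg$gwas_ld_per_locus)
          lds[[length(lds) + 1L]] <- ld
          control_rsids <- c(control_rsids, lead_rs, ld$rsid)
        }
      }
    }
    list(leads = bind_rows(leads), lds = bind_rows(lds),
         links = bind_rows(planted_links), control_rsids = control_rsids)
  })

  loops <- if (length(loop_rows)) {
    lr <- bind_rows(loop_rows)
    loop_table(lr$chrom, lr$startA, lr$endA, lr$startB, lr$endB,
               qvalue = runif_det(nrow(lr), seed), build = build)
  } else {
    loop_table(character(), numeric(), numeric(), numeric(), numeric())
  }
  gwas_links <- gwas$links
  gwas_links$evidence <- ifelse(is.na(gwas_links$loop_index), NA_character_,
                                loops$loop_id[gwas_links$loop_index])

  # ---- expression ---------------------------------------------------------
  genes <- with_seed_(sub_seed(seed, 12), {
    base <- rlnorm(nrow(genes), cfg$expression_meanlog, cfg$expression_sdlog)
    base[genes$compartment %in% "B"] <-
      base[genes$compartment %in% "B"] * cfg$b_expression_factor
    boost <- genes$gene_id %in% se_gene_map$gene_id
    base[boost] <- base[boost] * cfg$se_boost
    genes$expression <- base
    genes
  })

  # ---- contact matrices ---------------------------------------------------
  matrices <- NULL
  if (cfg$make_matrix) {
    matrices <- with_seed_(sub_seed(seed, 13), {
      out <- list()
      for (ch in build$chrom) {
        n <- as.integer(chrom_lengths(build)[[ch]] / bs)
        bin_start <- (seq_len(n) - 1) * bs
        tid <- rep(NA_integer_, n)
        ti <- which(tads$chrom == ch)
        for (t in ti) {
          sel <- bin_start >= tads$start[t] & bin_start < tads$end[t]
          tid[sel] <- t
        }
        lab <- rep(NA_character_, n)
        si <- which(segments$chrom == ch)
        for (s in si) {
          sel <- bin_start >= segments$start[s] & bin_start < segments$end[s]
          lab[sel] <- segments$label[s]
        }
        D <- abs(outer(seq_len(n), seq_len(n), "-"))
        expmat <- cfg$base_level * (D + 1)^(-cfg$decay_exponent)
        sameT <- outer(tid, tid, function(a, b) !is.na(a) & !is.na(b) & a == b)
        expmat <- expmat * ifelse(sameT, cfg$tad_factor, 1)
        sameC <- outer(lab, lab, function(a, b) !is.na(a) & !is.na(b) & a == b)
        expmat <- expmat * ifelse(sameC, cfg$compartment_factor, 1)
        lsel <- which(loops$chrom == ch)
        for (l in lsel) {
          i <- loops$startA[l] / bs + 1; j <- loops$startB[l] / bs + 1
          expmat[i, j] <- expmat[i, j] * cfg$loop_factor
          expmat[j, i] <- expmat[i, j]
        }
        ut <- upper.tri(expmat, diag = TRUE)
        counts <- numeric(sum(ut))
        if (cfg$noise == "poisson") {
          counts <- rpois(sum(ut), expmat[ut])
        } else {
          counts <- stats::rnbinom(sum(ut), size = cfg$nb_size, mu = expmat[ut])
        }
        m <- matrix(0, n, n)
        m[ut] <- counts
        m <- m + t(m) - diag(diag(m))
        out[[ch]] <- contact_matrix(m, ch, bs, build = build,
                                    mask = rep(TRUE, n))
      }
      out
    })
  }

  cres_full <- merge_active_states(states)
  truth <- list(
    tads = tads,
    shared_boundaries = shared_boundaries,
    compartments = segments,
    se = se_truth,
    se_constituents = constituents,
    se_genes = se_gene_map,
    enhancers = enhancers,
    intronic_cre = intronic_cre,
    eqtls = eqtl_truth,
    same_tad_fraction = mean(eqtl_truth$same_tad),
    gwas_links = gwas_links,
    gwas_control_rsids = gwas$control_rsids,
    se_boost = cfg$se_boost
  )
  structure(list(config = cfg, seed = seed, build = build,
                 tads = tads[, c("chrom", "start", "end")],
                 compartments = segments,
                 genes = genes, states = states, cres = cres_full,
                 case_track = tracks$case, control_track = tracks$control,
                 loops = loops, eqtls = eqtls,
                 lead_variants = gwas$leads, ld_variants = gwas$lds,
                 matrices = matrices, truth = truth),
            class = "synthetic_bundle")
}

# deterministic per-loop q-values without disturbing component sub-streams
runif_det <- function(n, seed) {
  with_seed_(sub_seed(seed, 14), runif(n, 0, 0.01))
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_bundle: %d chrom, %d TADs, %d SEs, %d genes, ",
                     "%d loops, %d eQTLs, %d lead + %d LD variants%s>\n"),
              nrow(x$build), nrow(x$tads), nrow(x$truth$se), nrow(x$genes),
              nrow(x$loops), nrow(x$eqtls), nrow(x$lead_variants),
              nrow(x$ld_variants),
              if (is.null(x$matrices)) "" else ", matrices"))
  invisible(x)
}

#' Shuffle eQTL variant positions (null control)
#'
#' Re-samples every variant position uniformly over the genome (chromosome
#' chosen proportional to length) while keeping the eGene assignments: the
#' same-TAD proportion of the shuffled set should be statistically
#' indistinguishable from the random-TAD null.
#'
#' @param eqtls eQTL tibble.
#' @param build Genome build.
#' @param seed RNG seed.
#' @return The shuffled eQTL tibble.
#' @export
null_variant_shuffle <- function(eqtls, build, seed) {
  with_seed_(seed, {
    lens <- chrom_lengths(build)
    ci <- sample.int(nrow(build), nrow(eqtls), replace = TRUE,
                     prob = build$length / sum(build$length))
    eqtls$chrom <- build$chrom[ci]
    eqtls$pos <- floor(runif(nrow(eqtls), 0, lens[ci]))
    eqtls
  })
}

#' Write a synthetic bundle to disk
#'
#' Emits the standard-format files every module consumes: TAD and
#' compartment BED, chromatin-state BED, gene and eQTL TSV, GWAS lead/LD
#' TSV, loop BEDPE, case/control bedGraph, per-chromosome triplet contact
#' matrices and a `truth.json`.
#'
#' @param bundle A [simulate_bundle()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_bed(bundle$tads, fp("tads.bed"))
  comp <- bundle$compartments
  comp$name <- comp$label
  write_bed(comp[, c("chrom", "start", "end", "name")], fp("compartments.bed"))
  st <- bundle$states
  st$name <- st$state
  write_bed(st[, c("chrom", "start", "end", "name")], fp("states.bed"))
  write_genes(bundle$genes, fp("genes.tsv"))
  write_bedpe(bundle$loops, fp("loops.bedpe"))
  write_bedgraph(bundle$case_track, fp("h3k27ac_case.bedGraph"))
  write_bedgraph(bundle$control_track, fp("h3k27ac_control.bedGraph"))
  write_eqtls(bundle$eqtls, fp("eqtls.tsv"))
  write_variants(bundle$lead_variants, fp("gwas_lead.tsv"))
  write_variants(bundle$ld_variants, fp("gwas_ld.tsv"))
  if (!is.null(bundle$matrices)) {
    for (ch in names(bundle$matrices)) {
      write_contact_matrix(bundle$matrices[[ch]],
                           fp(sprintf("matrix_%s.txt", ch)))
    }
  }
  truth <- bundle$truth
  jsonlite::write_json(truth, fp("truth.json"), dataframe = "rows",
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Constructed two-genome fixture for conservation analysis
#'
#' Builds a deterministic pair of genomes with a one-to-one ortholog map in
#' which an exact, chosen fraction of species-B same-TAD gene pairs (and of
#' loop-connected gene pairs) is preserved in species A; the recovered
#' fractions from [gene_pair_conservation()] equal the planted values
#' exactly.
#'
#' @param n_pairs Number of species-B gene pairs (each pair in its own TAD
#'   and connected by one loop).
#' @param frac_tad Fraction of pairs whose orthologs share a TAD in A.
#' @param frac_loop Fraction of pairs loop-connected in A.
#' @return List with `a` and `b` topologies (`tads`, `loops`, `genes`),
#'   `map`, and the planted fractions.
#' @export
simulate_ortholog_fixture <- function(n_pairs = 10, frac_tad = 0.4,
                                      frac_loop = 0.4) {
  k_tad <- round(frac_tad * n_pairs)
  k_loop <- round(frac_loop * n_pairs)
  unit <- 2e5
  mk_genes <- function(prefix, n, chrom, offset, spacing) {
    starts <- offset + (seq_len(n) - 1) * spacing
    tibble(gene_id = sprintf("%s%03d", prefix, seq_len(n)),
           symbol = sprintf("%s%03d", prefix, seq_len(n)),
           chrom = chrom, strand = "+", start = starts, end = starts + 1e4,
           tss = starts, expression = 1)
  }
  # species B: pair i = genes (2i-1, 2i), both in TAD i, linked by loop i
  genes_b <- mk_genes("mg", 2 * n_pairs, "chrB", 5e4, unit / 2)
  tads_b <- tibble(chrom = "chrB",
                   start = 5e4 + (seq_len(n_pairs) - 1) * unit - 1e4,
                   end = 5e4 + (seq_len(n_pairs) - 1) * unit + unit / 2 + 2e4)
  loops_b <- loop_table("chrB",
                        genes_b$start[seq(1, 2 * n_pairs, 2)],
                        genes_b$start[seq(1, 2 * n_pairs, 2)] + 5e3,
                        genes_b$start[seq(2, 2 * n_pairs, 2)],
                        genes_b$start[seq(2, 2 * n_pairs, 2)] + 5e3)
  # species A: orthologs; first k pairs co-placed, the rest split far apart
  genes_a <- genes_b
  genes_a$gene_id <- sub("^mg", "hg", genes_b$gene_id)
  genes_a$symbol <- genes_a$gene_id
  genes_a$chrom <- "chrA"
  split <- seq_len(n_pairs) > k_tad
  # move the second gene of each split pair out of reach of any TAD
  second <- seq(2, 2 * n_pairs, 2)
  far <- 5e6 + seq_len(n_pairs) * 3e5
  genes_a$start[second[split]] <- far[split]
  genes_a$end[second[split]] <- far[split] + 1e4
  genes_a$tss[second[split]] <- far[split]
  tads_a <- tads_b
  tads_a$chrom <- "chrA"
  loops_keep <- seq_len(n_pairs) <= k_loop
  loops_a <- loop_table("chrA",
                        genes_a$start[seq(1, 2 * n_pairs, 2)][loops_keep],
                        genes_a$start[seq(1, 2 * n_pairs, 2)][loops_keep] + 5e3,
                        genes_a$start[second][loops_keep],
                        genes_a$start[second][loops_keep] + 5e3)
  map <- tibble(gene_b = genes_b$gene_id, gene_a = genes_a$gene_id)
  list(a = list(tads = tads_a, loops = loops_a, genes = genes_a),
       b = list(tads = tads_b, loops = loops_b, genes = genes_b),
       map = map, frac_tad = k_tad / n_pairs, frac_loop = k_loop / n_pairs)
}
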
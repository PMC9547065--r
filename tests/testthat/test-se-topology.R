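test_that("region placement classifies edge, non-edge, spanning and outside", {
  tads <- tibble::tibble(chrom = "c1", start = 100000, end = 500000)
  regions <- tibble::tibble(chrom = "c1",
                            start = c(100000, 200000, 490000, 600000),
                            end = c(120000, 220000, 520000, 620000))
  pl <- place_regions_in_tads(regions, tads, 5000)
  expect_equal(pl$position_class,
               c("edge", "non_edge", "spanning_boundary", "outside_tad"))
  expect_equal(pl$boundary_distance[1], 0)
  expect_equal(pl$boundary_distance[2], 100000)

  expect_error(place_regions_in_tads(
    regions, tibble::tibble(chrom = "c1", start = c(0, 100), end = c(200, 300)),
    5000), "overlap")
})

test_that("random placements match a brute-force containment oracle", {
  set.seed(51)
  tads <- tibble::tibble(chrom = rep(c("c1", "c2"), each = 5),
                         start = rep(seq(0, 8000, 2000), 2),
                         end = rep(seq(0, 8000, 2000), 2) + 1500)
  regions <- rand_intervals(500, max_len = 600)
  pl <- place_regions_in_tads(regions, tads, 100)
  for (i in seq_len(nrow(regions))) {
    host <- NA; cls <- "outside_tad"
    for (j in seq_len(nrow(tads))) {
      if (tads$chrom[j] != regions$chrom[i]) next
      if (regions$start[i] < tads$end[j] && tads$start[j] < regions$end[i]) {
        if (regions$start[i] >= tads$start[j] && regions$end[i] <= tads$end[j]) {
          host <- j
          d <- min(regions$start[i] - tads$start[j], tads$end[j] - regions$end[i])
          cls <- if (d < 100) "edge" else "non_edge"
        } else if (is.na(host)) cls <- "spanning_boundary"
      }
    }
    expect_equal(pl$position_class[i], cls)
    if (!is.na(host)) expect_equal(pl$host_tad[i], host)
  }
})

test_that("TAD classification requires full single-label compartment coverage", {
  tads <- tibble::tibble(chrom = "c1", start = c(0, 1000, 2000),
                         end = c(1000, 2000, 3000))
  comp <- tibble::tibble(chrom = "c1", start = c(0, 1500), end = c(1500, 3000),
                         label = c("A", "B"))
  se <- tibble::tibble(chrom = "c1", start = 10, end = 100)
  pl <- place_regions_in_tads(se, tads, 50)
  cls <- classify_tads(tads, comp, pl)
  expect_equal(cls$group, c("A_edge_SE", "unassigned", "B_compartment"))

  # no SEs: groups collapse but A/B assignment is unchanged
  cls0 <- classify_tads(tads, comp, pl[0, ])
  expect_equal(cls0$group, c("A_no_SE", "unassigned", "B_compartment"))
  expect_equal(cls0$compartment, cls$compartment)
})

test_that("planted TAD group memberships are recovered exactly on the bundle", {
  b <- default_bundle(matrices = FALSE)
  ses_truth <- b$truth$se
  pl <- place_regions_in_tads(
    tibble::tibble(region_id = ses_truth$se_id, chrom = ses_truth$chrom,
                   start = ses_truth$start, end = ses_truth$end),
    b$tads, 5000)
  # placement classes match the planted ones
  expect_equal(pl$position_class, ses_truth$position_class)
  expect_equal(pl$host_tad, ses_truth$host_tad)
  cls <- classify_tads(b$tads, b$compartments, pl)
  truth_tads <- b$truth$tads
  want <- ifelse(truth_tads$label == "B", "B_compartment", NA)
  hosted <- split(ses_truth$position_class, ses_truth$host_tad)
  for (i in which(truth_tads$label == "A")) {
    h <- hosted[[as.character(i)]]
    want[i] <- if (is.null(h)) "A_no_SE"
    else if (any(h == "edge")) "A_edge_SE" else "A_nonedge_SE"
  }
  expect_equal(cls$group, want)
})

test_that("per-TAD loop statistics equal the all-pairs oracle", {
  set.seed(52)
  tads <- tibble::tibble(chrom = "c1", start = seq(0, 8e5, 2e5),
                         end = seq(0, 8e5, 2e5) + 1.5e5)
  sa <- sample(seq(0, 9e5, 5000), 50)
  sb <- pmin(sa + sample(seq(2e4, 3e5, 5000), 50, replace = TRUE), 9.95e5)
  loops <- loop_table("c1", sa, sa + 5000, sb, sb + 5000)
  st <- tad_loop_stats(tads, loops)
  for (t in seq_len(nrow(tads))) {
    in_tad <- function(s, e) s < tads$end[t] && tads$start[t] < e
    touch <- c(); cross <- c()
    for (l in seq_len(nrow(loops))) {
      a <- in_tad(loops$startA[l], loops$endA[l])
      b <- in_tad(loops$startB[l], loops$endB[l])
      if (a || b) {
        touch <- c(touch, l)
        cross <- c(cross, xor(a, b))
      }
    }
    expect_equal(st$n_loops[t], length(touch))
    if (length(touch)) {
      expect_equal(st$mean_loop_size[t], mean(loop_sizes(loops)[touch]))
      expect_equal(st$pct_crossing[t], 100 * mean(cross))
    }
  }
})

test_that("region loop summary separates touching from fully-internal loops", {
  regions <- tibble::tibble(region_id = c("r1", "r2"), chrom = "c1",
                            start = c(0, 100000), end = c(50000, 150000))
  loops <- loop_table("c1",
                      startA = c(5000, 20000), endA = c(10000, 25000),
                      startB = c(30000, 110000), endB = c(35000, 115000))
  rs <- region_loop_summary(regions, loops)
  # loop 1 internal to r1; loop 2 straddles r1 and r2
  expect_equal(rs$per_region$n_touching, c(2L, 1L))
  expect_equal(rs$per_region$n_internal, c(1L, 0L))
  expect_equal(rs$n_loops_touching, 2)
  expect_equal(sort(rs$touching_sizes), sort(loop_sizes(loops)))
})

test_that("unique contacted features accumulate over distal feet only", {
  regions <- tibble::tibble(region_id = "se1", chrom = "c1",
                            start = 0, end = 10000)
  # one loop from the region to a distal foot holding 2 TSS and 1 CRE
  loops <- loop_table("c1", 2000, 7000, 50000, 55000)
  genes <- tibble::tibble(gene_id = c("g1", "g2", "g3"), symbol = "s",
                          chrom = "c1", strand = "+",
                          start = c(51000, 53000, 90000),
                          end = c(52000, 54000, 91000),
                          tss = c(51000, 53000, 90000))
  cres <- tibble::tibble(chrom = "c1", start = 52000, end = 52500)
  rc <- region_contact_features(regions, loops, cres, genes)
  expect_equal(rc$n_tss, 2)
  expect_equal(rc$n_cres, 1)
  expect_equal(rc$n_regions, 0)

  # a second loop reaching the same CRE adds nothing (uniqueness)
  loops2 <- loop_table("c1", c(2000, 3000), c(7000, 8000),
                       c(50000, 50000), c(55000, 55000))
  rc2 <- region_contact_features(regions, loops2, cres, genes)
  expect_equal(rc2$n_cres, 1)
})

test_that("boundary-crossing fraction hits its extremes and flags emptiness", {
  tads <- tibble::tibble(chrom = "c1", start = c(0, 2e5), end = c(2e5, 4e5))
  regions <- tibble::tibble(chrom = "c1", start = 10000, end = 20000)
  intra <- loop_table("c1", 10000, 15000, 100000, 105000)
  expect_equal(crossing_fraction(regions, intra, tads)$pct_crossing, 0)
  inter <- loop_table("c1", 10000, 15000, 300000, 305000)
  expect_equal(crossing_fraction(regions, inter, tads)$pct_crossing, 100)
  none <- loop_table("c1", 300000, 305000, 350000, 355000)
  cf <- crossing_fraction(regions, none, tads)
  expect_true(cf$flag)
  expect_true(is.na(cf$pct_crossing))
})

test_that("expression means and folds count genes once and handle exclusivity", {
  genes <- tibble::tibble(gene_id = c("a", "b", "c"), symbol = "s",
                          chrom = "c1", strand = "+",
                          start = c(100, 200, 300), end = c(150, 250, 350),
                          tss = c(100, 200, 300),
                          expression = c(10, 20, 5))
  ses <- tibble::tibble(chrom = "c1", start = c(90, 95), end = c(250, 260))
  cres <- tibble::tibble(chrom = "c1", start = 290, end = 310)
  # genes a,b in SEs (each once despite two overlapping regions), c in CREs
  f <- expression_fold(genes, ses, cres)
  expect_equal(f$fold, 3)
  expect_equal(f$n_a, 2)
  # identical region sets, non-exclusive -> fold 1
  f1 <- expression_fold(genes, ses, ses, exclusive = FALSE)
  expect_equal(f1$fold, 1)
  # empty comparison group -> flagged
  f2 <- expression_fold(genes, ses, ses, exclusive = TRUE)
  expect_true(f2$flag)
})

test_that("gene-set TSS overlap percentage hits its extremes", {
  genes <- tibble::tibble(gene_id = c("a", "b"), symbol = "s", chrom = "c1",
                          strand = "+", start = c(0, 100), end = c(50, 150),
                          tss = c(0, 100))
  all_cover <- tibble::tibble(chrom = "c1", start = 0, end = 200)
  expect_equal(geneset_tss_overlap_fraction(genes, all_cover), 100)
  none <- tibble::tibble(chrom = "c1", start = 500, end = 600)
  expect_equal(geneset_tss_overlap_fraction(genes, none), 0)
})

test_that("gene-pair conservation recovers identity, disjoint and planted fractions", {
  fx <- simulate_ortholog_fixture(n_pairs = 10, frac_tad = 1, frac_loop = 1)
  cs <- gene_pair_conservation(fx$a$tads, fx$a$loops, fx$a$genes,
                               fx$b$tads, fx$b$loops, fx$b$genes, fx$map)
  expect_equal(cs$frac_tad_conserved, 1)
  expect_equal(cs$frac_loop_conserved, 1)

  fx0 <- simulate_ortholog_fixture(n_pairs = 10, frac_tad = 0, frac_loop = 0)
  cs0 <- gene_pair_conservation(fx0$a$tads, fx0$a$loops, fx0$a$genes,
                                fx0$b$tads, fx0$b$loops, fx0$b$genes, fx0$map)
  expect_equal(cs0$frac_tad_conserved, 0)
  expect_equal(cs0$frac_loop_conserved, 0)

  fx4 <- simulate_ortholog_fixture(n_pairs = 10, frac_tad = 0.4, frac_loop = 0.4)
  cs4 <- gene_pair_conservation(fx4$a$tads, fx4$a$loops, fx4$a$genes,
                                fx4$b$tads, fx4$b$loops, fx4$b$genes, fx4$map)
  expect_equal(cs4$frac_tad_conserved, 0.4)
  expect_equal(cs4$frac_loop_conserved, 0.4)
  expect_equal(cs4$n_pairs_tad_b, 10)

  bad_map <- fx$map
  bad_map$gene_a[2] <- bad_map$gene_a[1]
  expect_error(gene_pair_conservation(fx$a$tads, fx$a$loops, fx$a$genes,
                                      fx$b$tads, fx$b$loops, fx$b$genes,
                                      bad_map), "one-to-one")
})
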
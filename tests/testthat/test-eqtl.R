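mini_genes <- function() {
  tibble::tibble(gene_id = c("gA", "gB"), symbol = c("A", "B"), chrom = "c1",
                 strand = "+", start = c(100000, 300000),
                 end = c(110000, 310000), tss = c(100000, 300000),
                 expression = 1, set_labels = "")
}

test_that("promoter/distal classification has an inclusive 2.5 kb boundary", {
  genes <- mini_genes()
  eq <- tibble::tibble(variant_id = c("v1", "v2", "v3"),
                       chrom = c("c1", "c1", "c2"),
                       pos = c(102500, 102501, 5000),
                       egene_id = "gA", tags = "")
  got <- classify_position(eq, genes)
  expect_equal(got$position_class, c("promoter", "distal", "distal"))
  expect_equal(got$trans, c(FALSE, FALSE, TRUE))

  set.seed(61)
  eqr <- tibble::tibble(variant_id = sprintf("v%d", 1:1000), chrom = "c1",
                        pos = sample(0:400000, 1000),
                        egene_id = sample(c("gA", "gB"), 1000, replace = TRUE),
                        tags = "")
  got <- classify_position(eqr, genes)
  tss <- ifelse(eqr$egene_id == "gA", 100000, 300000)
  expect_equal(got$position_class,
               ifelse(abs(eqr$pos - tss) <= 2500, "promoter", "distal"))
})

test_that("variant compartment labels come from the containing segment", {
  comp <- tibble::tibble(chrom = "c1", start = c(0, 1000), end = c(1000, 2000),
                         label = c("A", "B"))
  eq <- tibble::tibble(variant_id = c("v1", "v2", "v3"), chrom = "c1",
                       pos = c(500, 1500, 5000), egene_id = "gA", tags = "")
  got <- compartment_of_variants(eq, comp)
  expect_equal(got$compartment, c("A", "B", "none"))
})

test_that("planted compartment proportions are recovered exactly on the bundle", {
  b <- default_bundle(matrices = FALSE)
  ann <- compartment_of_variants(b$eqtls, b$compartments)
  seg <- b$truth$compartments
  want <- vapply(seq_len(nrow(b$eqtls)), function(i) {
    hit <- seg$chrom == b$eqtls$chrom[i] & seg$start <= b$eqtls$pos[i] &
      b$eqtls$pos[i] < seg$end
    if (any(hit)) seg$label[which(hit)[1]] else "none"
  }, character(1))
  expect_equal(ann$compartment, want)
})

test_that("same-TAD co-residence and its enrichment behave on simple cases", {
  genes <- mini_genes()
  tads <- tibble::tibble(chrom = "c1", start = c(50000, 250000),
                         end = c(150000, 350000))
  eq <- tibble::tibble(variant_id = c("v1", "v2"), chrom = "c1",
                       pos = c(120000, 200000), egene_id = "gA", tags = "")
  st <- same_tad_analysis(eq, tads, genes)
  expect_equal(st$records$same_tad, c(TRUE, FALSE))
  expect_equal(st$observed_proportion, 0.5)
  expect_null(st$enrichment)
})

test_that("pieQTL taxonomy follows the opposite-foot promoter rule", {
  genes <- mini_genes()
  # loops: v on foot A; foot B at gA promoter / at gB promoter / at neither
  loops <- loop_table("c1",
                      startA = c(0, 10000, 20000),
                      endA = c(5000, 15000, 25000),
                      startB = c(98000, 298000, 200000),
                      endB = c(103000, 303000, 205000))
  eq <- tibble::tibble(variant_id = sprintf("v%d", 1:4), chrom = "c1",
                       pos = c(2500, 12500, 22500, 50000),
                       egene_id = "gA", tags = "")
  got <- pieqtl_classify(eq, loops, genes)
  expect_equal(got$loop_class,
               c("egene_pieqtl", "non_egene_pieqtl", "eqtl_only", "not_on_loop"))
})

test_that("a multi-loop variant takes the highest class and classes are exhaustive", {
  genes <- mini_genes()
  loops <- loop_table("c1",
                      startA = c(0, 0),
                      endA = c(5000, 5000),
                      startB = c(200000, 98000),
                      endB = c(205000, 103000))
  eq <- tibble::tibble(variant_id = "v1", chrom = "c1", pos = 2500,
                       egene_id = "gA", tags = "")
  # with only the first loop: eqtl_only; adding the promoter loop upgrades
  expect_equal(pieqtl_classify(eq, loops[1, ], genes)$loop_class, "eqtl_only")
  expect_equal(pieqtl_classify(eq, loops, genes)$loop_class, "egene_pieqtl")

  b <- default_bundle(matrices = FALSE)
  cls <- pieqtl_classify(b$eqtls, b$loops, b$genes)$loop_class
  expect_equal(length(cls), nrow(b$eqtls))
  expect_true(all(cls %in% c("not_on_loop", "eqtl_only", "non_egene_pieqtl",
                             "egene_pieqtl")))
})

test_that("regulatory overlap gives SE precedence and tracks eGene overlap", {
  genes <- mini_genes()
  cres <- tibble::tibble(chrom = "c1", start = c(95000, 200000),
                         end = c(96000, 201000))
  ses <- tibble::tibble(chrom = "c1", start = 95500, end = 115000)
  eq <- tibble::tibble(variant_id = sprintf("v%d", 1:3), chrom = "c1",
                       pos = c(95700, 200500, 5000),
                       egene_id = "gA", tags = "")
  got <- regulatory_overlap(eq, cres, ses, genes)
  # v1 is in both a CRE and an SE spanning the gA body -> SE wins
  expect_equal(got$regulatory_class, c("SE", "CRE", "none"))
  expect_equal(got$region_overlaps_egene, c(TRUE, FALSE, FALSE))
})

test_that("H3K27Ac context matches a direct Welch-formula oracle", {
  build <- genome_build(c(c1 = 1e6))
  set.seed(62)
  vals <- runif(10000, 0, 3)
  tr <- signal_track(build, 100, values = list(c1 = vals))
  eq <- tibble::tibble(variant_id = sprintf("v%d", 1:40), chrom = "c1",
                       pos = sample(1000:999000, 40), egene_id = "gA",
                       tags = "",
                       position_class = rep(c("promoter", "distal"), 20),
                       regulatory_class = "CRE")
  got <- h3k27ac_context(eq, tr)
  d <- got$records$h3k27ac[eq$position_class == "distal"]
  p <- got$records$h3k27ac[eq$position_class == "promoter"]
  # independent Welch computation
  se2 <- var(d) / length(d) + var(p) / length(p)
  t_want <- (mean(d) - mean(p)) / sqrt(se2)
  df_want <- se2^2 / ((var(d) / length(d))^2 / (length(d) - 1) +
                        (var(p) / length(p))^2 / (length(p) - 1))
  expect_equal(got$tests$t, t_want, tolerance = 1e-10)
  expect_equal(got$tests$df, df_want, tolerance = 1e-10)
  expect_equal(got$tests$p, 2 * pt(-abs(t_want), df_want), tolerance = 1e-10)
  expect_equal(got$tests$n_promoter, 20)

  # sign convention: distal listed first, promoter higher -> negative t
  eq2 <- eq
  tr2 <- signal_track(build, 100, values = list(c1 = vals))
  prom_pos <- eq2$pos[eq2$position_class == "promoter"]
  for (pp in prom_pos) tr2 <- track_add(tr2, "c1", pp - 100, pp + 100, 50)
  got2 <- h3k27ac_context(eq2, tr2)
  expect_lt(got2$tests$t, 0)
})

test_that("planted eQTL classes are recovered perfectly on the default bundle", {
  b <- default_bundle(matrices = FALSE)
  ly <- bundle_layers(b)
  ann <- suppressWarnings(
    annotate_eqtls(b$eqtls, b$genes, b$loops, b$tads, b$compartments,
                   ly$cres, ly$ses, track = b$case_track))
  m <- dplyr::left_join(ann$records, b$truth$eqtls, by = "variant_id",
                        suffix = c("", ".planted"))
  expect_equal(m$loop_class, m$loop_class.planted)
  expect_equal(m$position_class, m$position_class.planted)
  expect_equal(m$regulatory_class, m$regulatory_class.planted)
  expect_equal(m$same_tad, m$same_tad.planted)
  expect_equal(m$region_overlaps_egene, m$region_overlaps_egene.planted)
})

test_that("disease-tag strata are exact subsets of the global annotation", {
  b <- default_bundle(matrices = FALSE)
  ly <- bundle_layers(b)
  ann <- annotate_eqtls(b$eqtls, b$genes, b$loops, b$tads, b$compartments,
                        ly$cres, ly$ses)
  s <- eqtl_summary(ann$records)
  expect_true(all(s$by_tag$n <= nrow(ann$records)))
  for (i in seq_len(nrow(s$by_tag))) {
    tg <- s$by_tag$tag[i]
    sel <- grepl(tg, ann$records$tags, fixed = TRUE)
    expect_equal(s$by_tag$n[i], sum(sel))
    expect_equal(s$by_tag$n_egene_pieqtl[i],
                 sum(ann$records$loop_class[sel] == "egene_pieqtl"))
  }
  expect_equal(sum(s$loop_class$n), nrow(ann$records))
})
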
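mk_ld <- function(n = 50, seed = 71) {
  set.seed(seed)
  tibble::tibble(rsid = sprintf("rs%03d", 1:n), chrom = "c1",
                 pos = sample(0:1e6, n), lead_rsid = "rs000",
                 r2 = round(runif(n), 3), maf = round(runif(n, 0, 0.5), 3))
}

test_that("LD filtering is inclusive at both bounds, idempotent and order-preserving", {
  ld <- tibble::tibble(rsid = c("a", "b", "c"), chrom = "c1", pos = 1:3,
                       lead_rsid = "L", r2 = c(0.7, 0.99, 0.7),
                       maf = c(0.01, 0.009, 0.5))
  got <- filter_ld(ld)
  expect_equal(got$rsid, c("a", "c"))

  ld2 <- mk_ld()
  f1 <- filter_ld(ld2)
  expect_identical(filter_ld(f1), f1)
  want <- ld2$maf >= 0.01 & ld2$r2 >= 0.7
  expect_equal(f1$rsid, ld2$rsid[want])

  ld3 <- ld
  ld3$maf[2] <- NA
  expect_warning(f3 <- filter_ld(ld3), "missing")
  expect_equal(f3$rsid, c("a", "c"))
  expect_error(filter_ld(ld3, on_missing = "error"), "missing")
})

test_that("tightening the LD thresholds never increases downstream counts", {
  ld <- mk_ld(200, seed = 72)
  n_links <- function(maf_min, r2_min) {
    nrow(filter_ld(ld, maf_min, r2_min))
  }
  base <- n_links(0.01, 0.7)
  expect_lte(n_links(0.05, 0.7), base)
  expect_lte(n_links(0.01, 0.9), base)
  expect_lte(n_links(0.05, 0.9), min(n_links(0.05, 0.7), n_links(0.01, 0.9)))
})

test_that("loop targets intersect the opposite foot with bodies and TSS", {
  genes <- tibble::tibble(gene_id = c("g1", "g2", "g3"), symbol = "s",
                          chrom = "c1", strand = "+",
                          start = c(50000, 53000, 200000),
                          end = c(52000, 56000, 210000),
                          tss = c(50000, 53000, 200000))
  loops <- loop_table("c1", 0, 5000, 51000, 56000)
  v <- tibble::tibble(rsid = "rsX", chrom = "c1", pos = 2500,
                      locus = "L", disease = "AMD")
  links <- loop_targets(v, loops, genes)
  expect_equal(sum(links$mechanism == "loop_to_body"), 2)  # g1 and g2 bodies
  expect_equal(sum(links$mechanism == "loop_to_tss"), 1)   # g2 TSS only
  expect_true(all(links$evidence == loops$loop_id))

  v_off <- tibble::tibble(rsid = "rsY", chrom = "c1", pos = 900000,
                          locus = "L", disease = "AMD")
  expect_equal(nrow(loop_targets(v_off, loops, genes)), 0)
})

test_that("shared-element targets require variant and gene in the same region", {
  genes <- tibble::tibble(gene_id = c("g1", "g2"), symbol = "s", chrom = "c1",
                          strand = "+", start = c(1000, 50000),
                          end = c(3000, 52000), tss = c(1000, 50000))
  ses <- tibble::tibble(chrom = "c1", start = 500, end = 4000)
  cres <- tibble::tibble(chrom = "c1", start = 10000, end = 11000)
  v <- tibble::tibble(rsid = c("in_se", "in_cre"), chrom = "c1",
                      pos = c(600, 10500), locus = "L", disease = "AMD")
  links <- regulatory_targets(v, cres, ses, genes)
  expect_equal(nrow(links[links$mechanism == "se_shared", ]), 1)
  expect_equal(links$gene_id[links$mechanism == "se_shared"], "g1")
  # CRE contains no gene -> no cre_shared link
  expect_equal(nrow(links[links$mechanism == "cre_shared", ]), 0)
})

test_that("closest targets use distance zero inside bodies and documented tie-breaks", {
  genes <- tibble::tibble(gene_id = c("g1", "g2"), symbol = "s", chrom = "c1",
                          strand = "+", start = c(0, 2000),
                          end = c(1000, 3000), tss = c(0, 2000))
  v <- tibble::tibble(rsid = c("inside", "equidistant"), chrom = "c1",
                      pos = c(500, 1500), locus = "L", disease = "AMD")
  ct <- closest_targets(v, genes)
  expect_equal(ct$gene_id[1], "g1")
  expect_equal(ct$distance[1], 0)
  # 1-bp point at 1500: gap to g1 end = 500, to g2 start = 499 -> g2
  expect_equal(ct$gene_id[2], "g2")

  set.seed(73)
  vr <- tibble::tibble(rsid = sprintf("r%d", 1:500), chrom = "c1",
                       pos = sample(0:5000, 500, replace = TRUE),
                       locus = "L", disease = "AMD")
  ct <- closest_targets(vr, genes)
  want <- oracle_closest(point_intervals(vr$chrom, vr$pos),
                         genes[, c("chrom", "start", "end")])
  expect_equal(ct$gene_id, genes$gene_id[want$feature_idx])
  expect_equal(ct$distance, want$distance)
})

test_that("locus summaries deduplicate variants per category", {
  loops <- loop_table("c1", 0, 5000, 50000, 55000)
  genes <- tibble::tibble(gene_id = "g1", symbol = "s", chrom = "c1",
                          strand = "+", start = 50000, end = 52000, tss = 50000)
  v <- tibble::tibble(rsid = "rs1", chrom = "c1", pos = 2500,
                      locus = "L1", disease = "AMD", variant_class = "lead")
  links <- loop_targets(v, loops, genes)
  expect_gte(nrow(links), 2)  # body + tss via the same loop
  s <- locus_summary(v, links, loops)
  expect_equal(s$per_disease$n_contacting_gene, 1)
  expect_equal(s$per_disease$n_on_loop, 1)

  s0 <- locus_summary(v, links[0, ], loops)
  expect_equal(s0$per_disease$n_contacting_gene, 0)
})

test_that("planted GWAS links are fully recovered with no spurious control links", {
  b <- default_bundle(matrices = FALSE)
  ly <- bundle_layers(b)
  fl <- filter_ld(b$ld_variants)
  gv <- dplyr::bind_rows(
    dplyr::mutate(b$lead_variants, variant_class = "lead"),
    dplyr::mutate(fl, variant_class = "filtered_LD"))
  lt <- loop_targets(gv, b$loops, b$genes)
  rt <- regulatory_targets(gv, ly$cres, ly$ses, b$genes)
  found <- c(paste(lt$rsid, lt$gene_id, lt$mechanism),
             paste(rt$rsid, rt$gene_id, rt$mechanism))
  planted <- b$truth$gwas_links
  expect_true(all(paste(planted$rsid, planted$gene_id, planted$mechanism)
                  %in% found))
  ctrl <- b$truth$gwas_control_rsids
  expect_equal(sum(lt$rsid %in% ctrl), 0)
  expect_equal(sum(rt$rsid %in% ctrl), 0)
})

test_that("every emitted link satisfies its own mechanism predicate", {
  b <- default_bundle(matrices = FALSE)
  ly <- bundle_layers(b)
  gv <- dplyr::bind_rows(
    dplyr::mutate(b$lead_variants, variant_class = "lead"),
    dplyr::mutate(filter_ld(b$ld_variants), variant_class = "filtered_LD"))
  lt <- loop_targets(gv, b$loops, b$genes)
  rt <- regulatory_targets(gv, ly$cres, ly$ses, b$genes)
  expect_true(check_links(lt, gv, b$loops, b$genes))
  expect_true(check_links(rt, gv, b$loops, b$genes,
                          cres = ly$cres, ses = ly$ses))
})
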
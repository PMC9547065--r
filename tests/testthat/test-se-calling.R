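test_that("active-state merging unions adjacent active segments only", {
  segs <- tibble::tibble(chrom = "c1",
                         start = c(0, 500, 900),
                         end = c(500, 900, 1400),
                         state = c("enhancer_1", "enhancer_2", "heterochromatin"))
  cre <- merge_active_states(segs)
  expect_equal(nrow(cre), 1)
  expect_equal(cre$start, 0)
  expect_equal(cre$end, 900)
  expect_false(cre$is_promoter_state)
  expect_match(cre$source_labels, "enhancer_1,enhancer_2")

  segs$state[1] <- "promoter"
  expect_true(merge_active_states(segs)$is_promoter_state)

  expect_error(merge_active_states(segs, active_label_set = "exotic_state"),
               "unknown state")
})

test_that("merged CREs equal the interval-union oracle on random segments", {
  set.seed(31)
  segs <- rand_intervals(300)
  segs <- segs[order(segs$chrom, segs$start), ]
  segs$state <- sample(state_vocabulary(), 300, replace = TRUE)
  cre <- merge_active_states(segs)
  act <- segs[segs$state %in% active_states(), ]
  # oracle: per-bp union of active segments
  for (ch in unique(act$chrom)) {
    covered <- rep(FALSE, 10000)
    a <- act[act$chrom == ch, ]
    for (i in seq_len(nrow(a))) covered[(a$start[i] + 1):a$end[i]] <- TRUE
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- c(0, ends[-length(ends)])
    want <- tibble::tibble(start = starts[r$values], end = ends[r$values])
    got <- cre[cre$chrom == ch, ]
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("TSS exclusion removes only fully contained CREs", {
  proms <- tibble::tibble(gene_id = "g", chrom = "c1", start = 0, end = 5000,
                          tss = 2500)
  cres <- tibble::tibble(chrom = "c1", start = c(1000, 4000), end = c(2000, 7000))
  kept <- exclude_tss_cres(cres, proms)
  expect_equal(kept$start, 4000)

  set.seed(32)
  cres <- rand_intervals(100)
  proms <- rand_intervals(30)
  proms$gene_id <- sprintf("g%d", 1:30)
  kept <- exclude_tss_cres(cres, proms)
  want <- vapply(seq_len(nrow(cres)), function(i) {
    !any(proms$chrom == cres$chrom[i] & proms$start <= cres$start[i] &
           cres$end[i] <= proms$end)
  }, logical(1))
  expect_equal(nrow(kept), sum(want))
  expect_equal(kept$start, cres$start[want])
})

test_that("stitching chains CREs across sub-threshold gaps", {
  cres <- tibble::tibble(chrom = "c1", start = c(0, 5000, 30000),
                         end = c(1000, 6000, 31000))
  st <- stitch(cres, 12500)
  expect_equal(st$start, c(0, 30000))
  expect_equal(st$end, c(6000, 31000))
  expect_equal(st$n_constituents, c(2L, 1L))

  st0 <- stitch(cres, 0)
  expect_equal(nrow(st0), 3)
})

test_that("stitching equals the transitive-closure oracle and is monotone", {
  set.seed(33)
  starts <- sort(sample(seq(0, 2e5, by = 50), 200))
  cres <- tibble::tibble(chrom = sample(c("c1", "c2"), 200, replace = TRUE),
                         start = starts, end = starts + 40)
  d <- 3000
  st <- stitch(cres, d)
  # oracle: transitive closure of the gap<d relation per chromosome
  n_regions_oracle <- 0
  for (ch in c("c1", "c2")) {
    x <- cres[cres$chrom == ch, ]
    x <- x[order(x$start), ]
    if (!nrow(x)) next
    gaps <- x$start[-1] - cummax(x$end[-nrow(x)])
    n_regions_oracle <- n_regions_oracle + 1 + sum(gaps >= d)
  }
  expect_equal(nrow(st), n_regions_oracle)
  # every CRE belongs to exactly one region
  expect_equal(sum(st$n_constituents), nrow(cres))
  # increasing the stitch distance never increases the region count
  counts <- vapply(c(0, 100, 1000, 5000, 20000), function(dd) nrow(stitch(cres, dd)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("region signal sums constituents only, floored at zero", {
  build <- genome_build(c(c1 = 50000))
  case <- signal_track(build, 100, values = list(c1 = rep(2, 500)))
  ctrl <- signal_track(build, 100, values = list(c1 = rep(1, 500)))
  cres <- tibble::tibble(chrom = "c1", start = c(0, 5000), end = c(500, 5500))
  st <- region_signal(stitch(cres, 12500), case, ctrl)
  expect_equal(st$case_signal, 2000)   # constituents total 1000 bp, gaps excluded
  expect_equal(st$net_signal, 1000)

  st2 <- region_signal(stitch(cres, 12500), ctrl, case)
  expect_equal(st2$net_signal, 0)

  set.seed(34)
  casr <- signal_track(build, 100, values = list(c1 = runif(500, 0, 4)))
  ctrr <- signal_track(build, 100, values = list(c1 = runif(500, 0, 4)))
  st3 <- region_signal(stitch(cres, 12500), casr, ctrr)
  want_case <- oracle_track_sum(casr, "c1", 0, 500) +
    oracle_track_sum(casr, "c1", 5000, 5500)
  expect_equal(st3$case_signal, want_case, tolerance = 1e-9)
})

test_that("the ROSE elbow equals an exhaustive argmin scan and handles degeneracy", {
  mk <- function(signals) {
    n <- length(signals)
    tibble::tibble(region_id = sprintf("r%02d", seq_len(n)), chrom = "c1",
                   start = (seq_len(n) - 1) * 1e4, end = (seq_len(n) - 1) * 1e4 + 5e3,
                   n_constituents = 1L,
                   constituents = replicate(n, tibble::tibble(), simplify = FALSE),
                   net_signal = signals)
  }
  s <- c(1, 1, 1, 1, 2, 3, 50, 60, 100)
  call <- rose_cutoff(mk(s))
  # exhaustive scan oracle
  ss <- sort(s)
  x <- (seq_along(ss) - 1) / (length(ss) - 1)
  y <- (ss - min(ss)) / (max(ss) - min(ss))
  k <- max(which((y - x) == min(y - x)))
  expect_equal(attr(call, "cutoff_index"), k)
  expect_equal(sort(call$net_signal[call$is_SE]), ss[ss > ss[k]])

  expect_warning(c0 <- rose_cutoff(mk(rep(5, 6))), "zero SEs")
  expect_equal(sum(c0$is_SE), 0)

  lin <- rose_cutoff(mk(1:10))
  expect_equal(sum(lin$is_SE), 0)  # y == x everywhere, tie -> last index
})

test_that("the elbow is invariant under affine rescaling of the signal", {
  set.seed(35)
  s <- c(runif(40, 0, 5), runif(5, 50, 100))
  mk <- function(signals) {
    n <- length(signals)
    tibble::tibble(region_id = sprintf("r%02d", seq_len(n)), chrom = "c1",
                   start = (seq_len(n) - 1) * 1e4, end = (seq_len(n) - 1) * 1e4 + 5e3,
                   n_constituents = 1L,
                   constituents = replicate(n, tibble::tibble(), simplify = FALSE),
                   net_signal = signals)
  }
  c1 <- rose_cutoff(mk(s))
  c2 <- rose_cutoff(mk(3.7 * s + 11))
  expect_equal(attr(c1, "cutoff_index"), attr(c2, "cutoff_index"))
  expect_equal(c1$is_SE, c2$is_SE)
})

test_that("per-chromosome SE summary computes r-squared and flags degenerate cases", {
  build <- genome_build(c(c1 = 1e6, c2 = 2e6, c3 = 3e6))
  genes <- tibble::tibble(gene_id = sprintf("g%d", 1:6), symbol = "s",
                          chrom = rep(c("c1", "c2", "c3"), times = c(1, 2, 3)),
                          strand = "+", start = 0, end = 10, tss = 0,
                          expression = 5)
  mk_call <- function(counts) {
    rows <- list()
    for (i in seq_along(counts)) {
      ch <- c("c1", "c2", "c3")[i]
      if (counts[i] > 0) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          chrom = ch, start = (seq_len(counts[i]) - 1) * 1e4,
          end = (seq_len(counts[i]) - 1) * 1e4 + 5e3)
      }
    }
    x <- dplyr::bind_rows(rows)
    x$region_id <- sprintf("r%02d", seq_len(nrow(x)))
    x$n_constituents <- 1L
    x$net_signal <- 10
    x$is_SE <- TRUE
    x$rank <- seq_len(nrow(x)); x$x <- 0; x$y <- 0
    structure(x, cutoff_index = 1L, cutoff_signal = 0,
              class = c("se_call", class(tibble::tibble())))
  }
  # SE counts proportional to chromosome size -> r2 = 1
  s1 <- se_summary(mk_call(c(1, 2, 3)), build, genes)
  expect_equal(s1$r2_size, 1)
  expect_equal(s1$r2_genes, 1)
  expect_false(s1$flag)
  # constant counts -> zero variance -> undefined, flagged
  s2 <- se_summary(mk_call(c(2, 2, 2)), build, genes)
  expect_true(is.na(s2$r2_size))
  expect_true(s2$flag)
})
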
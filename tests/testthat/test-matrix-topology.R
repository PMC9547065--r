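sym_rand_matrix <- function(n, lambda = 5) {
  m <- matrix(rpois(n * n, lambda), n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

test_that("expected-by-distance matches direct per-diagonal averaging", {
  cm <- contact_matrix(matrix(3, 10, 10), "c1", 100, mask = rep(TRUE, 10))
  expect_equal(expected_by_distance(cm), rep(3, 10))

  d <- diag(7)
  cm <- contact_matrix(d, "c1", 100, mask = rep(TRUE, 7))
  e <- expected_by_distance(cm)
  expect_equal(e[1], 1)
  expect_equal(e[-1], rep(0, 6))

  set.seed(21)
  m <- sym_rand_matrix(50)
  mask <- runif(50) > 0.1
  cm <- contact_matrix(m, "c1", 100, mask = mask)
  expect_equal(expected_by_distance(cm), oracle_expected(m, mask),
               tolerance = 1e-12)
})

test_that("all-masked diagonals are undefined, not zero", {
  m <- matrix(0, 6, 6)
  diag(m) <- 1
  cm <- contact_matrix(m, "c1", 100, mask = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  e <- expected_by_distance(cm)
  expect_true(is.na(e[4]))  # separation 3 only pairs valid x masked bins
})

test_that("diamond insulation is zero on a constant matrix and matches the loop oracle", {
  cm <- contact_matrix(matrix(2, 40, 40), "c1", 5000, mask = rep(TRUE, 40))
  ins <- diamond_insulation(cm, window_bp = 25000)  # w = 5 bins
  expect_equal(ins$score[ins$valid], rep(0, sum(ins$valid)), tolerance = 1e-12)
  expect_false(any(ins$valid[c(1:5, 36:40)]))

  set.seed(22)
  m <- sym_rand_matrix(60)
  mask <- runif(60) > 0.05
  cm <- contact_matrix(m, "c1", 5000, mask = mask)
  ins <- diamond_insulation(cm, window_bp = 5 * 5000)
  want <- oracle_diamond(m, 5, mask)
  expect_equal(ins$score[ins$valid], want[ins$valid], tolerance = 1e-9)

  expect_error(diamond_insulation(cm, window_bp = 7777), "multiple")
  expect_error(diamond_insulation(cm, window_bp = 60 * 5000), "larger")
})

test_that("the insulation minimum of a two-TAD block matrix sits at the boundary", {
  n <- 60
  base <- matrix(1, n, n)
  b <- 30  # boundary between bins 30 and 31 (1-based)
  base[1:b, 1:b] <- 3
  base[(b + 1):n, (b + 1):n] <- 3
  cm <- contact_matrix(base, "c1", 5000, mask = rep(TRUE, n))
  ins <- diamond_insulation(cm, window_bp = 10 * 5000)
  valid <- which(ins$valid)
  argmin <- valid[which.min(ins$score[valid])]
  # boundary coordinate 30*5000 lives in 0-based bin 30 (1-based 31)
  expect_lte(abs(argmin - (b + 1)), 1)
})

test_that("per-TAD boundary insulation averages the two boundary bins", {
  ins <- tibble::tibble(chrom = "c1", start = (0:9) * 5000,
                        end = (1:10) * 5000, bin = 0:9,
                        score = c(NA, -1, 0, 0, 0, 0, 0, 0, -3, NA),
                        valid = c(FALSE, rep(TRUE, 8), FALSE))
  attr(ins, "bin_size") <- 5000
  tads <- tibble::tibble(chrom = "c1", start = 5000, end = 40000)
  got <- tad_boundary_insulation(tads, ins)
  expect_equal(got$boundary_score, (-1 + -3) / 2)

  # one invalid boundary bin -> the valid one, flagged count
  tads2 <- tibble::tibble(chrom = "c1", start = 0, end = 40000)
  got2 <- tad_boundary_insulation(tads2, ins)
  expect_equal(got2$boundary_score, -3)
  expect_equal(got2$n_valid_bins, 1L)
  expect_false(got2$flag_invalid)

  tads3 <- tibble::tibble(chrom = "c1", start = 0, end = 50000)
  got3 <- tad_boundary_insulation(tads3, ins)
  expect_true(got3$flag_invalid)
})

planted_checkerboard <- function(n = 80, gamma = 2, seed = 23) {
  set.seed(seed)
  lab <- rep(c("A", "B"), times = n / 20, each = 10)
  expected <- outer(seq_len(n), seq_len(n),
                    function(i, j) 50 / (abs(i - j) + 1))
  boost <- outer(lab, lab, "==") * (gamma - 1) + 1
  m <- matrix(rpois(n * n, expected * boost), n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  ref <- ifelse(lab == "A", 2, 0) + runif(n, 0, 0.5)
  list(mat = m, lab = lab, ref = ref)
}

test_that("compartment call recovers a planted checkerboard and honours the reference sign", {
  pc <- planted_checkerboard()
  cm <- contact_matrix(pc$mat, "c1", 1e5, mask = rep(TRUE, 80))
  cc <- compartment_call(cm, pc$ref, bin_size = 1e5)
  acc <- mean(cc$bins$label == pc$lab)
  expect_gte(acc, 0.95)

  # negating the reference flips labels; eigenvector unchanged up to sign
  cc2 <- compartment_call(cm, -pc$ref, bin_size = 1e5)
  expect_equal(abs(cc2$bins$eigen), abs(cc$bins$eigen), tolerance = 1e-9)
  flip <- mean(cc2$bins$label != cc$bins$label)
  expect_gte(flip, 0.95)
})

test_that("compartment call is invariant under uniform scaling and errors on degenerate input", {
  pc <- planted_checkerboard(seed = 24)
  cm <- contact_matrix(pc$mat, "c1", 1e5, mask = rep(TRUE, 80))
  cm2 <- contact_matrix(pc$mat * 7, "c1", 1e5, mask = rep(TRUE, 80))
  c1 <- compartment_call(cm, pc$ref)
  c2 <- compartment_call(cm2, pc$ref)
  expect_equal(c1$bins$label, c2$bins$label)
  expect_equal(c1$bins$eigen, c2$bins$eigen, tolerance = 1e-9)

  uni <- contact_matrix(matrix(4, 30, 30), "c1", 1e5, mask = rep(TRUE, 30))
  expect_error(compartment_call(uni, runif(30)), "no compartment signal")
})

test_that("contact matrix triplet files round-trip", {
  set.seed(25)
  m <- sym_rand_matrix(15, 2)
  cm <- contact_matrix(m, "chr9", 5000, mask = rep(TRUE, 15))
  f <- withr::local_tempfile()
  write_contact_matrix(cm, f)
  cm2 <- read_contact_matrix(f)
  expect_equal(cm2$mat, cm$mat)
  expect_equal(cm2$chrom, "chr9")
  expect_equal(cm2$bin_size, 5000)
})
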
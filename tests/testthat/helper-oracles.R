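# Brute-force oracles, written independently of the package's engines:
# literal all-pairs scans and per-bp expansions.

oracle_join <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          a$start[i] < b$end[j] && b$start[j] < a$end[i]) {
        out[[length(out) + 1L]] <- c(i, j)
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(a_idx = integer(), b_idx = integer()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(a_idx = m[, 1], b_idx = m[, 2])
}

oracle_closest <- function(q, f) {
  res <- list()
  for (i in seq_len(nrow(q))) {
    best <- NA_integer_; best_d <- Inf; best_abs <- Inf
    for (j in seq_len(nrow(f))) {
      if (f$chrom[j] != q$chrom[i]) next
      d <- if (f$start[j] < q$end[i] && q$start[i] < f$end[j]) 0
      else if (f$start[j] >= q$end[i]) f$start[j] - q$end[i]
      else -(q$start[i] - f$end[j])
      better <- abs(d) < best_abs ||
        (abs(d) == best_abs && !is.na(best) &&
           (f$start[j] < f$start[best] ||
              (f$start[j] == f$start[best] && j < best)))
      if (is.na(best) || better) { best <- j; best_d <- d; best_abs <- abs(d) }
    }
    res[[i]] <- tibble::tibble(query_idx = i, feature_idx = best,
                               distance = if (is.na(best)) NA_real_ else best_d)
  }
  dplyr::bind_rows(res)
}

# per-bp expansion of a signal track over [start, end)
oracle_track_sum <- function(track, chrom, start, end) {
  bs <- track$bin_size
  v <- track$values[[chrom]]
  if (end <= start) return(0)
  bp <- start:(end - 1)
  sum(v[floor(bp / bs) + 1])
}

oracle_expected <- function(mat, mask = rep(TRUE, nrow(mat))) {
  n <- nrow(mat)
  out <- rep(NA_real_, n)
  for (d in 0:(n - 1)) {
    vals <- c()
    for (i in 1:(n - d)) {
      j <- i + d
      if (mask[i] && mask[j]) vals <- c(vals, mat[i, j])
    }
    if (length(vals)) out[d + 1] <- mean(vals)
  }
  out
}

oracle_diamond <- function(mat, w, mask = rep(TRUE, nrow(mat))) {
  n <- nrow(mat)
  raw <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - w < 1 || i + w > n) next
    vals <- c()
    for (r in (i - w):(i - 1)) {
      for (cc in (i + 1):(i + w)) {
        if (mask[r] && mask[cc]) vals <- c(vals, mat[r, cc])
      }
    }
    if (length(vals)) raw[i] <- mean(vals)
  }
  gm <- mean(raw, na.rm = TRUE)
  log2(raw / gm)
}

# random interval tables on a two-chromosome toy build
rand_intervals <- function(n, max_len = 200, chroms = c("c1", "c2"),
                          span = 10000) {
  start <- floor(runif(n, 0, span - max_len))
  len <- pmax(1, floor(runif(n, 1, max_len)))
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = start, end = start + len)
}

toy_build <- function() genome_build(c(c1 = 10000, c2 = 10000))
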
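# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) abort("a seed is required for every random generator")
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a component sub-seed from a master seed; keeps results independent
# across components and below 2^31.
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103515245 + 12345 * offset) %% 2147483647L)
}

#' Random fixed-length region sets
#'
#' Generates `n_sets` sets of `count` random regions of fixed `length`,
#' mirroring `bedtools random`: each region's chromosome is chosen with
#' probability proportional to its placeable length and its start uniformly
#' on `[0, chrom_length - length]`. Regions within a set may overlap one
#' another. Used as the null for super-enhancer-sized region statistics
#' (typically `length` = the median SE length, `count` = the number of SEs,
#' `n_sets` = 100).
#'
#' @param build Genome build.
#' @param count Regions per set.
#' @param length Region length in bp.
#' @param n_sets Number of sets (default 100).
#' @param seed Mandatory RNG seed.
#' @return Tibble with columns `set_index` (0-based), `chrom`, `start`,
#'   `end`.
#' @export
sample_random_regions <- function(build, count, length, n_sets = 100, seed) {
  check_build(build)
  placeable <- pmax(build$length - length + 1, 0)
  if (all(placeable == 0)) abort("region length exceeds every chromosome")
  with_seed_(seed, {
    n_tot <- count * n_sets
    ch_i <- sample.int(nrow(build), n_tot, replace = TRUE,
                       prob = placeable / sum(placeable))
    start <- floor(runif(n_tot, 0, placeable[ch_i]))
    tibble(set_index = rep(0:(n_sets - 1), each = count),
           chrom = build$chrom[ch_i],
           start = start, end = start + length)
  })
}

#' Random TAD sets preserving the observed length multiset
#'
#' Generates `n_sets` sets of non-overlapping random domains whose lengths
#' are permuted copies of the observed TAD lengths, so each set has exactly
#' the observed count and mean length. Lengths are assigned to chromosomes
#' at random subject to capacity and placed with random gaps (uniform
#' stick-breaking of the per-chromosome slack), which always succeeds when
#' the total fits; infeasible layouts raise an error suggesting a larger
#' genome.
#'
#' @param build Genome build.
#' @param observed_tads Interval table of observed TADs.
#' @param n_sets Number of sets (default 100).
#' @param seed Mandatory RNG seed.
#' @param max_attempts Reshuffle attempts per set before giving up.
#' @return Tibble with columns `set_index` (0-based), `chrom`, `start`,
#'   `end`.
#' @export
sample_random_tads <- function(build, observed_tads, n_sets = 100, seed,
                               max_attempts = 100) {
  check_build(build)
  check_intervals(observed_tads, build, "observed TADs")
  lens <- observed_tads$end - observed_tads$start
  with_seed_(seed, {
    sets <- lapply(0:(n_sets - 1), function(si) {
      for (attempt in seq_len(max_attempts)) {
        ord <- sample.int(length(lens))
        cap <- chrom_lengths(build)
        assign_ch <- character(length(lens))
        ok <- TRUE
        for (i in ord) {
          fits <- names(cap)[cap >= lens[i]]
          if (!length(fits)) { ok <- FALSE; break }
          ch <- if (length(fits) == 1) fits else {
            sample(fits, 1, prob = cap[fits] / sum(cap[fits]))
          }
          assign_ch[i] <- ch
          cap[ch] <- cap[ch] - lens[i]
        }
        if (!ok) next
        placed <- lapply(unique(assign_ch), function(ch) {
          li <- lens[assign_ch == ch]
          li <- li[sample.int(length(li))]
          slack <- chrom_lengths(build)[[ch]] - sum(li)
          cuts <- sort(runif(length(li), 0, 1))
          gaps <- floor(diff(c(0, cuts, 1)) * slack)
          starts <- cumsum(gaps[-length(gaps)] + c(0, li[-length(li)]))
          tibble(chrom = ch, start = starts, end = starts + li)
        })
        out <- bind_rows(placed)
        out$set_index <- si
        return(out[order(out$chrom, out$start), ])
      }
      abort("random TAD placement failed; use a larger genome or fewer/shorter TADs")
    })
    bind_rows(sets)[, c("set_index", "chrom", "start", "end")]
  })
}

#' Resampling enrichment t-test against random sets
#'
#' The null-comparison unit used throughout: an observed statistic is
#' compared with the same statistic computed on each of `n` random sets
#' (typically 100, giving df = 99) by a one-sample t-test of the random
#' values against the observed constant:
#' `t = (mean(random) - observed) / (sd(random) / sqrt(n))`, two-sided p
#' from the t distribution with `n - 1` df. Sign convention: negative t
#' means the observed value exceeds the random mean (an enrichment).
#'
#' @param observed Observed statistic (scalar).
#' @param random_values Numeric vector of the statistic on random sets.
#' @param name Optional statistic name carried in the result.
#' @return An object of class `enrichment_result`; see
#'   [tidy.enrichment_result()].
#' @export
enrichment_t <- function(observed, random_values, name = NULL) {
  n <- length(random_values)
  if (n < 2) abort("need at least 2 random values")
  m <- mean(random_values)
  s <- sd(random_values)
  direction <- if (observed > m) "observed_higher"
  else if (observed < m) "observed_lower" else "none"
  if (s == 0) {
    warn("zero variance in random values: t undefined, reporting direction only")
    t_stat <- NA_real_; p <- NA_real_
  } else {
    t_stat <- (m - observed) / (s / sqrt(n))
    p <- 2 * pt(-abs(t_stat), df = n - 1)
  }
  p_emp <- (1 + sum(abs(random_values - m) >= abs(observed - m))) / (n + 1)
  structure(list(statistic = name %||% "statistic",
                 observed = observed, random_values = random_values,
                 n_sets = n, random_mean = m, random_sd = s,
                 t = t_stat, df = n - 1, p = p, p_empirical = p_emp,
                 direction = direction),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment: %s observed=%.4g random=%.4g+/-%.3g t(%d)=%.3f p=%.3g [%s]>\n",
              x$statistic, x$observed, x$random_mean, x$random_sd,
              x$df, x$t, x$p, x$direction))
  invisible(x)
}
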
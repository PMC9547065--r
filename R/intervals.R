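#' Overlap join between two interval tables
#'
#' Half-open overlap semantics: intervals `a` and `b` overlap iff they share
#' a chromosome and `a.start < b.end && b.start < a.end`. The engine sorts
#' the subject intervals and prunes candidates by start coordinate with a
#' binary search (`findInterval`); its output is defined to be identical to
#' the all-pairs scan, ordered by `(a_idx, b_idx)`.
#'
#' @param a,b Interval tables (columns `chrom`, `start`, `end`).
#' @return A tibble with columns `a_idx`, `b_idx`, row indices into `a` and
#'   `b` of each overlapping pair. Empty inputs give an empty result.
#' @export
join_overlaps <- function(a, b) {
  check_intervals(a, what = "a")
  check_intervals(b, what = "b")
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble(a_idx = integer(), b_idx = integer()))
  }
  a_idx_all <- seq_len(nrow(a))
  out <- vector("list", 0L)
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ai <- a_idx_all[a$chrom == ch]
    bi <- which(b$chrom == ch)
    ord <- order(b$start[bi])
    bi <- bi[ord]
    bs <- b$start[bi]
    be <- b$end[bi]
    # candidates: b.start < a.end
    n_cand <- findInterval(a$end[ai] - 0.5, bs)
    keep_a <- n_cand > 0L
    if (!any(keep_a)) next
    a_rep <- rep(ai[keep_a], n_cand[keep_a])
    a_start_rep <- rep(a$start[ai[keep_a]], n_cand[keep_a])
    pos <- sequence(n_cand[keep_a])
    hit <- be[pos] > a_start_rep
    if (!any(hit)) next
    out[[length(out) + 1L]] <- tibble(a_idx = a_rep[hit], b_idx = bi[pos[hit]])
  }
  if (!length(out)) return(tibble(a_idx = integer(), b_idx = integer()))
  res <- bind_rows(out)
  res[order(res$a_idx, res$b_idx), ]
}

#' Test each query interval for overlap with a feature set
#'
#' @param query,features Interval tables.
#' @return Logical vector, one element per row of `query`.
#' @export
overlaps_any <- function(query, features) {
  hits <- join_overlaps(query, features)
  out <- logical(nrow(query))
  out[unique(hits$a_idx)] <- TRUE
  out
}

count_overlaps <- function(query, features) {
  hits <- join_overlaps(query, features)
  tab <- tabulate(hits$a_idx, nbins = nrow(query))
  as.integer(tab)
}

#' Closest feature to each query interval
#'
#' For each query, returns the nearest feature on the same chromosome with a
#' signed distance: 0 when overlapping, positive when the feature starts
#' downstream of the query end, negative when it ends upstream of the query
#' start. Ties on absolute distance are broken deterministically by smaller
#' feature start, then by feature input order; set `all_ties = TRUE` to get
#' every co-minimal feature instead.
#'
#' @param query,features Interval tables.
#' @param all_ties Return all tied nearest features (long format) instead of
#'   one row per query.
#' @return A tibble with columns `query_idx`, `feature_idx`, `distance`.
#'   Queries with no feature on their chromosome get `feature_idx = NA`.
#' @export
closest_feature <- function(query, features, all_ties = FALSE) {
  check_intervals(query, what = "query")
  check_intervals(features, what = "features")
  rows <- vector("list", nrow(query))
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    fi <- which(features$chrom == ch)
    if (!length(fi)) {
      for (q in qi) {
        rows[[q]] <- tibble(query_idx = q, feature_idx = NA_integer_,
                            distance = NA_real_)
      }
      next
    }
    fs <- features$start[fi]
    fe <- features$end[fi]
    for (q in qi) {
      qs <- query$start[q]; qe <- query$end[q]
      d <- numeric(length(fi))
      right <- fs >= qe
      left <- fe <= qs
      d[right] <- fs[right] - qe
      d[left] <- -(qs - fe[left])
      # remaining are overlaps, distance 0
      o <- order(abs(d), fs, seq_along(fi))
      if (all_ties) {
        best <- abs(d) == abs(d[o[1]])
        keep <- o[abs(d[o]) == abs(d[o[1]])]
        rows[[q]] <- tibble(query_idx = q, feature_idx = fi[keep],
                            distance = d[keep])
      } else {
        rows[[q]] <- tibble(query_idx = q, feature_idx = fi[o[1]],
                            distance = d[o[1]])
      }
    }
  }
  bind_rows(rows)
}

# 1-bp point intervals from 0-based positions.
point_intervals <- function(chrom, pos) {
  tibble(chrom = chrom, start = pos, end = pos + 1)
}

# Union (merge) of possibly-overlapping intervals; `gap` merges intervals
# separated by less than `gap` bp (gap = 0 merges touching intervals only
# when they overlap or abut).
merge_intervals <- function(x, gap = 0) {
  if (nrow(x) == 0) return(tibble(chrom = character(), start = numeric(), end = numeric()))
  x <- x[order(x$chrom, x$start, x$end), ]
  out <- vector("list", 0L)
  for (ch in unique(x$chrom)) {
    xi <- x[x$chrom == ch, ]
    s <- xi$start; e <- xi$end
    grp <- cumsum(c(1L, as.integer(s[-1] > cummax(e[-length(e)]) + gap)))
    out[[length(out) + 1L]] <- tibble(
      chrom = ch,
      start = tapply(s, grp, min)[as.character(unique(grp))],
      end = tapply(e, grp, max)[as.character(unique(grp))]
    )
  }
  res <- bind_rows(out)
  res$start <- as.numeric(res$start); res$end <- as.numeric(res$end)
  res
}

# Total length of the pairwise intersection of interval `q` with set `x`
# (x assumed non-overlapping).
overlap_width <- function(q, x) {
  hits <- join_overlaps(q, x)
  if (nrow(hits) == 0) return(numeric(nrow(q)))
  w <- pmin(q$end[hits$a_idx], x$end[hits$b_idx]) -
    pmax(q$start[hits$a_idx], x$start[hits$b_idx])
  out <- numeric(nrow(q))
  agg <- tapply(w, hits$a_idx, sum)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}
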
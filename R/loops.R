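#' Construct a chromatin-loop table
#'
#' Loops are cis pairwise contacts between two anchor intervals ("feet",
#' typically fixed-width bins from the loop caller). Feet are stored in
#' canonical order (`startA <= startB`); identical feet are rejected.
#'
#' @param chrom Chromosome of both feet (loops are cis).
#' @param startA,endA,startB,endB Foot coordinates (0-based half-open).
#' @param qvalue Optional per-loop FDR q-value in \[0, 1\].
#' @param contact_count Optional non-negative supporting contact count.
#' @param build Optional genome build for coordinate validation.
#' @return A tibble with columns `loop_id`, `chrom`, `startA`, `endA`,
#'   `startB`, `endB`, `qvalue`, `contact_count`.
#' @export
loop_table <- function(chrom, startA, endA, startB, endB,
                       qvalue = NA_real_, contact_count = NA_real_,
                       build = NULL) {
  x <- tibble(chrom = chrom, startA = startA, endA = endA,
              startB = startB, endB = endB,
              qvalue = qvalue, contact_count = contact_count)
  if (nrow(x)) {
    swap <- x$startA > x$startB |
      (x$startA == x$startB & x$endA > x$endB)
    if (any(swap)) {
      tmp_s <- x$startA[swap]; tmp_e <- x$endA[swap]
      x$startA[swap] <- x$startB[swap]; x$endA[swap] <- x$endB[swap]
      x$startB[swap] <- tmp_s; x$endB[swap] <- tmp_e
    }
    same <- x$startA == x$startB & x$endA == x$endB
    if (any(same)) {
      abort(sprintf("loop %d has identical feet", which(same)[1]))
    }
    bad_q <- !is.na(x$qvalue) & (x$qvalue < 0 | x$qvalue > 1)
    if (any(bad_q)) abort("loop q-values must lie in [0, 1]")
    check_intervals(tibble(chrom = x$chrom, start = x$startA, end = x$endA),
                    build, "loop feet A")
    check_intervals(tibble(chrom = x$chrom, start = x$startB, end = x$endB),
                    build, "loop feet B")
  }
  x$loop_id <- if (nrow(x)) sprintf("loop_%05d", seq_len(nrow(x))) else character()
  x[, c("loop_id", "chrom", "startA", "endA", "startB", "endB",
        "qvalue", "contact_count")]
}

#' Loop sizes (midpoint-to-midpoint distance)
#'
#' Loop size is defined as the distance between the midpoints of the two
#' feet, which is invariant under foot-order permutation and insensitive to
#' foot width.
#'
#' @param loops A loop table.
#' @return Numeric vector of sizes in bp.
#' @export
loop_sizes <- function(loops) {
  (loops$startB + loops$endB) / 2 - (loops$startA + loops$endA) / 2
}

# Feet of a loop table as an interval table; `which` selects foot A, B, or
# both (stacked, with a `foot` column). Row index into `loops` kept as
# `loop_idx`.
loop_feet <- function(loops, which = c("both", "A", "B")) {
  which <- match.arg(which)
  a <- tibble(chrom = loops$chrom, start = loops$startA, end = loops$endA,
              loop_idx = seq_len(nrow(loops)), foot = "A")
  b <- tibble(chrom = loops$chrom, start = loops$startB, end = loops$endB,
              loop_idx = seq_len(nrow(loops)), foot = "B")
  switch(which, A = a, B = b, both = bind_rows(a, b))
}
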
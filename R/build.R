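#' Define a genome build
#'
#' A genome build is the coordinate frame every other object is validated
#' against: an ordered table of chromosome names and lengths in base pairs.
#' All coordinates in the package are 0-based, half-open (BED convention);
#' 1-based inputs (variant tables) are converted at the reader boundary.
#'
#' @param lengths Named numeric vector of chromosome lengths in bp, in the
#'   desired chromosome order. Names must be unique, lengths positive.
#' @return A tibble with columns `chrom` and `length`.
#' @examples
#' genome_build(c(chr1 = 1e6, chr2 = 5e5))
#' @export
genome_build <- function(lengths) {
  if (is.null(names(lengths)) || anyNA(names(lengths)) || any(names(lengths) == "")) {
    abort("`lengths` must be a named vector of chromosome lengths")
  }
  if (anyDuplicated(names(lengths))) abort("chromosome names must be unique")
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    abort("chromosome lengths must be positive and finite")
  }
  tibble(chrom = names(lengths), length = as.numeric(lengths))
}

chrom_lengths <- function(build) setNames(build$length, build$chrom)

check_build <- function(build) {
  if (!is.data.frame(build) || !all(c("chrom", "length") %in% names(build))) {
    abort("`build` must be a genome build tibble with columns chrom, length")
  }
  invisible(build)
}

# Validate an interval table against the coordinate conventions and,
# optionally, a genome build. Returns the input invisibly.
check_intervals <- function(x, build = NULL, what = "intervals") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x))) {
    abort(sprintf("%s must have columns chrom, start, end", what))
  }
  if (nrow(x) == 0) return(invisible(x))
  bad <- which(!(x$start < x$end) | x$start < 0)
  if (length(bad)) {
    abort(sprintf("%s: invalid interval at row %d (need 0 <= start < end)",
                  what, bad[1]))
  }
  if (!is.null(build)) {
    check_build(build)
    lens <- chrom_lengths(build)
    missing <- setdiff(unique(x$chrom), names(lens))
    if (length(missing)) {
      abort(sprintf("%s: chromosome '%s' not in build", what, missing[1]))
    }
    over <- which(x$end > lens[x$chrom])
    if (length(over)) {
      abort(sprintf("%s: interval at row %d exceeds chromosome length",
                    what, over[1]))
    }
  }
  invisible(x)
}

# Column accessor tolerant of absent columns (tibbles warn on `$` misses).
col_or <- function(x, nm, default = NULL) {
  if (nm %in% names(x)) x[[nm]] else default
}
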
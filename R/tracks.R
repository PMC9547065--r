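#' Binned signal track
#'
#' A per-chromosome array of non-negative per-bp signal rates at a fixed bin
#' size: bin `b` of chromosome `c` stores the mean per-bp signal over
#' `[b * bin_size, (b + 1) * bin_size)`. Used for H3K27Ac case/input
#' coverage and any other base-level signal.
#'
#' @param build Genome build.
#' @param bin_size Bin width in bp.
#' @param values Optional named list (one numeric vector per chromosome,
#'   length `ceiling(length / bin_size)`); defaults to all-zero.
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(build, bin_size, values = NULL) {
  check_build(build)
  if (bin_size <= 0) abort("bin_size must be positive")
  lens <- chrom_lengths(build)
  n_bins <- ceiling(lens / bin_size)
  if (is.null(values)) {
    values <- lapply(n_bins, numeric)
  } else {
    miss <- setdiff(names(lens), names(values))
    if (length(miss)) abort(sprintf("values missing chromosome '%s'", miss[1]))
    for (ch in names(lens)) {
      if (length(values[[ch]]) != n_bins[[ch]]) {
        abort(sprintf("values for %s must have %d bins", ch, n_bins[[ch]]))
      }
      if (any(values[[ch]] < 0)) abort("signal values must be non-negative")
    }
    values <- values[names(lens)]
  }
  structure(list(build = build, bin_size = bin_size, values = values),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("<signal_track: %d chromosome(s), bin %d bp>\n",
              nrow(x$build), as.integer(x$bin_size)))
  invisible(x)
}

# Add `rate` per-bp signal over [start, end) of `chrom`; partial bins get
# the length-weighted share. Used by readers and the simulator.
track_add <- function(track, chrom, start, end, rate) {
  bs <- track$bin_size
  v <- track$values[[chrom]]
  if (is.null(v)) abort(sprintf("chromosome '%s' not in track", chrom))
  for (i in seq_along(start)) {
    b0 <- floor(start[i] / bs); b1 <- floor((end[i] - 1) / bs)
    bins <- b0:b1
    lo <- pmax(bins * bs, start[i])
    hi <- pmin((bins + 1) * bs, end[i])
    v[bins + 1] <- v[bins + 1] + rate[i] * (hi - lo) / bs
  }
  track$values[[chrom]] <- v
  track
}

#' Summed signal in a window around a position
#'
#' Sums per-bp signal over the inclusive window `[center - halfwidth,
#' center + halfwidth]` (so a uniform 1.0/bp track gives `2 * halfwidth +
#' 1`). Partial bins contribute in proportion to the overlapped fraction;
#' the window is clipped to the chromosome.
#'
#' @param track A [signal_track()].
#' @param chrom Chromosome name.
#' @param center 0-based position; must lie on the chromosome.
#' @param halfwidth Window half-width in bp (> 0).
#' @return Numeric vector of summed coverage, one value per center.
#' @export
coverage_in_window <- function(track, chrom, center, halfwidth) {
  if (halfwidth <= 0) abort("halfwidth must be positive")
  lens <- chrom_lengths(track$build)
  out <- numeric(length(center))
  for (i in seq_along(center)) {
    len <- lens[[chrom[[min(i, length(chrom))]]]]
    ch <- chrom[[min(i, length(chrom))]]
    if (center[i] < 0 || center[i] >= len) {
      abort(sprintf("center %s is outside chromosome %s", format(center[i]), ch))
    }
    s <- max(center[i] - halfwidth, 0)
    e <- min(center[i] + halfwidth + 1, len)  # inclusive window
    out[i] <- track_sum_one(track, ch, s, e)
  }
  out
}

track_sum_one <- function(track, chrom, start, end) {
  if (end <= start) return(0)
  bs <- track$bin_size
  v <- track$values[[chrom]]
  b0 <- floor(start / bs); b1 <- floor((end - 1) / bs)
  bins <- b0:b1
  lo <- pmax(bins * bs, start)
  hi <- pmin((bins + 1) * bs, end)
  sum(v[bins + 1] * (hi - lo))
}

# Summed per-bp signal over each interval (half-open).
track_sum <- function(track, intervals) {
  vapply(seq_len(nrow(intervals)), function(i) {
    track_sum_one(track, intervals$chrom[i], intervals$start[i], intervals$end[i])
  }, numeric(1))
}

# Mean per-bp signal of a track rebinned to `bin_size`, for one chromosome.
track_rebin <- function(track, chrom, bin_size) {
  len <- chrom_lengths(track$build)[[chrom]]
  n <- ceiling(len / bin_size)
  starts <- (seq_len(n) - 1) * bin_size
  ends <- pmin(starts + bin_size, len)
  sums <- vapply(seq_len(n), function(i) track_sum_one(track, chrom, starts[i], ends[i]),
                 numeric(1))
  sums / (ends - starts)
}

#' Read / write bedGraph signal
#'
#' bedGraph records (`chrom start end value`, 0-based half-open) are
#' rasterized onto the track's bins; each bin stores the length-weighted
#' mean per-bp value. Writing merges runs of equal-valued bins.
#'
#' @param path File path.
#' @param build Genome build.
#' @param bin_size Track bin size in bp.
#' @return A [signal_track()].
#' @export
read_bedgraph <- function(path, build, bin_size) {
  lf <- read_tab_lines(path)
  tr <- signal_track(build, bin_size)
  if (!length(lf$lines)) return(tr)
  parts <- strsplit(lf$lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 4)) {
    abort(sprintf("malformed bedGraph line %d in %s",
                  lf$numbers[which(lengths(parts) < 4)[1]], path))
  }
  chrom <- vapply(parts, `[[`, character(1), 1)
  start <- as.numeric(vapply(parts, `[[`, character(1), 2))
  end <- as.numeric(vapply(parts, `[[`, character(1), 3))
  val <- as.numeric(vapply(parts, `[[`, character(1), 4))
  check_intervals(tibble(chrom = chrom, start = start, end = end), build,
                  sprintf("bedGraph %s", path))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    tr <- track_add(tr, ch, start[sel], end[sel], val[sel])
  }
  tr
}

#' @rdname read_bedgraph
#' @param track Track to write.
#' @param provenance Emit the `#chromhub` header line.
#' @export
write_bedgraph <- function(track, path, provenance = TRUE) {
  bs <- track$bin_size
  lens <- chrom_lengths(track$build)
  lines <- if (provenance) PROVENANCE_HEADER else character()
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    if (!length(v)) next
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- c(0, ends_bin[-length(ends_bin)])
    keep <- r$values != 0
    if (!any(keep)) next
    lines <- c(lines, paste(ch,
                            format_coord(starts_bin[keep] * bs),
                            format_coord(pmin(ends_bin[keep] * bs, lens[[ch]])),
                            format(r$values[keep], scientific = FALSE, trim = TRUE),
                            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
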
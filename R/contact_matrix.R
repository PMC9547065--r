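#' Binned cis contact matrix
#'
#' A square, symmetric, non-negative matrix of raw or balanced contact
#' counts for one chromosome at a fixed bin size, with a valid-bin mask.
#' Masked bins are excluded from every downstream statistic.
#'
#' @param mat Square numeric matrix (bin x bin contact counts).
#' @param chrom Chromosome name.
#' @param bin_size Bin width in bp.
#' @param build Optional genome build (checks bin count).
#' @param mask Optional logical valid-bin vector; defaults to bins with any
#'   signal.
#' @param tol Symmetry tolerance.
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(mat, chrom, bin_size, build = NULL, mask = NULL,
                           tol = 1e-8) {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat)) abort("matrix must be square")
  if (any(mat < 0)) abort("contact counts must be non-negative")
  if (max(abs(mat - t(mat))) > tol * max(1, max(abs(mat)))) {
    abort("matrix must be symmetric")
  }
  if (!is.null(build)) {
    n_expected <- ceiling(chrom_lengths(build)[[chrom]] / bin_size)
    if (nrow(mat) != n_expected) {
      abort(sprintf("expected %d bins for %s at %d bp, got %d",
                    n_expected, chrom, as.integer(bin_size), nrow(mat)))
    }
  }
  if (is.null(mask)) mask <- rowSums(mat) > 0
  if (length(mask) != nrow(mat)) abort("mask length must equal bin count")
  structure(list(mat = mat, chrom = chrom, bin_size = bin_size, mask = mask),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix: %s, %d bins of %d bp, %d valid>\n",
              x$chrom, nrow(x$mat), as.integer(x$bin_size), sum(x$mask)))
  invisible(x)
}

#' Expected contact count by genomic separation
#'
#' Entry `d + 1` is the mean over valid pixels at separation `d` bins
#' (`d * bin_size` bp). Separations where every pixel is masked are
#' `NA` (undefined), never zero.
#'
#' @param cm A [contact_matrix()].
#' @return Numeric vector of length `n_bins`.
#' @export
expected_by_distance <- function(cm) {
  n <- nrow(cm$mat)
  out <- rep(NA_real_, n)
  for (d in 0:(n - 1)) {
    i <- seq_len(n - d)
    ok <- cm$mask[i] & cm$mask[i + d]
    if (any(ok)) {
      out[d + 1] <- mean(cm$mat[cbind(i[ok], i[ok] + d)])
    }
  }
  out
}

# Sum-aggregate a contact matrix to a coarser bin size (integer factor).
coarsen_matrix <- function(cm, factor) {
  if (factor == 1) return(cm)
  n <- nrow(cm$mat)
  n2 <- ceiling(n / factor)
  grp <- rep(seq_len(n2), each = factor)[seq_len(n)]
  agg <- rowsum(cm$mat, grp)
  agg <- t(rowsum(t(agg), grp))
  mask2 <- as.logical(tapply(cm$mask, grp, any))
  contact_matrix(agg, cm$chrom, cm$bin_size * factor, mask = mask2)
}

#' A/B compartment call from a contact matrix
#'
#' The canonical principal-component method: the observed/expected matrix
#' over valid bins is turned into a Pearson correlation matrix whose leading
#' eigenvector separates the two long-range contact "checkerboard" groups.
#' The eigenvector sign (arbitrary in PCA) is oriented with an external
#' reference signal (gene density or an active mark such as H3K27Ac): bins
#' with above-median reference signal average positive, and positive bins
#' are labelled `A`, negative `B`.
#'
#' @param cm A [contact_matrix()].
#' @param reference A [signal_track()] or a numeric per-bin vector (at the
#'   compartment bin size) used to orient the eigenvector.
#' @param bin_size Compartment resolution in bp (default 100 kb); the matrix
#'   is sum-aggregated to this resolution first.
#' @return An object of class `compartment_call` with per-bin eigenvector
#'   values/labels and merged same-label segments.
#' @export
compartment_call <- function(cm, reference, bin_size = 1e5) {
  if (bin_size %% cm$bin_size != 0) {
    abort("compartment bin_size must be a multiple of the matrix bin size")
  }
  cmc <- coarsen_matrix(cm, bin_size / cm$bin_size)
  n <- nrow(cmc$mat)
  valid <- which(cmc$mask)
  if (length(valid) < 10) abort("need at least 10 valid bins for a compartment call")
  expd <- expected_by_distance(cmc)
  d <- abs(outer(valid, valid, "-"))
  oe <- cmc$mat[valid, valid, drop = FALSE] / matrix(expd[d + 1], nrow = length(valid))
  oe[!is.finite(oe)] <- NA
  suppressWarnings(cc <- cor(oe, use = "pairwise.complete.obs"))
  cc[!is.finite(cc)] <- 0
  if (max(abs(cc[upper.tri(cc)])) < 1e-12) {
    abort("no compartment signal: degenerate correlation matrix")
  }
  ev <- eigen(cc, symmetric = TRUE)
  v <- ev$vectors[, 1]
  if (all(abs(v) < 1e-12)) abort("no compartment signal: null leading eigenvector")
  ref <- if (inherits(reference, "signal_track")) {
    track_rebin(reference, cmc$chrom, bin_size)[valid]
  } else {
    if (length(reference) == n) reference[valid]
    else if (length(reference) == length(valid)) reference
    else abort("reference length must match compartment bins")
  }
  hi <- ref > median(ref)
  if (any(hi) && mean(v[hi]) < 0) v <- -v
  label <- ifelse(v >= 0, "A", "B")
  bins <- tibble(chrom = cmc$chrom,
                 start = (valid - 1) * bin_size,
                 end = valid * bin_size,
                 bin = valid - 1L,
                 eigen = v,
                 label = label)
  seg_grp <- cumsum(c(1L, as.integer(label[-1] != label[-length(label)] |
                                       diff(valid) != 1L)))
  segments <- bins |>
    mutate(.grp = seg_grp) |>
    group_by(.data$.grp) |>
    summarise(chrom = .data$chrom[1], start = min(.data$start),
              end = max(.data$end), label = .data$label[1],
              mean_eigen = mean(.data$eigen), .groups = "drop") |>
    select("chrom", "start", "end", "label", "mean_eigen")
  structure(list(bins = bins, segments = segments, chrom = cmc$chrom,
                 bin_size = bin_size),
            class = "compartment_call")
}

#' @export
print.compartment_call <- function(x, ...) {
  cat(sprintf("<compartment_call: %s, %d bins (%d A / %d B), %d segments>\n",
              x$chrom, nrow(x$bins), sum(x$bins$label == "A"),
              sum(x$bins$label == "B"), nrow(x$segments)))
  invisible(x)
}

#' Segments of one or more compartment calls as a single table
#'
#' @param ... `compartment_call` objects (or a single list of them).
#' @return Tibble of segments (`chrom`, `start`, `end`, `label`).
#' @export
compartment_segments <- function(...) {
  calls <- list(...)
  if (length(calls) == 1 && is.list(calls[[1]]) &&
      !inherits(calls[[1]], "compartment_call")) {
    calls <- calls[[1]]
  }
  bind_rows(lapply(calls, function(x) x$segments))
}

#' Diamond insulation score
#'
#' For bin `i` and a window of `w = window_bp / bin_size` bins, the raw
#' score is the mean of valid pixels in the off-diagonal diamond
#' `{i-w..i-1} x {i+1..i+w}` (contacts crossing bin `i`); the reported value
#' is `log2(raw / chromosome-wide mean raw)`, so a constant matrix scores 0
#' everywhere and insulation minima mark domain boundaries. The first and
#' last `w` bins are invalid.
#'
#' @param cm A [contact_matrix()].
#' @param window_bp Diamond window in bp; must be a multiple of the bin
#'   size (default 100 kb).
#' @return A tibble of class `insulation_track` with columns `chrom`,
#'   `start`, `end`, `bin`, `score`, `valid`.
#' @export
diamond_insulation <- function(cm, window_bp = 1e5) {
  bs <- cm$bin_size
  if (window_bp %% bs != 0) abort("window_bp must be a multiple of bin_size")
  w <- as.integer(window_bp / bs)
  n <- nrow(cm$mat)
  if (w < 1) abort("window must span at least one bin")
  if (2 * w + 1 > n) abort("window larger than chromosome")
  sums <- numeric(n)
  cnts <- numeric(n)
  for (a in seq_len(w)) {
    for (b in seq_len(w)) {
      i <- (a + 1):(n - b)
      ok <- cm$mask[i - a] & cm$mask[i + b]
      vals <- cm$mat[cbind(i - a, i + b)]
      sums[i] <- sums[i] + ifelse(ok, vals, 0)
      cnts[i] <- cnts[i] + as.numeric(ok)
    }
  }
  in_range <- seq_len(n) > w & seq_len(n) <= n - w
  valid <- in_range & cnts > 0
  raw <- rep(NA_real_, n)
  raw[valid] <- sums[valid] / cnts[valid]
  gmean <- mean(raw[valid])
  score <- rep(NA_real_, n)
  if (is.finite(gmean) && gmean > 0) score[valid] <- log2(raw[valid] / gmean)
  valid <- valid & is.finite(score)
  out <- tibble(chrom = cm$chrom,
                start = (seq_len(n) - 1) * bs,
                end = seq_len(n) * bs,
                bin = seq_len(n) - 1L,
                score = score,
                valid = valid)
  attr(out, "bin_size") <- bs
  attr(out, "window_bp") <- window_bp
  class(out) <- c("insulation_track", class(out))
  out
}

#' Per-TAD boundary insulation
#'
#' For each TAD, the mean of the insulation values at the two bins
#' containing its start and end coordinates. Invalid boundary bins are
#' skipped; a TAD whose two boundary bins are both invalid is flagged.
#'
#' @param tads Interval table of TADs.
#' @param insulation An insulation track from [diamond_insulation()] (or
#'   several row-bound together for multiple chromosomes).
#' @return Tibble with one row per TAD: `boundary_score`, `n_valid_bins`,
#'   `flag_invalid`.
#' @export
tad_boundary_insulation <- function(tads, insulation) {
  bs <- attr(insulation, "bin_size") %||%
    (insulation$end[1] - insulation$start[1])
  key <- paste(insulation$chrom, insulation$bin)
  score_of <- function(chrom, pos) {
    b <- floor(pos / bs)
    i <- match(paste(chrom, b), key)
    ifelse(is.na(i), NA_real_,
           ifelse(insulation$valid[i], insulation$score[i], NA_real_))
  }
  s1 <- score_of(tads$chrom, tads$start)
  s2 <- score_of(tads$chrom, tads$end)
  both <- cbind(s1, s2)
  n_valid <- rowSums(!is.na(both))
  tibble(chrom = tads$chrom, start = tads$start, end = tads$end,
         boundary_score = rowMeans(both, na.rm = TRUE),
         n_valid_bins = as.integer(n_valid),
         flag_invalid = n_valid == 0L)
}

#' Read / write a contact matrix in triplet text format
#'
#' Plain-text format: `#chrom=`, `#bin_size=`, `#n_bins=` header lines
#' followed by tab-separated `bin_i bin_j count` triplets (0-based, upper
#' triangle including the diagonal).
#'
#' @param path File path.
#' @param build Optional genome build.
#' @return A [contact_matrix()].
#' @export
read_contact_matrix <- function(path, build = NULL) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get_hdr <- function(k) {
    h <- hdr[startsWith(hdr, paste0("#", k, "="))]
    if (!length(h)) abort(sprintf("matrix file %s missing #%s= header", path, k))
    sub(paste0("^#", k, "="), "", h[1])
  }
  chrom <- get_hdr("chrom")
  bin_size <- as.numeric(get_hdr("bin_size"))
  n <- as.integer(get_hdr("n_bins"))
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  mat <- matrix(0, n, n)
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    i <- as.integer(vapply(parts, `[[`, character(1), 1)) + 1L
    j <- as.integer(vapply(parts, `[[`, character(1), 2)) + 1L
    v <- as.numeric(vapply(parts, `[[`, character(1), 3))
    mat[cbind(i, j)] <- v
    mat[cbind(j, i)] <- v
  }
  contact_matrix(mat, chrom, bin_size, build = build)
}

#' @rdname read_contact_matrix
#' @param cm Contact matrix to write.
#' @param provenance Emit the `#chromhub` header line.
#' @export
write_contact_matrix <- function(cm, path, provenance = TRUE) {
  n <- nrow(cm$mat)
  idx <- which(upper.tri(cm$mat, diag = TRUE) & cm$mat != 0, arr.ind = TRUE)
  lines <- c(if (provenance) PROVENANCE_HEADER,
             sprintf("#chrom=%s", cm$chrom),
             sprintf("#bin_size=%s", format_coord(cm$bin_size)),
             sprintf("#n_bins=%d", n))
  if (nrow(idx)) {
    lines <- c(lines, paste(idx[, 1] - 1L, idx[, 2] - 1L,
                            format(cm$mat[idx], scientific = FALSE, trim = TRUE),
                            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
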
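PROVENANCE_HEADER <- "#chromhub v1"

read_tab_lines <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  list(lines = lines[keep], numbers = which(keep))
}

#' Read a BED file
#'
#' BED3+ with tab separation; coordinates are 0-based half-open per the BED
#' standard. Optional 4th (name) and 5th (score) columns are kept. Lines
#' starting with `#` are ignored. Malformed lines and chromosomes absent
#' from the build are rejected with the offending line number.
#'
#' @param path File path.
#' @param build Optional genome build to validate against.
#' @return A tibble with columns `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`. Input order is preserved.
#' @export
read_bed <- function(path, build = NULL) {
  lf <- read_tab_lines(path)
  if (!length(lf$lines)) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  parts <- strsplit(lf$lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 3)) {
    abort(sprintf("malformed BED line %d in %s (fewer than 3 fields)",
                  lf$numbers[which(ncols < 3)[1]], path))
  }
  nc <- min(ncols)
  get <- function(i) vapply(parts, `[[`, character(1), i)
  out <- tibble(chrom = get(1),
                start = suppressWarnings(as.numeric(get(2))),
                end = suppressWarnings(as.numeric(get(3))))
  if (nc >= 4) out$name <- get(4)
  if (nc >= 5) out$score <- suppressWarnings(as.numeric(get(5)))
  if (nc >= 6) out$strand <- get(6)
  bad <- which(is.na(out$start) | is.na(out$end))
  if (length(bad)) {
    abort(sprintf("malformed BED line %d in %s (non-numeric coordinates)",
                  lf$numbers[bad[1]], path))
  }
  bad <- which(!(out$start < out$end))
  if (length(bad)) {
    abort(sprintf("malformed BED line %d in %s (empty or inverted interval)",
                  lf$numbers[bad[1]], path))
  }
  check_intervals(out, build, sprintf("BED file %s", path))
  out
}

#' Write a BED file
#'
#' @param x Interval table; extra columns `name`, `score`, `strand` are
#'   written when present.
#' @param path Output path.
#' @param provenance Emit the `#chromhub` header line (toggle off for
#'   strict-format consumers).
#' @export
write_bed <- function(x, path, provenance = TRUE) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  # BED columns are positional: stop at the first absent one
  want <- c("chrom", "start", "end", "name", "score", "strand")
  upto <- max(which(want %in% cols & cumsum(!(want %in% cols)) == 0))
  cols <- want[seq_len(upto)]
  body <- do.call(paste, c(lapply(cols, function(cl) format_coord(x[[cl]])),
                           sep = "\t"))
  lines <- c(if (provenance) PROVENANCE_HEADER, body)
  writeLines(lines, path)
  invisible(path)
}

format_coord <- function(v) {
  if (is.numeric(v)) format(v, scientific = FALSE, trim = TRUE) else as.character(v)
}

#' Read a BEDPE loop file
#'
#' Six or more tab-separated columns (`chrom1 start1 end1 chrom2 start2 end2
#' [name] [score]`); the 8th column, when present, is interpreted as the
#' loop q-value. Feet are stored in canonical order. Trans (inter-
#' chromosomal) records are rejected under `strict_cis = TRUE` (default) or
#' dropped with a warning otherwise.
#'
#' @param path File path.
#' @param build Optional genome build.
#' @param strict_cis Error on trans records instead of dropping them.
#' @return A loop table (see [loop_table()]).
#' @export
read_bedpe <- function(path, build = NULL, strict_cis = TRUE) {
  lf <- read_tab_lines(path)
  if (!length(lf$lines)) {
    return(loop_table(character(), numeric(), numeric(), numeric(), numeric()))
  }
  parts <- strsplit(lf$lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 6)) {
    abort(sprintf("malformed BEDPE line %d in %s (fewer than 6 fields)",
                  lf$numbers[which(ncols < 6)[1]], path))
  }
  get <- function(i) vapply(parts, function(p) if (length(p) >= i) p[[i]] else NA_character_, character(1))
  c1 <- get(1); c2 <- get(4)
  trans <- c1 != c2
  if (any(trans)) {
    if (strict_cis) {
      abort(sprintf("trans pair at line %d in %s (%s vs %s); loops must be cis",
                    lf$numbers[which(trans)[1]], path,
                    c1[which(trans)[1]], c2[which(trans)[1]]))
    }
    warn(sprintf("dropping %d trans record(s) from %s", sum(trans), path))
  }
  keep <- !trans
  q <- suppressWarnings(as.numeric(get(8)))
  loop_table(chrom = c1[keep],
             startA = as.numeric(get(2))[keep], endA = as.numeric(get(3))[keep],
             startB = as.numeric(get(5))[keep], endB = as.numeric(get(6))[keep],
             qvalue = q[keep], build = build)
}

#' Write a BEDPE loop file
#'
#' @param loops Loop table.
#' @param path Output path.
#' @param provenance Emit the `#chromhub` header line.
#' @export
write_bedpe <- function(loops, path, provenance = TRUE) {
  name <- if ("loop_id" %in% names(loops)) loops$loop_id else rep(".", nrow(loops))
  score <- ifelse(is.na(loops$qvalue), ".", format(loops$qvalue, scientific = FALSE, trim = TRUE))
  body <- paste(loops$chrom, format_coord(loops$startA), format_coord(loops$endA),
                loops$chrom, format_coord(loops$startB), format_coord(loops$endB),
                name, score, sep = "\t")
  writeLines(c(if (provenance) PROVENANCE_HEADER, body), path)
  invisible(path)
}

#' Read a gene table
#'
#' Tab-separated with a header; required columns `gene_id`, `symbol`,
#' `chrom`, `strand`, `start`, `end`, `tss` (all coordinates 0-based
#' half-open; `tss` a 0-based position), optional `expression` (FPKM-like)
#' and `set_labels` (comma-separated gene-set tags).
#'
#' @param path File path.
#' @param build Optional genome build.
#' @return A gene tibble.
#' @export
read_genes <- function(path, build = NULL) {
  g <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  need <- c("gene_id", "symbol", "chrom", "strand", "start", "end", "tss")
  miss <- setdiff(need, names(g))
  if (length(miss)) abort(sprintf("gene table missing column '%s'", miss[1]))
  if (!"expression" %in% names(g)) g$expression <- NA_real_
  if (!"set_labels" %in% names(g)) g$set_labels <- ""
  g$set_labels[is.na(g$set_labels)] <- ""
  check_intervals(g, build, "gene bodies")
  bad <- which(g$tss < g$start | g$tss >= g$end)
  if (length(bad)) {
    abort(sprintf("gene table row %d: tss outside gene body", bad[1]))
  }
  as_tibble(g)
}

#' @rdname read_genes
#' @param genes Gene tibble to write.
#' @export
write_genes <- function(genes, path) {
  readr::write_tsv(genes, path, progress = FALSE)
  invisible(path)
}

#' Read an eQTL variant-eGene table
#'
#' Tab-separated with header: `variant_id`, `chrom`, `pos` (1-based, as
#' variant tables conventionally are; converted to 0-based internally),
#' `egene_id`, optional `tags`. Each row is one variant-eGene pair; all
#' downstream classifications operate at pair level.
#'
#' @param path File path.
#' @param build Optional genome build.
#' @param genes Optional gene table; every `egene_id` must resolve in it.
#' @return Tibble with `variant_id`, `chrom`, `pos` (0-based), `egene_id`,
#'   `tags`.
#' @export
read_eqtls <- function(path, build = NULL, genes = NULL) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  need <- c("variant_id", "chrom", "pos", "egene_id")
  miss <- setdiff(need, names(x))
  if (length(miss)) abort(sprintf("eQTL table missing column '%s'", miss[1]))
  x$pos <- x$pos - 1  # 1-based -> 0-based
  if (!"tags" %in% names(x)) x$tags <- ""
  x$tags[is.na(x$tags)] <- ""
  if (!is.null(build)) {
    check_intervals(point_intervals(x$chrom, x$pos), build, "eQTL positions")
  }
  if (!is.null(genes)) {
    missing_genes <- setdiff(x$egene_id, genes$gene_id)
    if (length(missing_genes)) {
      abort(sprintf("eGene '%s' not present in gene table", missing_genes[1]))
    }
  }
  as_tibble(x)
}

#' @rdname read_eqtls
#' @param eqtls eQTL tibble (0-based `pos`) to write; converted back to
#'   1-based on output.
#' @export
write_eqtls <- function(eqtls, path) {
  out <- eqtls
  out$pos <- out$pos + 1
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read GWAS lead- and LD-variant tables
#'
#' Lead table columns: `rsid`, `chrom`, `pos` (1-based), `locus`, `disease`.
#' LD table columns: `rsid`, `chrom`, `pos` (1-based), `lead_rsid`, `r2`,
#' `maf`. Positions are converted to 0-based.
#'
#' @param path File path.
#' @param build Optional genome build.
#' @return A tibble; positions 0-based.
#' @export
read_lead_variants <- function(path, build = NULL) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  need <- c("rsid", "chrom", "pos", "locus", "disease")
  miss <- setdiff(need, names(x))
  if (length(miss)) abort(sprintf("lead-variant table missing column '%s'", miss[1]))
  x$pos <- x$pos - 1
  if (!is.null(build)) {
    check_intervals(point_intervals(x$chrom, x$pos), build, "lead variants")
  }
  as_tibble(x)
}

#' @rdname read_lead_variants
#' @export
read_ld_variants <- function(path, build = NULL) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  need <- c("rsid", "chrom", "pos", "lead_rsid", "r2", "maf")
  miss <- setdiff(need, names(x))
  if (length(miss)) abort(sprintf("LD-variant table missing column '%s'", miss[1]))
  x$pos <- x$pos - 1
  if (!is.null(build)) {
    check_intervals(point_intervals(x$chrom, x$pos), build, "LD variants")
  }
  as_tibble(x)
}

write_variants <- function(x, path) {
  out <- x
  out$pos <- out$pos + 1
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
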
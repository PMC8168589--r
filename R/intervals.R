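# Genomic intervals are plain data.frames with 0-based half-open
# coordinates (columns chrom/start/end and optional name/score/strand).
# Interval algebra is delegated to GenomicRanges behind these wrappers;
# the 0-based <-> 1-based conversion happens in exactly one place.

#' Construct a genomic interval table
#'
#' @param chrom,start,end vectors defining 0-based half-open intervals.
#' @param name,score,strand optional BED6 fields.
#' @return data.frame with columns chrom, start, end, name, score, strand.
#' @export
intervals <- function(chrom, start, end, name = ".", score = 0,
                      strand = ".") {
  n <- length(chrom)
  out <- data.frame(chrom = as.character(chrom),
                    start = as.numeric(start), end = as.numeric(end),
                    name = rep_len(as.character(name), n),
                    score = rep_len(as.numeric(score), n),
                    strand = rep_len(as.character(strand), n),
                    stringsAsFactors = FALSE)
  if (any(out$start < 0) || any(out$start >= out$end))
    stopf("invalid interval: require 0 <= start < end")
  out
}

validate_intervals <- function(x, assembly = NULL, what = "interval") {
  if (any(x$start < 0) || any(x$start >= x$end))
    stopf("invalid %s: require 0 <= start < end", what)
  if (!is.null(assembly)) {
    idx <- chrom_rank(assembly, x$chrom)
    if (anyNA(idx))
      stopf("unknown chromosome in %s: %s", what, x$chrom[is.na(idx)][1])
    if (any(x$end > chrom_length(assembly, x$chrom)))
      stopf("%s extends past chromosome end", what)
  }
  invisible(x)
}

# 0-based half-open data.frame -> GRanges (1-based closed) and back
as_granges0 <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1, end = x$end))
}

from_granges0 <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

sort_intervals <- function(x) {
  out <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a BED or bedGraph file
#'
#' BED3/BED6 files yield an interval table; bedGraph files yield a signal
#' track (`chrom`, `start`, `end`, `value`) whose `bin_size` attribute is
#' set when all intervals share one width (fixed-step binned track).
#' Coordinates are 0-based half-open, the native convention of both formats.
#'
#' @param path input file (plain text).
#' @param kind `"bed"` or `"bedgraph"`.
#' @param assembly optional [genome_assembly()] used to validate coordinates.
#' @return data.frame, sorted within chromosome; for `kind = "bedgraph"`,
#'   class `signal_track`.
#' @export
read_intervals <- function(path, kind = c("bed", "bedgraph"), assembly = NULL) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  keep <- nzchar(lines) & !grepl("^(#|track|browser)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0)
    return(if (kind == "bed") intervals(character(), numeric(), numeric() + 1)[0, ]
           else signal_track(character(), numeric(), numeric() + 1, numeric())[0, ])
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- vapply(parts, length, 0L)
  need <- if (kind == "bed") 3L else 4L
  if (any(ncols < need))
    stopf("line %d: expected >= %d columns", lineno[which(ncols < need)[1]], need)
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad))
    stopf("line %d: invalid interval (%s)", lineno[bad[1]], lines[bad[1]])
  if (!is.null(assembly)) {
    idx <- chrom_rank(assembly, chrom)
    if (anyNA(idx))
      stopf("line %d: unknown chromosome %s", lineno[is.na(idx)][1],
            chrom[is.na(idx)][1])
    if (any(end > chrom_length(assembly, chrom))) {
      bad <- which(end > chrom_length(assembly, chrom))[1]
      stopf("line %d: interval extends past chromosome end", lineno[bad])
    }
  }
  if (kind == "bed") {
    out <- intervals(chrom, start, end,
                     name = if (all(ncols >= 4)) vapply(parts, `[[`, "", 4L) else ".",
                     score = if (all(ncols >= 5))
                       suppressWarnings(as.numeric(vapply(parts, `[[`, "", 5L))) else 0,
                     strand = if (all(ncols >= 6)) vapply(parts, `[[`, "", 6L) else ".")
    sort_intervals(out)
  } else {
    value <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 4L)))
    if (anyNA(value)) stopf("non-numeric bedGraph value")
    sort_intervals(signal_track(chrom, start, end, value))
  }
}

#' Construct a signal track
#'
#' A signal track is a sorted, non-overlapping set of intervals each
#' carrying a numeric value (a bedGraph in memory). When every interval has
#' the same width the track is treated as fixed-step binned and the width is
#' recorded as attribute `bin_size`.
#'
#' @param chrom,start,end 0-based half-open intervals.
#' @param value finite numeric values.
#' @return data.frame of class `signal_track`.
#' @export
signal_track <- function(chrom, start, end, value) {
  if (any(!is.finite(value))) stopf("signal values must be finite")
  out <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                    end = as.numeric(end), value = as.numeric(value),
                    stringsAsFactors = FALSE)
  if (any(out$start < 0) || any(out$start >= out$end))
    stopf("invalid signal interval")
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  sp <- split(seq_len(nrow(out)), out$chrom)
  for (ii in sp) {
    if (length(ii) > 1 && any(out$start[ii][-1] < out$end[ii][-length(ii)]))
      stopf("signal track intervals overlap within a chromosome")
  }
  w <- unique(out$end - out$start)
  if (length(w) == 1L) attr(out, "bin_size") <- w
  class(out) <- c("signal_track", "data.frame")
  out
}

#' Write intervals or a signal track to BED / bedGraph
#' @param x interval table (BED6 written) or `signal_track` (bedGraph).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path) {
  if (inherits(x, "signal_track")) {
    writeLines(sprintf("%s\t%d\t%d\t%s", x$chrom, as.integer(x$start),
                       as.integer(x$end), format(x$value, trim = TRUE,
                                                 scientific = FALSE)), path)
  } else {
    name <- if ("name" %in% names(x)) x$name else "."
    score <- if ("score" %in% names(x)) x$score else 0
    strand <- if ("strand" %in% names(x)) x$strand else "."
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s", x$chrom, as.integer(x$start),
                       as.integer(x$end), name,
                       format(score, trim = TRUE, scientific = FALSE), strand),
               path)
  }
  invisible(path)
}

#' Merge intervals closer than a gap
#'
#' Two intervals on the same chromosome are merged when the gap between them
#' is at most `max_gap` bp (inclusive "within"); overlapping or bookended
#' intervals always merge. The operation is idempotent and
#' coverage-preserving.
#'
#' @param x interval table.
#' @param max_gap maximum separating gap in bp (>= 0).
#' @return Sorted, non-overlapping interval table (chrom/start/end only).
#' @export
merge_intervals <- function(x, max_gap = 0) {
  if (max_gap < 0) stopf("max_gap must be >= 0")
  if (nrow(x) == 0) return(x[, c("chrom", "start", "end")])
  gr <- GenomicRanges::reduce(as_granges0(x), min.gapwidth = max_gap + 1)
  out <- from_granges0(gr)
  sort_intervals(out)
}

#' Remove or trim intervals overlapping a blacklist
#'
#' @param x interval table.
#' @param blacklist interval table of excluded regions.
#' @param mode `"drop"` removes any interval with >= 1 bp of overlap;
#'   `"trim"` clips the overlapping parts (an interval may split).
#' @return Filtered interval table.
#' @export
subtract_blacklist <- function(x, blacklist, mode = c("drop", "trim")) {
  mode <- match.arg(mode)
  if (nrow(x) == 0 || is.null(blacklist) || nrow(blacklist) == 0) return(x)
  qgr <- as_granges0(x)
  bgr <- GenomicRanges::reduce(as_granges0(blacklist))
  if (mode == "drop") {
    hit <- IRanges::overlapsAny(qgr, bgr)
    out <- x[!hit, , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  pieces <- GenomicRanges::setdiff(qgr, bgr)
  hits <- GenomicRanges::findOverlaps(pieces, qgr)
  kept <- GenomicRanges::pintersect(pieces[S4Vectors::queryHits(hits)],
                                    qgr[S4Vectors::subjectHits(hits)])
  out <- from_granges0(kept)
  extra <- setdiff(names(x), c("chrom", "start", "end"))
  for (col in extra) out[[col]] <- x[[col]][S4Vectors::subjectHits(hits)]
  sort_intervals(out)
}

# logical: does each interval of a overlap any interval of b?
overlaps_any <- function(a, b) {
  if (nrow(a) == 0) return(logical(0))
  if (is.null(b) || nrow(b) == 0) return(rep(FALSE, nrow(a)))
  IRanges::overlapsAny(as_granges0(a), as_granges0(b))
}

# total bp of a covered by b
overlap_bp <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  inter <- GenomicRanges::intersect(GenomicRanges::reduce(as_granges0(a)),
                                    GenomicRanges::reduce(as_granges0(b)))
  sum(GenomicRanges::width(inter))
}

# Mean track value over a set of intervals, weighting each overlapping
# track bin by the overlapped width.
track_mean_over <- function(track, query) {
  if (nrow(query) == 0) return(NaN)
  tgr <- as_granges0(track)
  qgr <- GenomicRanges::reduce(as_granges0(query))
  hits <- GenomicRanges::findOverlaps(tgr, qgr)
  if (length(hits) == 0) return(NaN)
  ov <- GenomicRanges::pintersect(tgr[S4Vectors::queryHits(hits)],
                                  qgr[S4Vectors::subjectHits(hits)])
  w <- GenomicRanges::width(ov)
  v <- track$value[S4Vectors::queryHits(hits)]
  sum(v * w) / sum(w)
}
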
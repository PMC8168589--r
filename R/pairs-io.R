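# Valid-pairs I/O. A pairs table is a data.frame with columns
# chrom1/pos1/chrom2/pos2 (+ optional strand1/strand2), one row per valid
# Hi-C contact, canonically ordered so that (chrom1, pos1) <= (chrom2, pos2)
# under the assembly's chromosome order. Positions are 0-based bp.

#' Canonically order a pairs table
#'
#' Swaps the two sides of every record so that the (chromosome rank,
#' position) of side 1 is never greater than that of side 2.
#'
#' @param pairs pairs data.frame.
#' @param assembly [genome_assembly()] defining the chromosome order.
#' @return The reordered pairs table.
#' @export
canonicalize_pairs <- function(pairs, assembly) {
  r1 <- chrom_rank(assembly, pairs$chrom1)
  r2 <- chrom_rank(assembly, pairs$chrom2)
  if (anyNA(r1) || anyNA(r2))
    stopf("unknown chromosome in pairs: %s",
          c(pairs$chrom1[is.na(r1)], pairs$chrom2[is.na(r2)])[1])
  swap <- r1 > r2 | (r1 == r2 & pairs$pos1 > pairs$pos2)
  if (any(swap)) {
    tmp_c <- pairs$chrom1[swap]; tmp_p <- pairs$pos1[swap]
    pairs$chrom1[swap] <- pairs$chrom2[swap]
    pairs$pos1[swap] <- pairs$pos2[swap]
    pairs$chrom2[swap] <- tmp_c
    pairs$pos2[swap] <- tmp_p
    if (all(c("strand1", "strand2") %in% names(pairs))) {
      tmp_s <- pairs$strand1[swap]
      pairs$strand1[swap] <- pairs$strand2[swap]
      pairs$strand2[swap] <- tmp_s
    }
  }
  pairs
}

#' Read a 4DN-style .pairs file
#'
#' Accepts the 4DN text dialect: `#`-prefixed header lines followed by
#' whitespace-separated columns `readID chrom1 pos1 chrom2 pos2
#' [strand1 strand2]`. Gzip-compressed files are read transparently.
#' Records are canonicalized; positions are converted to the package's
#' 0-based convention according to `pairs_base`.
#'
#' @param path input .pairs file (optionally .gz).
#' @param assembly [genome_assembly()] for validation and chromosome order.
#' @param namespace_filter optional namespace tag(s); records with either
#'   side outside the filter are dropped (count reported in attributes).
#' @param pairs_base 0 or 1: coordinate base of the input file.
#' @param on_unknown `"error"` (default) or `"skip"` for records on
#'   chromosomes absent from the assembly; skipped records are counted.
#' @return Pairs data.frame with attributes `n_read`, `n_dropped_namespace`,
#'   `n_skipped_unknown`.
#' @export
read_pairs <- function(path, assembly, namespace_filter = NULL,
                       pairs_base = 0, on_unknown = c("error", "skip")) {
  on_unknown <- match.arg(on_unknown)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0) {
    out <- data.frame(chrom1 = character(), pos1 = numeric(),
                      chrom2 = character(), pos2 = numeric(),
                      strand1 = character(), strand2 = character(),
                      stringsAsFactors = FALSE)
    attr(out, "n_read") <- 0L
    return(out)
  }
  parts <- strsplit(body, "[ \t]+")
  ncols <- vapply(parts, length, 0L)
  if (any(ncols < 5L))
    stopf("malformed pairs record: %s", body[which(ncols < 5L)[1]])
  pairs <- data.frame(
    chrom1 = vapply(parts, `[[`, "", 2L),
    pos1 = as.numeric(vapply(parts, `[[`, "", 3L)),
    chrom2 = vapply(parts, `[[`, "", 4L),
    pos2 = as.numeric(vapply(parts, `[[`, "", 5L)),
    strand1 = if (all(ncols >= 7L)) vapply(parts, `[[`, "", 6L) else ".",
    strand2 = if (all(ncols >= 7L)) vapply(parts, `[[`, "", 7L) else ".",
    stringsAsFactors = FALSE)
  if (pairs_base == 1) {
    pairs$pos1 <- pairs$pos1 - 1
    pairs$pos2 <- pairs$pos2 - 1
  }
  n_read <- nrow(pairs)
  known <- !is.na(chrom_rank(assembly, pairs$chrom1)) &
    !is.na(chrom_rank(assembly, pairs$chrom2))
  n_unknown <- sum(!known)
  if (n_unknown > 0) {
    if (on_unknown == "error")
      stopf("unknown chromosome in pairs file (%d records); use on_unknown = 'skip' to drop them",
            n_unknown)
    warnf("skipped %d pairs on unknown chromosomes", n_unknown)
    pairs <- pairs[known, , drop = FALSE]
  }
  len1 <- chrom_length(assembly, pairs$chrom1)
  len2 <- chrom_length(assembly, pairs$chrom2)
  if (any(pairs$pos1 < 0 | pairs$pos1 >= len1 |
          pairs$pos2 < 0 | pairs$pos2 >= len2))
    stopf("pair position outside chromosome bounds")
  n_ns <- 0L
  if (!is.null(namespace_filter)) {
    ns1 <- assembly$namespace[chrom_rank(assembly, pairs$chrom1)]
    ns2 <- assembly$namespace[chrom_rank(assembly, pairs$chrom2)]
    keep <- ns1 %in% namespace_filter & ns2 %in% namespace_filter
    n_ns <- sum(!keep)
    pairs <- pairs[keep, , drop = FALSE]
  }
  pairs <- canonicalize_pairs(pairs, assembly)
  rownames(pairs) <- NULL
  attr(pairs, "n_read") <- n_read
  attr(pairs, "n_dropped_namespace") <- n_ns
  attr(pairs, "n_skipped_unknown") <- n_unknown
  pairs
}

#' Write a pairs table as a 4DN-style .pairs file
#'
#' Emits a minimal `## pairs format v1.0` header with `#chromsize` lines and
#' one record per row. Read IDs are synthesized; a read/write/read cycle
#' preserves the multiset of (chrom1, pos1, chrom2, pos2, strands).
#'
#' @param pairs pairs data.frame (canonical).
#' @param path output path (`.gz` suffix compresses).
#' @param assembly [genome_assembly()] for the header.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path, assembly) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(c("## pairs format v1.0",
               "#columns: readID chrom1 pos1 chrom2 pos2 strand1 strand2",
               sprintf("#chromsize: %s %d", assembly$chrom,
                       as.integer(assembly$length))), con)
  if (nrow(pairs) > 0) {
    s1 <- if ("strand1" %in% names(pairs)) pairs$strand1 else "."
    s2 <- if ("strand2" %in% names(pairs)) pairs$strand2 else "."
    writeLines(sprintf("r%d\t%s\t%d\t%s\t%d\t%s\t%s", seq_len(nrow(pairs)),
                       pairs$chrom1, as.integer(pairs$pos1), pairs$chrom2,
                       as.integer(pairs$pos2), s1, s2), con)
  }
  invisible(path)
}
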
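#' Construct a genome assembly
#'
#' An assembly is an ordered table of chromosomes with lengths and an
#' optional namespace tag per chromosome. Namespaces separate the sample
#' genome from an exogenous spike-in genome carried in the same coordinate
#' space (e.g. a fish assembly merged with fly chromosomes `2L`, `2R`, ...),
#' so that downstream analyses can be restricted to one genome.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length integer-like vector of chromosome lengths in bp (> 0).
#' @param namespace single tag or per-chromosome tag vector
#'   (default `"target"`).
#' @return A `data.frame` of class `genome_assembly` with columns
#'   `chrom`, `length`, `namespace`, preserving input order.
#' @export
genome_assembly <- function(chrom, length, namespace = "target") {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom))
    stopf("duplicate chromosome name: %s", chrom[duplicated(chrom)][1])
  if (any(!is.finite(length)) || any(length <= 0))
    stopf("chromosome lengths must be positive")
  if (base::length(namespace) == 1L)
    namespace <- rep(namespace, base::length(chrom))
  out <- data.frame(chrom = chrom, length = length,
                    namespace = as.character(namespace),
                    stringsAsFactors = FALSE)
  class(out) <- c("genome_assembly", "data.frame")
  out
}

#' Read a UCSC chrom.sizes file
#'
#' Two tab-separated columns: chromosome name and length. Chromosomes can be
#' assigned namespaces through `namespace_rule`, a named list mapping a tag
#' to the chromosome names it covers; unlisted chromosomes receive
#' `default_namespace`.
#'
#' @param path path to the chrom.sizes file.
#' @param namespace_rule named list, e.g.
#'   `list(spikein = c("2L","2R","3L","3R","4D","XD","YD"))`.
#' @param default_namespace tag for chromosomes not named in the rule.
#' @return A [genome_assembly()] preserving file order.
#' @export
read_chrom_sizes <- function(path, namespace_rule = NULL,
                             default_namespace = "target") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stopf("empty chrom.sizes file: %s", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 2L)
  if (length(bad)) stopf("malformed chrom.sizes line %d: %s", bad[1], lines[bad[1]])
  chrom <- vapply(parts, `[[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(len) || any(len <= 0)) {
    bad <- which(is.na(len) | len <= 0)[1]
    stopf("non-positive or unparsable length at line %d: %s", bad, lines[bad])
  }
  if (anyDuplicated(chrom)) {
    bad <- which(duplicated(chrom))[1]
    stopf("duplicate chromosome at line %d: %s", bad, chrom[bad])
  }
  ns <- rep(default_namespace, length(chrom))
  if (!is.null(namespace_rule)) {
    for (tag in names(namespace_rule))
      ns[chrom %in% namespace_rule[[tag]]] <- tag
  }
  genome_assembly(chrom, len, ns)
}

#' Write an assembly back to chrom.sizes format
#' @param assembly a [genome_assembly()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(assembly, path) {
  writeLines(sprintf("%s\t%d", assembly$chrom, as.integer(assembly$length)), path)
  invisible(path)
}

#' Restrict an assembly to one namespace
#' @param assembly a [genome_assembly()].
#' @param namespace tag to keep.
#' @return The filtered assembly.
#' @export
assembly_subset <- function(assembly, namespace) {
  out <- assembly[assembly$namespace %in% namespace, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("genome_assembly", "data.frame")
  out
}

chrom_rank <- function(assembly, chrom) {
  match(chrom, assembly$chrom)
}

chrom_length <- function(assembly, chrom) {
  assembly$length[match(chrom, assembly$chrom)]
}
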
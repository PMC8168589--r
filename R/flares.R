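# Flare ("hinge-like domain") calling. A flare is a run of positive
# largest-window insulation scores: enriched contacts between loci
# equidistant from a pivot produce a block of elevated diamond means
# centered on the pivot, read out as a positive run in the insulation
# track. Candidate runs are merged across short gaps, blacklist-filtered,
# and passed through an automated width/peak filter (replacing manual
# curation of assembly artifacts); each call records its pivot (the
# maximal-score bin) and peak score.

#' Call flares from positive insulation runs
#'
#' @param track an `insulation_track` with a defined largest-window column.
#' @param blacklist optional interval table; candidates overlapping it are
#'   dropped.
#' @param merge_gap candidates within this gap merge (bp; default 50 kb).
#' @param min_width minimum flare width in bp.
#' @param min_peak minimum peak (maximum in-interval) z score.
#' @param min_peak_log2 minimum peak in centered-log2 units: the z track is
#'   normalized per chromosome, so counting noise alone produces +3 z
#'   excursions on structureless maps; this absolute enrichment criterion
#'   keeps only runs with a real contact excess.
#' @param threshold score threshold defining "positive" (default 0.15 z:
#'   on a per-chromosome z-scored track a literal 0 admits a large share of
#'   background bins, so the default sits just above the background mode;
#'   set to 0 for strict positive-value extraction).
#' @return data.frame of class `flare_set`: `chrom`, `start`, `end`,
#'   `width`, `pivot` (bp midpoint of the maximal-score bin), `peak_score`.
#' @export
call_flares <- function(track, blacklist = NULL, merge_gap = 50e3,
                        min_width = 50e3, min_peak = 0.5,
                        min_peak_log2 = 0.15, threshold = 0.15) {
  s <- track$largest
  s2 <- track$largest_log2
  res <- track$resolution
  pos <- !is.na(s) & s > threshold
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      width = numeric(), pivot = numeric(),
                      peak_score = numeric(), stringsAsFactors = FALSE)
  if (!any(pos)) return(structure(empty, class = c("flare_set", "data.frame")))
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(first = starts[r$values], last = ends[r$values])
  cand <- intervals(track$chrom, (runs$first - 1) * res, runs$last * res)
  cand <- merge_intervals(cand, max_gap = merge_gap)
  if (!is.null(blacklist) && nrow(blacklist) > 0)
    cand <- subtract_blacklist(cand, blacklist, mode = "drop")
  if (nrow(cand) == 0)
    return(structure(empty, class = c("flare_set", "data.frame")))
  out <- do.call(rbind, lapply(seq_len(nrow(cand)), function(k) {
    b1 <- floor(cand$start[k] / res) + 1
    b2 <- ceiling(cand$end[k] / res)
    vals <- s[b1:b2]
    if (all(is.na(vals))) return(NULL)
    peak <- max(vals, na.rm = TRUE)
    pb <- b1 + which.max(vals) - 1   # first maximal bin on ties
    peak2 <- if (!is.null(s2)) suppressWarnings(max(s2[b1:b2], na.rm = TRUE))
    else Inf
    data.frame(chrom = cand$chrom[k], start = cand$start[k],
               end = cand$end[k], width = cand$end[k] - cand$start[k],
               pivot = (pb - 0.5) * res, peak_score = peak,
               peak_log2 = peak2, stringsAsFactors = FALSE)
  }))
  out <- out[out$width >= min_width & out$peak_score >= min_peak &
               out$peak_log2 >= min_peak_log2, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("flare_set", "data.frame"))
}

#' Width statistics of a flare set
#'
#' @param flares a `flare_set` (>= 1 row).
#' @param hist_bin histogram bin width in bp.
#' @return list: `count`, `widths`, `hist` (data.frame `lo`, `hi`, `mid`,
#'   `count`), `modal_width` (center of the highest histogram bin; ties
#'   resolve to the smaller width).
#' @export
flare_size_stats <- function(flares, hist_bin = 50e3) {
  if (nrow(flares) == 0) stopf("empty flare set")
  w <- flares$width
  breaks <- seq(0, (max(w) %/% hist_bin + 1) * hist_bin, by = hist_bin)
  idx <- findInterval(w, breaks, rightmost.closed = FALSE)
  cnt <- tabulate(idx, nbins = length(breaks) - 1)
  hist <- data.frame(lo = breaks[-length(breaks)], hi = breaks[-1],
                     mid = breaks[-length(breaks)] + hist_bin / 2,
                     count = cnt)
  modal <- hist$mid[which.max(hist$count)]   # which.max takes first on ties
  list(count = nrow(flares), widths = w, hist = hist, modal_width = modal)
}

#' Spacing statistics of a flare set
#'
#' Distance between consecutive flare midpoints per chromosome. A pair is
#' excluded when the span between the two midpoints overlaps the blacklist
#' (e.g. an assembly gap that would distort the distance).
#'
#' @param flares a `flare_set`.
#' @param blacklist optional interval table of excluded spans.
#' @return list: `spacings` (bp), `median_spacing`, `n_excluded`.
#' @export
flare_spacing <- function(flares, blacklist = NULL) {
  spac <- numeric(0)
  n_excl <- 0L
  for (chrom in unique(flares$chrom)) {
    f <- flares[flares$chrom == chrom, , drop = FALSE]
    f <- f[order(f$start), , drop = FALSE]
    if (nrow(f) < 2) next
    mid <- (f$start + f$end) / 2
    for (k in seq_len(nrow(f) - 1)) {
      span <- intervals(chrom, mid[k], mid[k + 1])
      if (!is.null(blacklist) && nrow(blacklist) > 0 &&
          overlaps_any(span, blacklist)) {
        n_excl <- n_excl + 1L
        next
      }
      spac <- c(spac, mid[k + 1] - mid[k])
    }
  }
  if (length(spac) == 0) warnf("no measurable flare spacings")
  list(spacings = spac,
       median_spacing = if (length(spac)) stats::median(spac) else NA_real_,
       n_excluded = n_excl)
}

#' Anti-diagonal symmetry score at a pivot
#'
#' Mean O/E over the anti-diagonal through the pivot bin: entries
#' `oe[pivot - d, pivot + d]` for `d` in `1..half_width_bins`, ignoring
#' undefined entries. Scores above 1 indicate enrichment of contacts
#' between loci equidistant from the pivot (the hinge signature).
#'
#' @param oe O/E matrix or [observed_over_expected()] result.
#' @param pivot_bin 1-based pivot bin index.
#' @param half_width_bins anti-diagonal reach in bins.
#' @return Numeric score (NaN when every entry is undefined).
#' @export
pivot_symmetry_score <- function(oe, pivot_bin, half_width_bins) {
  if (is.list(oe) && !is.null(oe$oe)) oe <- oe$oe
  n <- nrow(oe)
  if (pivot_bin - half_width_bins < 1 || pivot_bin + half_width_bins > n)
    stopf("pivot bin %d closer than %d bins to a matrix edge", pivot_bin,
          half_width_bins)
  d <- seq_len(half_width_bins)
  vals <- oe[cbind(pivot_bin - d, pivot_bin + d)]
  if (all(is.na(vals))) return(NaN)
  mean(vals, na.rm = TRUE)
}

#' Permutation test for interval-feature association
#'
#' The observed statistic is the mean track value over the query (signal
#' feature) or the fraction of query bp overlapped (interval feature). The
#' null is the same statistic on length-preserving uniform relocations of
#' the query intervals within their own chromosome, avoiding the blacklist;
#' the empirical p-value uses the add-one rule and so is never 0.
#'
#' @param query interval table under test.
#' @param feature `signal_track` or interval table.
#' @param assembly [genome_assembly()] (shuffle bounds).
#' @param blacklist optional interval table excluded from shuffle placement.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @param alternative `"greater"` (enrichment), `"less"`, or `"two.sided"`
#'   (min tail doubled, capped at 1).
#' @param max_tries rejection-sampling cap per interval per permutation.
#' @return list: `observed`, `null` (vector), `fold` (observed / mean null),
#'   `p_value`, `alternative`.
#' @export
interval_enrichment <- function(query, feature, assembly, blacklist = NULL,
                                n_perm = 1000, seed = 1,
                                alternative = c("greater", "less", "two.sided"),
                                max_tries = 50) {
  alternative <- match.arg(alternative)
  if (n_perm < 100) stopf("n_perm must be >= 100")
  widths <- query$end - query$start
  chroms <- query$chrom
  lens <- chrom_length(assembly, chroms)
  if (anyNA(lens)) stopf("query chromosome missing from assembly")
  # precomputed per-chromosome structures so the per-permutation statistic
  # is plain arithmetic
  covered_bp <- function(s, e, fs, fe) {
    # total bp of [s, e) covered by disjoint sorted intervals [fs, fe)
    if (length(fs) == 0) return(0)
    sum(pmax(0, pmin(e, fe) - pmax(s, fs)))
  }
  if (inherits(feature, "signal_track")) {
    bs <- attr(feature, "bin_size")
    if (is.null(bs)) stopf("signal feature must be a fixed-bin track")
    dense <- lapply(split(feature, feature$chrom), function(tr) {
      L <- max(tr$end)
      v <- numeric(ceiling(L / bs))
      v[floor(tr$start / bs) + 1] <- tr$value
      v
    })
    stat1 <- function(chrom, s, e) {
      v <- dense[[chrom]]
      if (is.null(v)) return(c(0, e - s))
      b1 <- floor(s / bs) + 1
      b2 <- min(length(v), floor((e - 1) / bs) + 1)
      if (b1 > length(v)) return(c(0, e - s))
      j <- b1:b2
      w <- pmin(e, j * bs) - pmax(s, (j - 1) * bs)
      c(sum(v[j] * w), e - s)
    }
  } else {
    fsp <- split(merge_intervals(feature), merge_intervals(feature)$chrom)
    stat1 <- function(chrom, s, e) {
      f <- fsp[[chrom]]
      if (is.null(f)) return(c(0, e - s))
      c(covered_bp(s, e, f$start, f$end), e - s)
    }
  }
  blsp <- if (!is.null(blacklist) && nrow(blacklist) > 0)
    split(merge_intervals(blacklist), merge_intervals(blacklist)$chrom)
  else NULL
  hits_blacklist <- function(chrom, s, e) {
    b <- blsp[[chrom]]
    !is.null(b) && covered_bp(s, e, b$start, b$end) > 0
  }
  stat_set <- function(st) {
    parts <- vapply(seq_along(st),
                    function(i) stat1(chroms[i], st[i], st[i] + widths[i]),
                    numeric(2))
    sum(parts[1, ]) / sum(parts[2, ])
  }
  obs <- stat_set(query$start)
  null <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      st <- numeric(length(widths))
      for (i in seq_along(widths)) {
        placed <- FALSE
        for (t in seq_len(max_tries)) {
          s <- floor(stats::runif(1, 0, lens[i] - widths[i]))
          if (is.null(blsp) || !hits_blacklist(chroms[i], s, s + widths[i])) {
            st[i] <- s
            placed <- TRUE
            break
          }
        }
        if (!placed) stopf("insufficient placeable space for shuffled intervals")
      }
      stat_set(st)
    }, numeric(1))
  })
  p_hi <- (1 + sum(null >= obs)) / (n_perm + 1)
  p_lo <- (1 + sum(null <= obs)) / (n_perm + 1)
  p <- switch(alternative, greater = p_hi, less = p_lo,
              two.sided = min(1, 2 * min(p_hi, p_lo)))
  list(observed = obs, null = null,
       fold = obs / mean(null), p_value = p, alternative = alternative)
}
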
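# ROSE-style enhancer stitching and stratification. Constituent peaks
# (typically the intersection of H3K27ac and H3K4me1 peak sets) are
# TSS-filtered, stitched across gaps, scored by summed control-subtracted
# signal, ranked, split into super-enhancers (SE) above the tangent-slope
# cutoff of the rescaled rank curve, and the remainder stratified into
# equal-size groups G3 (strongest) > G2 > G1.

#' Keep peaks of `a` that overlap `b`
#'
#' Convenience for building the intersected peak list two ChIP marks must
#' agree on; coordinates of `a` are kept.
#'
#' @param a,b interval tables.
#' @return Subset of `a` overlapping at least one interval of `b`.
#' @export
intersect_peaks <- function(a, b) {
  out <- a[overlaps_any(a, b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stitch peaks into scored enhancer regions
#'
#' Peaks fully contained in a TSS exclusion window (TSS midpoint +/-
#' `tss_excl`) are removed; survivors within `stitch_gap` of each other are
#' merged; each stitched region is scored by the sum over its span of
#' per-bin `signal - control`, floored at 0 per bin (track values are
#' treated as per-bin densities, weighted by overlapped width / bin width).
#' Regions are ranked 1 = highest score.
#'
#' @param peaks interval table of constituent peaks (pre-intersected).
#' @param signal fixed-bin `signal_track`.
#' @param control optional matched `signal_track` subtracted bin-wise.
#' @param tss optional interval table of TSS positions.
#' @param stitch_gap merge gap in bp (ROSE default 12,500).
#' @param tss_excl TSS exclusion half-window in bp (default 2,000).
#' @return data.frame of class `stitched_enhancers`: `chrom`, `start`,
#'   `end`, `n_peaks`, `peak_ids`, `score`, `rank`, `group` (NA until
#'   [stratify_groups()]).
#' @export
stitch_and_score <- function(peaks, signal, control = NULL, tss = NULL,
                             stitch_gap = 12500, tss_excl = 2000) {
  if (!is.null(tss) && nrow(tss) > 0 && nrow(peaks) > 0) {
    tmid <- floor((tss$start + tss$end) / 2)
    excl <- intervals(tss$chrom, pmax(0, tmid - tss_excl), tmid + tss_excl)
    gr_p <- as_granges0(peaks)
    gr_e <- as_granges0(excl)
    within <- IRanges::overlapsAny(gr_p, gr_e, type = "within")
    peaks <- peaks[!within, , drop = FALSE]
  }
  if (nrow(peaks) == 0) stopf("no peaks survive TSS exclusion")
  if (is.null(peaks$name) || all(peaks$name == "."))
    peaks$name <- sprintf("peak_%d", seq_len(nrow(peaks)))
  stitched <- merge_intervals(peaks, max_gap = stitch_gap)
  hit <- GenomicRanges::findOverlaps(as_granges0(peaks), as_granges0(stitched))
  ids <- split(peaks$name[S4Vectors::queryHits(hit)],
               S4Vectors::subjectHits(hit))
  score <- vapply(seq_len(nrow(stitched)), function(k) {
    region_signal_sum(signal, control, stitched$chrom[k], stitched$start[k],
                      stitched$end[k])
  }, numeric(1))
  out <- data.frame(chrom = stitched$chrom, start = stitched$start,
                    end = stitched$end,
                    n_peaks = vapply(ids[as.character(seq_len(nrow(stitched)))],
                                     length, 0L),
                    peak_ids = vapply(ids[as.character(seq_len(nrow(stitched)))],
                                      paste, "", collapse = ","),
                    score = score, stringsAsFactors = FALSE)
  out$rank <- rank(-out$score, ties.method = "first")
  out$group <- NA_character_
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("stitched_enhancers", "data.frame"))
}

# Sum of floored (signal - control) over [start, end), per-bin semantics:
# each track bin contributes value * overlap_width / bin_width.
region_signal_sum <- function(signal, control, chrom, start, end) {
  bs <- attr(signal, "bin_size")
  if (is.null(bs)) stopf("signal must be a fixed-bin track")
  tr <- signal[signal$chrom == chrom, , drop = FALSE]
  if (nrow(tr) == 0) return(0)
  ctl <- if (!is.null(control)) control[control$chrom == chrom, , drop = FALSE]
  sel <- tr$end > start & tr$start < end
  tr <- tr[sel, , drop = FALSE]
  if (nrow(tr) == 0) return(0)
  v <- tr$value
  if (!is.null(ctl) && nrow(ctl) > 0) {
    cv <- ctl$value[match(tr$start, ctl$start)]
    cv[is.na(cv)] <- 0
    v <- v - cv
  }
  v <- pmax(v, 0)
  w <- pmin(end, tr$end) - pmax(start, tr$start)
  sum(v * w / bs)
}

#' Super-enhancer cutoff on a ranked score curve
#'
#' Scores are sorted ascending and both axes rescaled to the unit square;
#' the cutoff sits where a line of slope 1 is tangent to the curve -- the
#' point of maximal vertical distance below the unit diagonal, i.e. where
#' the discrete slope of the (convex) rank curve crosses 1. Ties resolve
#' to the top of the curve, so a perfectly linear curve yields no
#' super-enhancers. Scores strictly above the cutoff value are
#' super-enhancers; the rule is invariant to positive rescaling.
#'
#' @param scores numeric vector of region scores (>= 3).
#' @return list: `cutoff` (score on the original scale), `n_se`, `is_se`
#'   (logical aligned with `scores`).
#' @export
se_cutoff <- function(scores) {
  n <- length(scores)
  if (n < 3) stopf("need at least 3 regions")
  if (max(scores) == min(scores)) {
    warnf("all scores equal: no super-enhancers")
    return(list(cutoff = max(scores), n_se = 0L, is_se = rep(FALSE, n)))
  }
  s <- sort(scores)
  xs <- seq(0, 1, length.out = n)
  ys <- (s - s[1]) / (s[n] - s[1])
  below <- ys - xs                      # vertical distance to the diagonal
  cut_idx <- max(which(below == min(below)))
  cutoff <- s[cut_idx]
  is_se <- scores > cutoff
  list(cutoff = cutoff, n_se = sum(is_se), is_se = is_se)
}

#' Stratify ranked non-SE enhancers into equal cohorts
#'
#' Applies [se_cutoff()] labels, then splits the non-SE regions by rank
#' into `n_groups` contiguous cohorts: G3 = strongest, G1 = weakest; a
#' remainder is distributed to the weakest groups so the strong cohorts are
#' never larger than stated.
#'
#' @param enh a `stitched_enhancers` table.
#' @param n_groups number of non-SE cohorts (default 3).
#' @return The table with `group` filled (`SE`, `G3`, ..., `G1`).
#' @export
stratify_groups <- function(enh, n_groups = 3) {
  sc <- se_cutoff(enh$score)
  enh$group <- ifelse(sc$is_se, "SE", NA_character_)
  non <- which(!sc$is_se)
  m <- length(non)
  if (m < n_groups) stopf("fewer non-SE regions (%d) than groups (%d)", m, n_groups)
  base <- m %/% n_groups
  extra <- m %% n_groups
  # cohort sizes from strongest (G<n_groups>) to weakest (G1): the extra
  # regions go to the weakest cohorts
  sizes <- rep(base, n_groups)
  if (extra > 0) sizes[(n_groups - extra + 1):n_groups] <- base + 1
  labels <- rep(sprintf("G%d", n_groups:1), times = sizes)
  non_sorted <- non[order(enh$rank[non])]
  enh$group[non_sorted] <- labels
  enh
}

#' Insulation composition of positive-insulation regions
#'
#' Maximal runs of positive summary insulation become regions; each region
#' falls into the stratum of its maximum score and is labeled by the
#' highest-priority overlapping enhancer group (SE > G3 > G2 > G1 > none).
#'
#' @param track an `insulation_track`.
#' @param enhancers a grouped `stitched_enhancers` table (or NULL: all
#'   regions count as "NoEnh").
#' @param strata_bounds ascending positive-score cut points (default
#'   0.1/0.2/0.3, giving strata (0, 0.1], (0.1, 0.2], (0.2, 0.3], > 0.3).
#' @param mode `"region"` counts regions (default); `"bin"` counts bins.
#' @return list: `table` (stratum x group counts), `proportions` (rows
#'   normalized to 1), `genome_share` (share of positive regions or bins
#'   per stratum), `regions` (the underlying region table).
#' @export
insulation_composition <- function(track, enhancers,
                                   strata_bounds = c(0.1, 0.2, 0.3),
                                   mode = c("region", "bin")) {
  mode <- match.arg(mode)
  s <- track$summary
  res <- track$resolution
  pos <- !is.na(s) & s > 0
  groups <- c("NoEnh", "G1", "G2", "G3", "SE")
  bounds <- c(0, strata_bounds, Inf)
  strata_names <- character(length(bounds) - 1)
  for (k in seq_len(length(bounds) - 1)) {
    strata_names[k] <- if (is.finite(bounds[k + 1]))
      sprintf("%g-%g", bounds[k], bounds[k + 1])
    else sprintf(">%g", bounds[k])
  }
  tab <- matrix(0L, length(strata_names), length(groups),
                dimnames = list(strata_names, groups))
  regions <- NULL
  if (any(pos)) {
    r <- rle(pos)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    first <- starts[r$values]; last <- ends[r$values]
    regions <- data.frame(chrom = track$chrom, start = (first - 1) * res,
                          end = last * res, stringsAsFactors = FALSE)
    regions$max_score <- vapply(seq_along(first),
                                function(k) max(s[first[k]:last[k]]),
                                numeric(1))
    regions$n_bins <- last - first + 1L
    regions$stratum <- strata_names[findInterval(regions$max_score,
                                                 bounds[-1],
                                                 left.open = FALSE) + 1]
    regions$group <- "NoEnh"
    if (!is.null(enhancers) && nrow(enhancers) > 0) {
      for (g in c("G1", "G2", "G3", "SE")) {   # ascending priority
        e <- enhancers[!is.na(enhancers$group) & enhancers$group == g, ,
                       drop = FALSE]
        if (nrow(e) == 0) next
        regions$group[overlaps_any(regions, e)] <- g
      }
    }
    w <- if (mode == "region") rep(1L, nrow(regions)) else regions$n_bins
    for (k in seq_len(nrow(regions)))
      tab[regions$stratum[k], regions$group[k]] <-
        tab[regions$stratum[k], regions$group[k]] + w[k]
  }
  totals <- rowSums(tab)
  prop <- tab / ifelse(totals == 0, 1, totals)
  list(table = tab, proportions = prop,
       genome_share = totals / max(1, sum(totals)), regions = regions)
}

#' Signal metaplot around features
#'
#' Per-feature signal resampled into fixed bins centered on feature
#' midpoints, averaged per column.
#'
#' @param track fixed-bin `signal_track` (e.g. log2 fold enrichment).
#' @param features interval table.
#' @param flank half-window in bp (multiple of `bin`).
#' @param bin output bin size in bp (default 10 kb).
#' @return list: `offsets` (bin center offsets, bp), `mean` (column means),
#'   `matrix` (features x bins).
#' @export
signal_metaplot <- function(track, features, flank, bin = 10e3) {
  if (flank %% bin != 0) stopf("flank must be a multiple of the bin size")
  bs <- attr(track, "bin_size")
  if (is.null(bs)) stopf("track must be a fixed-bin signal track")
  nb <- as.integer(flank / bin)
  offsets <- seq(-nb, nb - 1) * bin + bin / 2
  mat <- matrix(0, nrow(features), 2 * nb)
  dense <- lapply(split(seq_len(nrow(track)), track$chrom), function(ii) {
    L <- max(track$end[ii])
    v <- numeric(ceiling(L / bs))
    v[floor(track$start[ii] / bs) + 1] <- track$value[ii]
    v
  })
  for (r in seq_len(nrow(features))) {
    mid <- floor((features$start[r] + features$end[r]) / 2)
    v <- dense[[features$chrom[r]]]
    for (k in seq_len(2 * nb)) {
      s <- mid + (k - nb - 1) * bin
      e <- s + bin
      if (is.null(v) || e <= 0) next
      b1 <- max(1, floor(s / bs) + 1)
      b2 <- min(length(v), floor((e - 1) / bs) + 1)
      if (b1 > b2) next
      j <- b1:b2
      w <- pmin(e, j * bs) - pmax(s, (j - 1) * bs)
      mat[r, k] <- sum(v[j] * w) / sum(w)
    }
  }
  list(offsets = offsets, mean = colMeans(mat), matrix = mat)
}
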
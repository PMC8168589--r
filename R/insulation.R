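# Multi-window diamond insulation. For window w (in bins) the raw score of
# bin i is the mean balanced count over the off-diagonal diamond
# {(a, b) : i-w <= a <= i-1, i+1 <= b <= i+w}; the reported score is the
# per-chromosome z-score of log2(raw + eps) so that positive values mark
# bins sitting inside self-interacting domains and negative values mark
# contact depletion (boundaries). Sign semantics follow the convention that
# red/positive = increased contacts. Bins within the window of a chromosome
# edge, masked bins, and bins with fully masked diamonds are undefined (NA).

INSULATION_EPS <- 1e-6

default_windows <- c(100e3, 200e3, 400e3, 800e3)

# Undo the positional component of balancing: the ICE weights of the
# expected (distance-only) model matrix capture exactly the inflation the
# equal-marginal constraint imposes near chromosome ends.
edge_corrected <- function(x, tol = 1e-6, max_iter = 200) {
  n <- nrow(x)
  dd <- abs(row(x) - col(x))
  ok <- !is.na(x)
  if (!any(ok)) return(x)
  f <- tapply(x[ok], dd[ok], mean)
  fv <- rep(NA_real_, n)
  fv[as.integer(names(f)) + 1] <- as.numeric(f)
  em <- matrix(fv[dd + 1], n, n)
  em[!ok] <- NA_real_
  valid <- rowSums(ok) > 0
  sub <- em[valid, valid, drop = FALSE]
  sub[is.na(sub)] <- 0
  u <- rep(1, nrow(sub))
  for (it in seq_len(max_iter)) {
    s <- rowSums(sub)
    if (any(s == 0)) break
    b <- s / mean(s)
    if (max(abs(b - 1)) < tol) break
    sub <- sub / outer(b, b)
    u <- u * b
  }
  uu <- rep(1, n)
  uu[valid] <- u
  x * outer(uu, uu)
}

#' Diamond insulation scores at multiple window sizes
#'
#' Balancing forces equal marginals, which systematically inflates
#' short-range values near chromosome ends (edge bins have a geometric
#' marginal deficit). With `edge_correct` (default) the balanced matrix is
#' multiplied by the outer product of the iterative-correction weights of
#' its own expected (distance-only) model matrix, which removes exactly
#' that positional inflation while keeping coverage normalization.
#'
#' @param m a balanced `contact_matrix`.
#' @param windows window sizes in bp; each must be a multiple of the matrix
#'   resolution with window/resolution >= 2. Defaults to 100-800 kb.
#' @param edge_correct undo the balancing-induced positional inflation at
#'   chromosome ends before computing diamond means.
#' @return An `insulation_track`: list with `chrom`, `resolution`,
#'   `windows`, `scores` (bins x windows z-score matrix), `summary` (per-bin
#'   mean across windows; NA unless all windows defined), and `largest`
#'   (the last, largest-window column, the flare-caller input).
#' @export
insulation_scores <- function(m, windows = default_windows,
                              edge_correct = TRUE) {
  if (!isTRUE(m$balanced)) stopf("insulation_scores needs a balanced matrix")
  res <- m$resolution
  windows <- sort(windows)
  wb <- windows / res
  if (any(wb != round(wb))) stopf("window must be a multiple of the resolution")
  if (any(wb < 2)) stopf("window/resolution must be >= 2")
  wb <- as.integer(wb)
  n <- nrow(m$counts)
  scores <- matrix(NA_real_, n, length(wb))
  log2_dev <- matrix(NA_real_, n, length(wb))
  colnames(scores) <- colnames(log2_dev) <- paste0("w", as.integer(windows))
  if (n < 2 * max(wb) + 1) {
    warnf("chromosome %s shorter than twice the largest window; track undefined", m$chrom)
  } else {
    x <- m$counts
    if (edge_correct) x <- edge_corrected(x)
    for (k in seq_along(wb)) {
      w <- wb[k]
      raw <- rep(NA_real_, n)
      for (i in (w + 1):(n - w)) {
        if (!m$mask[i]) next
        block <- x[(i - w):(i - 1), (i + 1):(i + w), drop = FALSE]
        mu <- mean(block, na.rm = TRUE)
        if (is.finite(mu)) raw[i] <- mu
      }
      lg <- log2(raw + INSULATION_EPS)
      scores[, k] <- zscore(lg)
      log2_dev[, k] <- lg - mean(lg[is.finite(lg)])   # centered log2, absolute units
    }
  }
  summary <- rowMeans(scores)   # NA unless every window column is defined
  structure(list(chrom = m$chrom, resolution = res, windows = windows,
                 scores = scores, summary = summary,
                 largest = scores[, length(wb)],
                 log2_dev = log2_dev,
                 summary_log2 = rowMeans(log2_dev),
                 largest_log2 = log2_dev[, length(wb)]),
            class = "insulation_track")
}

#' @export
print.insulation_track <- function(x, ...) {
  cat(sprintf("<insulation_track> %s @ %d bp: %d bins, windows %s kb (%d defined)\n",
              x$chrom, as.integer(x$resolution), length(x$summary),
              paste(x$windows / 1e3, collapse = "/"), sum(!is.na(x$summary))))
  invisible(x)
}

#' Call boundaries at insulation-summary minima
#'
#' A boundary is a strict local minimum of the summary track within
#' `+/- min_separation` bins whose value is at most `-min_depth` and whose
#' prominence -- the smaller of the rises to the highest flank on either
#' side of that neighborhood -- is at least `min_prominence`. Prominence is
#' reported as the boundary strength. The neighborhood defaults to the
#' smallest insulation window so that boundaries of adjacent small domains
#' do not suppress one another.
#'
#' @param track an `insulation_track`.
#' @param min_depth minimum dip depth (z units, positive number).
#' @param min_prominence minimum prominence (z units).
#' @param min_log2_drop minimum prominence in centered-log2 units. The
#'   z-scored track is normalized per chromosome, so on a structureless
#'   map pure counting noise still reaches |z| ~ 3; this absolute
#'   contact-depletion criterion (a boundary-strength threshold in log2
#'   units) is what separates real boundaries from that noise.
#' @param min_separation neighborhood half-width in bins (default: smallest
#'   window / resolution).
#' @return data.frame: `chrom`, `bin` (1-based), `start`, `end` (bin bp),
#'   `pos` (bin midpoint bp), `score` (summary value), `strength`
#'   (prominence).
#' @export
call_boundaries <- function(track, min_depth = 1.5, min_prominence = 1.5,
                            min_log2_drop = 0.3, min_separation = NULL) {
  s <- track$summary
  s2 <- track$summary_log2
  n <- length(s)
  res <- track$resolution
  if (is.null(min_separation))
    min_separation <- max(2L, as.integer(min(track$windows) / res))
  empty <- data.frame(chrom = character(), bin = integer(), start = numeric(),
                      end = numeric(), pos = numeric(), score = numeric(),
                      strength = numeric(), stringsAsFactors = FALSE)
  if (sum(!is.na(s)) < 3) return(empty)
  hits <- integer(0); strength <- numeric(0)
  for (i in seq_len(n)) {
    if (i == 1 || i == n) next
    if (is.na(s[i]) || s[i] > -min_depth) next
    lo <- max(1, i - min_separation); hi <- min(n, i + min_separation)
    left <- s[lo:(i - 1)]; right <- s[(i + 1):hi]
    if (!all(s[i] < left[!is.na(left)]) || !all(s[i] < right[!is.na(right)]))
      next
    lrise <- suppressWarnings(max(left, na.rm = TRUE)) - s[i]
    rrise <- suppressWarnings(max(right, na.rm = TRUE)) - s[i]
    if (!is.finite(lrise) || !is.finite(rrise)) next
    prom <- min(lrise, rrise)
    if (prom < min_prominence) next
    if (!is.null(s2) && min_log2_drop > 0) {
      l2 <- suppressWarnings(max(s2[lo:(i - 1)], na.rm = TRUE)) - s2[i]
      r2 <- suppressWarnings(max(s2[(i + 1):hi], na.rm = TRUE)) - s2[i]
      if (!is.finite(l2) || !is.finite(r2) || min(l2, r2) < min_log2_drop)
        next
    }
    hits <- c(hits, i); strength <- c(strength, prom)
  }
  if (length(hits) == 0) return(empty)
  data.frame(chrom = track$chrom, bin = hits,
             start = (hits - 1) * res, end = hits * res,
             pos = (hits - 0.5) * res, score = s[hits], strength = strength,
             stringsAsFactors = FALSE)
}

feature_center_bin <- function(features, resolution) {
  centers <- floor((features$start + features$end) / 2)
  floor(centers / resolution) + 1
}

#' Feature-centered insulation heatmap
#'
#' One row per feature: summary insulation in bins spanning the feature
#' midpoint +/- `flank`. Undefined bins propagate as NA. `rank_by =
#' "center"` orders rows by the central-bin value (descending); the applied
#' order is attached as attribute `row_order` so one stage's ranking can be
#' reused on another stage's track via `row_order`.
#'
#' @param track an `insulation_track`.
#' @param features interval table on the track's chromosome.
#' @param flank half-width in bp (multiple of the resolution).
#' @param rank_by `"given"` keeps input order; `"center"` sorts by the
#'   central column.
#' @param row_order explicit row permutation overriding `rank_by`.
#' @return Matrix (features x bins) with attribute `row_order`.
#' @export
feature_insulation_heatmap <- function(track, features, flank,
                                       rank_by = c("given", "center"),
                                       row_order = NULL) {
  rank_by <- match.arg(rank_by)
  res <- track$resolution
  if (flank %% res != 0) stopf("flank must be a multiple of the resolution")
  fb <- as.integer(flank / res)
  n <- length(track$summary)
  ncol_out <- 2L * fb + 1L
  out <- matrix(NA_real_, nrow(features), ncol_out)
  colnames(out) <- as.character(seq(-fb, fb) * res)
  onchrom <- features$chrom == track$chrom
  if (any(!onchrom)) warnf("%d features on other chromosomes: rows undefined",
                           sum(!onchrom))
  centers <- feature_center_bin(features, res)
  for (r in which(onchrom)) {
    bins <- (centers[r] - fb):(centers[r] + fb)
    ok <- bins >= 1 & bins <= n
    out[r, ok] <- track$summary[bins[ok]]
  }
  if (!is.null(row_order)) {
    out <- out[row_order, , drop = FALSE]
    attr(out, "row_order") <- row_order
  } else if (rank_by == "center") {
    ord <- order(out[, fb + 1L], decreasing = TRUE, na.last = TRUE)
    out <- out[ord, , drop = FALSE]
    attr(out, "row_order") <- ord
  } else {
    attr(out, "row_order") <- seq_len(nrow(out))
  }
  out
}

#' Aggregate metaplot of a feature-centered heatmap
#'
#' @param heatmap matrix from [feature_insulation_heatmap()] (or any
#'   feature x position matrix).
#' @return data.frame `offset` (column label), `mean` (column mean over
#'   defined entries; NaN when a column is all-undefined), `n_defined`.
#' @export
aggregate_metaplot <- function(heatmap) {
  mean_na <- suppressWarnings(apply(heatmap, 2, mean, na.rm = TRUE))
  mean_na[!is.finite(mean_na)] <- NaN
  data.frame(offset = as.numeric(colnames(heatmap) %||%
                                   seq_len(ncol(heatmap))),
             mean = as.numeric(mean_na),
             n_defined = apply(heatmap, 2, function(col) sum(!is.na(col))))
}
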
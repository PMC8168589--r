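# Per-chromosome binned contact matrices. A contact_matrix is a list with
# fields chrom, resolution, counts (dense symmetric n x n), mask (logical,
# TRUE = valid bin), weights (balancing weights, NA when unbalanced or
# masked) and balanced flag. Masked bins carry NA rows/columns after
# balancing so that undefined values propagate explicitly.

standard_resolutions <- c(10e3, 25e3, 50e3, 100e3)

new_contact_matrix <- function(chrom, resolution, counts, mask,
                               weights = NULL, balanced = FALSE) {
  structure(list(chrom = chrom, resolution = resolution, counts = counts,
                 mask = mask, weights = weights, balanced = balanced),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s @ %d bp: %d bins (%d masked), %s\n",
              x$chrom, as.integer(x$resolution), nrow(x$counts),
              sum(!x$mask), if (x$balanced) "balanced" else "raw"))
  invisible(x)
}

#' Bin valid pairs into per-chromosome contact matrices
#'
#' Each retained cis pair increments the symmetric count matrix at
#' `(floor(pos1/res), floor(pos2/res))`. Trans pairs are counted and
#' dropped when `cis_only` (per-chromosome cis matrices are the analysis
#' substrate throughout the package); pairs closer than `min_dist` are
#' dropped. Only conventional Hi-C resolutions (10/25/50/100 kb) are
#' accepted unless `allow_any_resolution`.
#'
#' @param pairs canonical pairs data.frame.
#' @param assembly [genome_assembly()]; one matrix per assembly chromosome.
#' @param resolution bin size in bp.
#' @param cis_only drop inter-chromosomal pairs (default TRUE).
#' @param min_dist drop cis pairs with |pos2 - pos1| < min_dist (bp).
#' @param allow_any_resolution accept non-standard bin sizes.
#' @return Named list of `contact_matrix` (one per chromosome), with
#'   attributes `n_retained`, `n_trans`, `n_short`.
#' @export
bin_pairs <- function(pairs, assembly, resolution, cis_only = TRUE,
                      min_dist = 0, allow_any_resolution = FALSE) {
  if (resolution <= 0) stopf("resolution must be positive")
  if (!allow_any_resolution && !resolution %in% standard_resolutions)
    stopf("non-standard resolution %d (standard: %s); set allow_any_resolution = TRUE",
          as.integer(resolution),
          paste(as.integer(standard_resolutions), collapse = "/"))
  if (nrow(pairs) == 0) warnf("binning an empty pairs table")
  is_cis <- pairs$chrom1 == pairs$chrom2
  n_trans <- sum(!is_cis)
  if (cis_only) pairs <- pairs[is_cis, , drop = FALSE]
  d <- abs(pairs$pos2 - pairs$pos1)
  short <- pairs$chrom1 == pairs$chrom2 & d < min_dist
  n_short <- sum(short)
  pairs <- pairs[!short, , drop = FALSE]
  out <- list()
  n_retained <- 0L
  for (k in seq_len(nrow(assembly))) {
    chrom <- assembly$chrom[k]
    n <- ceiling(assembly$length[k] / resolution)
    m <- matrix(0, n, n)
    sel <- pairs$chrom1 == chrom & pairs$chrom2 == chrom
    if (any(sel)) {
      b1 <- floor(pairs$pos1[sel] / resolution) + 1
      b2 <- floor(pairs$pos2[sel] / resolution) + 1
      lo <- pmin(b1, b2); hi <- pmax(b1, b2)
      idx <- (lo - 1) * n + hi   # column-major linear index of [hi, lo]
      cnt <- tabulate(idx, nbins = n * n)
      m <- matrix(cnt, n, n)     # lower triangle filled
      m <- m + t(m)
      diag(m) <- diag(m) / 2
      n_retained <- n_retained + sum(sel)
    }
    out[[chrom]] <- new_contact_matrix(chrom, resolution, m,
                                       mask = rep(TRUE, n))
  }
  attr(out, "n_retained") <- n_retained
  attr(out, "n_trans") <- n_trans
  attr(out, "n_short") <- n_short
  out
}

#' Balance a contact matrix by iterative correction
#'
#' Sinkhorn-style iterative correction: bins whose raw marginal falls below
#' `mask_frac` times the median non-zero marginal are masked, then rows and
#' columns of the remaining submatrix are rescaled until every valid-bin
#' marginal agrees with the mean marginal within `tol` (relative). The
#' accumulated per-bin weights are stored; masked bins become NA
#' rows/columns in the balanced matrix.
#'
#' @param m a `contact_matrix` with raw counts.
#' @param tol convergence tolerance on the relative marginal deviation.
#' @param max_iter iteration cap.
#' @param mask_frac low-coverage masking fraction of the median marginal.
#' @return The balanced `contact_matrix` (weights filled, `balanced = TRUE`,
#'   attribute `n_iter`).
#' @export
balance_matrix <- function(m, tol = 1e-5, max_iter = 500, mask_frac = 0.1) {
  counts <- m$counts
  n <- nrow(counts)
  marg <- rowSums(counts)
  nz <- marg[marg > 0]
  if (length(nz) == 0) stopf("matrix too sparse: all bins empty")
  valid <- m$mask & marg >= mask_frac * stats::median(nz) & marg > 0
  if (!any(valid)) stopf("matrix too sparse: all bins masked")
  sub <- counts[valid, valid, drop = FALSE]
  w <- rep(1, sum(valid))
  it <- 0L
  repeat {
    it <- it + 1L
    s <- rowSums(sub)
    if (any(s == 0)) stopf("matrix too sparse: empty bin after masking")
    b <- s / mean(s)
    dev <- max(abs(b - 1))
    if (dev < tol || it >= max_iter) break
    sub <- sub / outer(b, b)
    w <- w * b
  }
  out <- matrix(NA_real_, n, n)
  out[valid, valid] <- sub
  weights <- rep(NA_real_, n)
  weights[valid] <- w
  res <- new_contact_matrix(m$chrom, m$resolution, out, mask = valid,
                            weights = weights, balanced = TRUE)
  attr(res, "n_iter") <- it
  res
}

#' Observed/expected transformation of a balanced matrix
#'
#' The expected value at bin distance `d` is the mean balanced count over
#' all valid entries with `|i - j| == d`; every entry is divided by the
#' expected value at its distance. Diagonals with no valid entries (or an
#' expected value of zero) yield NA.
#'
#' @param m a balanced `contact_matrix`.
#' @return list with `oe` (matrix), `expected` (data.frame `dist_bins`,
#'   `value`, `n`) and the `mask`.
#' @export
observed_over_expected <- function(m) {
  if (!isTRUE(m$balanced)) stopf("observed_over_expected needs a balanced matrix")
  x <- m$counts
  n <- nrow(x)
  d <- abs(row(x) - col(x))
  ok <- !is.na(x)
  expected <- rep(NA_real_, n)
  cnt <- integer(n)
  sums <- tapply(x[ok], d[ok], sum)
  ns <- tapply(rep(1, sum(ok)), d[ok], sum)
  dist_ids <- as.integer(names(sums))
  expected[dist_ids + 1] <- as.numeric(sums) / as.numeric(ns)
  cnt[dist_ids + 1] <- as.integer(ns)
  ev <- expected[d + 1]
  oe <- x / ev
  oe[!is.finite(oe)] <- NA_real_
  list(oe = oe,
       expected = data.frame(dist_bins = 0:(n - 1), value = expected, n = cnt),
       mask = m$mask, resolution = m$resolution, chrom = m$chrom)
}

#' Contact-frequency decay curve
#'
#' Histograms cis contact distances into log-spaced bins and reports both
#' the per-bin probability mass (`prob`, summing to 1 over distances >=
#' `min_dist`) and the width-normalized value (`density`, the quantity whose
#' log-log slope estimates the decay exponent).
#'
#' @param pairs canonical pairs table (cis pairs are selected internally).
#' @param log_bins_per_decade number of bins per factor-of-10 distance.
#' @param min_dist minimum distance in bp (default 1 kb, suppressing
#'   self-ligation artifacts).
#' @return data.frame of class `decay_curve`: `lo`, `hi`, `mid` (geometric
#'   midpoint), `count`, `prob`, `density`.
#' @export
contact_decay <- function(pairs, log_bins_per_decade = 10, min_dist = 1000) {
  cis <- pairs$chrom1 == pairs$chrom2
  d <- abs(pairs$pos2 - pairs$pos1)[cis]
  d <- d[d >= min_dist]
  if (length(d) == 0) stopf("no cis pairs at distance >= %d", as.integer(min_dist))
  lo10 <- log10(min_dist)
  hi10 <- log10(max(d) + 1)
  step <- 1 / log_bins_per_decade
  breaks <- 10^seq(lo10, hi10 + step, by = step)
  h <- findInterval(d, breaks, rightmost.closed = FALSE)
  cnt <- tabulate(h, nbins = length(breaks) - 1)
  width <- diff(breaks)
  prob <- cnt / sum(cnt)
  density <- prob / width
  out <- data.frame(lo = breaks[-length(breaks)], hi = breaks[-1],
                    mid = sqrt(breaks[-length(breaks)] * breaks[-1]),
                    count = cnt, prob = prob, density = density)
  class(out) <- c("decay_curve", "data.frame")
  out
}

#' Log-log slope of a decay curve
#'
#' Least-squares slope of `log(density)` against `log(distance)` over an
#' optional distance range; for data generated with `P(s) ~ s^-alpha` the
#' slope estimates `-alpha`.
#'
#' @param curve a [contact_decay()] result.
#' @param min_dist,max_dist distance range (bp) entering the fit.
#' @return Numeric slope.
#' @export
decay_slope <- function(curve, min_dist = -Inf, max_dist = Inf) {
  sel <- curve$count > 0 & curve$mid >= min_dist & curve$mid <= max_dist
  if (sum(sel) < 3) stopf("too few populated bins for a slope fit")
  stats::coef(stats::lm(log(curve$density[sel]) ~ log(curve$mid[sel])))[[2]]
}

#' Downsample a pairs table without replacement
#'
#' @param pairs pairs data.frame.
#' @param n sample size (<= nrow(pairs)).
#' @param seed RNG seed; the draw is deterministic given the seed and the
#'   caller's RNG state is untouched.
#' @return Pairs table with exactly `n` rows.
#' @export
downsample_pairs <- function(pairs, n, seed) {
  if (n > nrow(pairs))
    stopf("cannot sample %d pairs from %d available", n, nrow(pairs))
  idx <- with_local_seed(seed, sample.int(nrow(pairs), n))
  out <- pairs[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a contact matrix as coordinate-sparse text
#'
#' Header lines (`#chrom`, `#resolution`, `#masked`) followed by
#' tab-separated `bin1 bin2 value` for the non-zero upper triangle
#' (1-based bins). Balanced matrices serialize their weights.
#'
#' @param m a `contact_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  n <- nrow(m$counts)
  writeLines(c(sprintf("#chrom\t%s", m$chrom),
               sprintf("#resolution\t%d", as.integer(m$resolution)),
               sprintf("#bins\t%d", n),
               sprintf("#balanced\t%d", as.integer(m$balanced)),
               sprintf("#masked\t%s", paste(which(!m$mask), collapse = ","))),
             con)
  if (!is.null(m$weights))
    writeLines(sprintf("#weights\t%s",
                       paste(format(m$weights, digits = 17, trim = TRUE),
                             collapse = ",")), con)
  ut <- which(upper.tri(m$counts, diag = TRUE) & m$counts != 0 &
                !is.na(m$counts), arr.ind = TRUE)
  writeLines(sprintf("%d\t%d\t%s", ut[, 1], ut[, 2],
                     format(m$counts[ut], digits = 17, trim = TRUE)), con)
  invisible(path)
}

#' Read a coordinate-sparse text contact matrix
#' @param path file written by [write_matrix()].
#' @return A `contact_matrix`.
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  get <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("#", key, "\t"))]
    if (length(ln) == 0) return(NULL)
    sub("^#[^\t]*\t", "", ln[1])
  }
  chrom <- get("chrom")
  res <- as.numeric(get("resolution"))
  n <- as.integer(get("bins"))
  balanced <- identical(get("balanced"), "1")
  masked <- get("masked")
  mask <- rep(TRUE, n)
  if (!is.null(masked) && nzchar(masked))
    mask[as.integer(strsplit(masked, ",")[[1]])] <- FALSE
  weights <- NULL
  wl <- get("weights")
  if (!is.null(wl)) {
    ws <- trimws(strsplit(wl, ",")[[1]])
    ws[ws == "NA"] <- NA_character_
    weights <- as.numeric(ws)
  }
  m <- matrix(0, n, n)
  if (balanced) {
    m[!mask, ] <- NA_real_
    m[, !mask] <- NA_real_
  }
  if (length(body)) {
    parts <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
    i <- as.integer(parts[, 1]); j <- as.integer(parts[, 2])
    v <- as.numeric(parts[, 3])
    m[cbind(i, j)] <- v
    m[cbind(j, i)] <- v
  }
  new_contact_matrix(chrom, res, m, mask, weights, balanced)
}
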
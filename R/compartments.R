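# A/B compartments from the first principal component of the Pearson
# correlation matrix of the observed/expected map, computed per chromosome.
# The PC1 sign is fixed against an external orientation track (gene density
# or GC content binned at the analysis resolution): A = PC1 > 0 after
# orienting PC1 to correlate positively with the track.

#' Pearson correlation matrix of an O/E map
#'
#' Correlation between row vectors of the O/E matrix over mutually defined
#' entries (masked bins are dropped and reinserted as NA). Rows with zero
#' variance yield NA correlations; the diagonal of defined bins is 1.
#'
#' @param oe O/E matrix (from [observed_over_expected()]), or the list that
#'   function returns.
#' @return Symmetric correlation matrix with NA at undefined bins.
#' @export
correlation_matrix <- function(oe) {
  if (is.list(oe) && !is.null(oe$oe)) oe <- oe$oe
  n <- nrow(oe)
  valid <- rowSums(!is.na(oe)) >= 3
  if (sum(valid) < 3) stopf("fewer than 3 valid bins")
  sub <- oe[valid, valid, drop = FALSE]
  cc <- suppressWarnings(stats::cor(t(sub), use = "pairwise.complete.obs"))
  diag(cc) <- 1
  out <- matrix(NA_real_, n, n)
  out[valid, valid] <- cc
  out
}

#' A/B compartment track from PC1 of the correlation matrix
#'
#' The leading principal component of the valid-bin submatrix of the
#' correlation matrix (columns mean-centered) is variance-normalized,
#' oriented by its Pearson correlation with `orientation` (flipped when
#' negative) and thresholded at zero: A where PC1 > 0, B where PC1 < 0.
#'
#' @param corr correlation matrix from [correlation_matrix()].
#' @param orientation numeric per-bin vector (length = number of bins) or a
#'   `signal_track` binned at `resolution`, correlating positively with the
#'   A state (e.g. gene density or GC).
#' @param resolution bin size in bp (used when `orientation` is a track).
#' @param chrom chromosome name carried into the result.
#' @return data.frame of class `compartment_track`: `bin`, `start`, `end`,
#'   `pc1`, `label` (A/B/NA).
#' @export
compartment_pc1 <- function(corr, orientation, resolution, chrom = "chr") {
  n <- nrow(corr)
  if (inherits(orientation, "signal_track")) {
    ov <- rep(NA_real_, n)
    sel <- orientation$chrom == chrom | length(unique(orientation$chrom)) == 1
    tr <- orientation[sel, , drop = FALSE]
    b <- floor(tr$start / resolution) + 1
    ov[b[b >= 1 & b <= n]] <- tr$value[b >= 1 & b <= n]
    orientation <- ov
  }
  if (length(orientation) != n)
    stopf("orientation must cover all %d bins", n)
  valid <- which(rowSums(is.na(corr)) < n)
  sub <- corr[valid, valid, drop = FALSE]
  complete <- rowSums(is.na(sub)) == 0
  valid <- valid[complete]
  sub <- sub[complete, complete, drop = FALSE]
  if (length(valid) < 3) stopf("fewer than 3 valid bins")
  pca <- stats::prcomp(sub, center = TRUE, scale. = FALSE)
  ev <- pca$sdev^2
  if (length(ev) >= 2 && abs(ev[1] - ev[2]) < 1e-9)
    stopf("ambiguous PC1: degenerate leading eigenvalues")
  pc1 <- pca$x[, 1]
  pc1 <- pc1 / stats::sd(pc1)
  r <- suppressWarnings(stats::cor(pc1, orientation[valid],
                                   use = "complete.obs"))
  if (is.finite(r) && r < 0) pc1 <- -pc1
  full <- rep(NA_real_, n)
  full[valid] <- pc1
  label <- ifelse(is.na(full), NA_character_,
                  ifelse(full > 0, "A", ifelse(full < 0, "B", NA_character_)))
  out <- data.frame(bin = seq_len(n), start = (seq_len(n) - 1) * resolution,
                    end = seq_len(n) * resolution, pc1 = full, label = label,
                    chrom = chrom, stringsAsFactors = FALSE)
  class(out) <- c("compartment_track", "data.frame")
  out
}

#' Concordance between two compartment tracks
#'
#' @param a,b `compartment_track`s on the same chromosome and resolution.
#' @return list: `fraction_agree` (share of co-defined bins with equal
#'   label), `transitions_a`, `transitions_b` (bins where the label
#'   changes), `transition_overlap` (transitions of `a` with a transition of
#'   `b` within +/- 1 bin), `n_codefined`.
#' @export
compartment_concordance <- function(a, b) {
  if (nrow(a) != nrow(b)) stopf("tracks differ in bin count")
  ok <- !is.na(a$label) & !is.na(b$label)
  if (!any(ok)) stopf("no co-defined bins")
  frac <- mean(a$label[ok] == b$label[ok])
  trans <- function(lab) {
    d <- which(!is.na(lab[-1]) & !is.na(lab[-length(lab)]) &
                 lab[-1] != lab[-length(lab)])
    d + 1L   # bin where the new label starts
  }
  ta <- trans(a$label); tb <- trans(b$label)
  overlap <- if (length(ta) && length(tb))
    sum(vapply(ta, function(t) any(abs(tb - t) <= 1), logical(1))) else 0L
  list(fraction_agree = frac, transitions_a = ta, transitions_b = tb,
       transition_overlap = overlap, n_codefined = sum(ok))
}
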
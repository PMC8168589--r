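# Contamination-mixing simulation: blend two valid-pairs sets at stated
# fractions and ask at which fraction reference boundaries become
# detectable as an aggregate insulation dip.

#' Mix two pairs sets at a stated fraction
#'
#' Draws exactly `round(n * fraction_b)` pairs without replacement from `b`
#' (round-half-even) and the remainder from `a`. Each record keeps a
#' provenance tag for audit.
#'
#' @param a,b pairs data.frames.
#' @param fraction_b fraction of the output drawn from `b` (in 0..1).
#' @param n total output size.
#' @param seed RNG seed (deterministic output).
#' @return Pairs table of `n` rows with a `source` column ("a"/"b") and
#'   attributes `n_a`, `n_b`.
#' @export
mix_pairs <- function(a, b, fraction_b, n, seed) {
  if (fraction_b < 0 || fraction_b > 1) stopf("fraction_b must be in [0, 1]")
  n_b <- round(n * fraction_b)
  n_a <- n - n_b
  if (n_b > nrow(b))
    stopf("need %d pairs from b but only %d available", n_b, nrow(b))
  if (n_a > nrow(a))
    stopf("need %d pairs from a but only %d available", n_a, nrow(a))
  cols <- intersect(names(a), names(b))
  out <- with_local_seed(seed, {
    ia <- if (n_a > 0) sample.int(nrow(a), n_a) else integer(0)
    ib <- if (n_b > 0) sample.int(nrow(b), n_b) else integer(0)
    rbind(cbind(a[ia, cols, drop = FALSE], source = rep("a", n_a)),
          cbind(b[ib, cols, drop = FALSE], source = rep("b", n_b)))
  })
  rownames(out) <- NULL
  attr(out, "n_a") <- n_a
  attr(out, "n_b") <- n_b
  out
}

#' Boundary dip depth of a pairs set
#'
#' Builds balanced matrices from the pairs, computes insulation, centers a
#' metaplot on the reference boundaries, and reports the dip depth: the
#' mean of the two flank-edge columns minus the central column. A positive
#' depth means contacts are depleted at the reference boundaries.
#'
#' @param pairs pairs data.frame.
#' @param assembly [genome_assembly()].
#' @param boundaries reference boundary table (from [call_boundaries()],
#'   needs `chrom` and `start`/`end` columns).
#' @param resolution matrix resolution in bp (default 25 kb).
#' @param windows insulation windows in bp.
#' @param flank metaplot half-width in bp (multiple of resolution).
#' @return list: `depth`, `metaplot` (data.frame), `tracks`.
#' @export
boundary_dip <- function(pairs, assembly, boundaries, resolution = 25e3,
                         windows = default_windows, flank = 500e3) {
  mats <- bin_pairs(pairs, assembly, resolution)
  heat <- NULL
  tracks <- list()
  for (chrom in names(mats)) {
    bd <- boundaries[boundaries$chrom == chrom, , drop = FALSE]
    if (nrow(bd) == 0) next
    tr <- insulation_scores(balance_matrix(mats[[chrom]]), windows)
    tracks[[chrom]] <- tr
    h <- feature_insulation_heatmap(tr, bd, flank)
    heat <- rbind(heat, h)
  }
  if (is.null(heat) || all(is.na(heat)))
    stopf("no reference boundary lands on a defined insulation track")
  mp <- aggregate_metaplot(heat)
  nc <- nrow(mp)
  depth <- mean(c(mp$mean[1], mp$mean[nc])) - mp$mean[(nc + 1) / 2]
  list(depth = depth, metaplot = mp, tracks = tracks)
}

#' Contamination sweep over mixing fractions
#'
#' For each fraction, a fresh seeded mixture of `n` pairs is drawn and its
#' boundary dip depth measured; the minimal detectable fraction is the
#' smallest with depth >= `tau`.
#'
#' @param a pairs of the unstructured (background) sample.
#' @param b pairs of the structured (contaminating) sample.
#' @param assembly [genome_assembly()].
#' @param boundaries reference boundaries (typically called on pure `b`).
#' @param fractions ascending mixing fractions.
#' @param n pairs per mixture.
#' @param seed base seed; each fraction uses a derived sub-seed.
#' @param tau detectability threshold on the dip depth (z units).
#' @param resolution,windows,flank passed to [boundary_dip()].
#' @return list: `table` (fraction, n_a, n_b, depth, detectable),
#'   `min_detectable_fraction` (NA when none).
#' @export
mixing_sweep <- function(a, b, assembly, boundaries,
                         fractions = seq(0, 0.5, by = 0.1), n = 2e6,
                         seed = 1, tau = 0.3, resolution = 25e3,
                         windows = default_windows, flank = 500e3) {
  fractions <- sort(fractions)
  rows <- lapply(seq_along(fractions), function(k) {
    mixed <- mix_pairs(a, b, fractions[k], n, seed = sub_seed(seed, k))
    dip <- boundary_dip(mixed, assembly, boundaries, resolution, windows,
                        flank)
    data.frame(fraction = fractions[k], n_a = attr(mixed, "n_a"),
               n_b = attr(mixed, "n_b"), depth = dip$depth,
               detectable = dip$depth >= tau)
  })
  tab <- do.call(rbind, rows)
  min_det <- if (any(tab$detectable)) min(tab$fraction[tab$detectable]) else NA_real_
  list(table = tab, min_detectable_fraction = min_det, tau = tau)
}
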
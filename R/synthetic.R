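# Synthetic valid-pairs generator with known ground truth. Pairs are drawn
# by an anchor + distance scheme (distance from a power-law decay with an
# optional lognormal long-range bump) and thinned by acceptance weights
# that multiply the proposal density: x beta when both ends fall in one
# true contact domain, x gamma when both ends share a compartment label,
# x eta when the pair is anti-diagonally symmetric about a hinge pivot.
# This produces the map-level signatures the detectors consume (block
# enrichment, checkerboard, flares) without simulating polymer mechanics.

#' Synthetic dataset specification
#'
#' @param assembly [genome_assembly()]; default two 20-Mb chromosomes.
#' @param n_pairs total cis pairs to generate.
#' @param decay list: `alpha` (power-law exponent), `min_dist`, `max_dist`
#'   (bp; `NULL` = chromosome length), optional `bump_mode`, `bump_sdlog`,
#'   `bump_weight` (lognormal long-range component).
#' @param tads `NULL` or list: `mean_size`, `cv` (size dispersion),
#'   `beta` (within-domain enrichment >= 1), optional `domains` (explicit
#'   interval table of enrichment islands instead of a full partition).
#' @param compartments `NULL` or list: `block_size`, `gamma` (>= 1).
#' @param hinges `NULL` or list: `spacing`, `half_width`, `eta` (>= 1),
#'   `sigma` (anti-diagonal tolerance, bp).
#' @param enhancers `NULL` or list: per-chromosome counts `n_se`,
#'   `n_per_group`, `slot_spacing`, `domain_size`, `domain_beta`.
#' @param seed RNG seed; the generated pairs are a pure function of the
#'   spec including the seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(assembly = default_assembly(), n_pairs = 2e6,
                           decay = list(alpha = 1.0, min_dist = 20e3,
                                        max_dist = NULL),
                           tads = NULL, compartments = NULL, hinges = NULL,
                           enhancers = NULL, seed = 1) {
  if (n_pairs <= 0) stopf("n_pairs must be positive")
  for (f in c("beta")) if (!is.null(tads) && tads[[f]] < 1)
    stopf("enrichment factors must be >= 1")
  if (!is.null(compartments) && compartments$gamma < 1)
    stopf("enrichment factors must be >= 1")
  if (!is.null(hinges)) {
    if (hinges$eta < 1) stopf("enrichment factors must be >= 1")
    if (hinges$half_width >= hinges$spacing / 2)
      stopf("infeasible hinge geometry: half_width must be < spacing/2")
  }
  structure(list(assembly = assembly, n_pairs = n_pairs, decay = decay,
                 tads = tads, compartments = compartments, hinges = hinges,
                 enhancers = enhancers, seed = seed),
            class = "synthetic_spec")
}

#' Default desk-scale assembly: two 20-Mb chromosomes
#' @return A [genome_assembly()].
#' @export
default_assembly <- function() {
  genome_assembly(c("chrS1", "chrS2"), c(20e6, 20e6))
}

#' Named synthetic presets
#'
#' `null` (decay only), `tads` (TAD partition, beta = 3), `compartments`
#' (1-Mb checkerboard, gamma = 2), `sperm` (hinge flares: 1-Mb pivot
#' spacing, 150-kb petal half-width, eta = 3, plus a mitotic-like
#' long-range decay bump at 2 Mb), and `post_zga_enhancers` (graded
#' enhancer signal with small contact domains at the strong enhancers).
#'
#' @param name preset name.
#' @param seed RNG seed.
#' @param n_pairs total pairs (default 2e6, the desk-scale depth).
#' @param assembly assembly (default two 20-Mb chromosomes).
#' @return A [synthetic_spec()].
#' @export
synthetic_preset <- function(name = c("null", "tads", "compartments",
                                      "sperm", "post_zga_enhancers"),
                             seed = 1, n_pairs = 2e6,
                             assembly = default_assembly()) {
  name <- match.arg(name)
  base <- list(assembly = assembly, n_pairs = n_pairs, seed = seed)
  spec <- switch(
    name,
    null = synthetic_spec(assembly, n_pairs, seed = seed),
    tads = synthetic_spec(assembly, n_pairs, seed = seed,
                          tads = list(mean_size = 500e3, cv = 0.3, beta = 3)),
    compartments = synthetic_spec(assembly, n_pairs, seed = seed,
                                  compartments = list(block_size = 1e6,
                                                      gamma = 2)),
    sperm = synthetic_spec(assembly, n_pairs, seed = seed,
                           decay = list(alpha = 0.45, min_dist = 20e3,
                                        max_dist = NULL, bump_mode = 2e6,
                                        bump_sdlog = 0.35,
                                        bump_weight = 0.25),
                           hinges = list(spacing = 1e6, half_width = 150e3,
                                         eta = 3, sigma = 25e3)),
    post_zga_enhancers = synthetic_spec(
      assembly, n_pairs, seed = seed,
      tads = list(beta = 3, mean_size = NA, cv = NA, domains = NULL),
      enhancers = list(n_se = 6, n_per_group = 10, slot_spacing = 500e3,
                       domain_size = 90e3, domain_beta = 3)))
  attr(spec, "preset") <- name
  spec
}

# ---- truth construction ---------------------------------------------------

make_truth <- function(spec) {
  asm <- spec$assembly
  truth <- list(assembly = asm, tads = NULL, boundaries = NULL,
                compartments = NULL, hinges = NULL, enhancers = NULL)
  seed0 <- sub_seed(spec$seed, 101)
  # enhancers first: the enhancer preset anchors contact domains on them
  if (!is.null(spec$enhancers)) {
    e <- spec$enhancers
    truth$enhancers <- with_local_seed(seed0, do.call(rbind, lapply(
      seq_len(nrow(asm)), function(k) {
        L <- asm$length[k]
        slots <- seq(e$slot_spacing / 2, L - e$slot_spacing / 2,
                     by = e$slot_spacing)
        n_tot <- e$n_se + 3 * e$n_per_group
        if (n_tot > length(slots)) stopf("too many enhancers for assembly")
        pos <- sort(sample(slots, n_tot))
        grp <- sample(rep(c("SE", "G3", "G2", "G1"),
                          c(e$n_se, rep(e$n_per_group, 3))))
        data.frame(chrom = asm$chrom[k], center = pos, group = grp,
                   stringsAsFactors = FALSE)
      })))
  }
  if (!is.null(spec$tads)) {
    if (!is.null(spec$enhancers)) {
      # small contact domains centered on the strong enhancers
      e <- truth$enhancers
      strong <- e[e$group %in% c("SE", "G3"), , drop = FALSE]
      half <- spec$enhancers$domain_size / 2
      truth$tads <- intervals(strong$chrom,
                              pmax(0, strong$center - half),
                              strong$center + half)[, c("chrom", "start", "end")]
      truth$boundaries <- NULL
    } else {
      t <- spec$tads
      shape <- 1 / t$cv^2
      doms <- with_local_seed(sub_seed(spec$seed, 202), do.call(rbind, lapply(
        seq_len(nrow(asm)), function(k) {
          L <- asm$length[k]
          sizes <- numeric(0)
          while (sum(sizes) < L)
            sizes <- c(sizes, stats::rgamma(50, shape = shape,
                                            scale = t$mean_size / shape))
          edges <- pmin(cumsum(sizes), L)
          edges <- round(unique(edges))
          starts <- c(0, edges[-length(edges)])
          keep <- edges - starts >= 2 * 25e3   # no sub-bin slivers
          data.frame(chrom = asm$chrom[k], start = starts[keep],
                     end = edges[keep], stringsAsFactors = FALSE)
        })))
      truth$tads <- doms
      bnd <- do.call(rbind, lapply(split(doms, doms$chrom), function(d) {
        d <- d[order(d$start), ]
        data.frame(chrom = d$chrom[-1], pos = d$start[-1],
                   stringsAsFactors = FALSE)
      }))
      rownames(bnd) <- NULL
      truth$boundaries <- bnd
    }
  }
  if (!is.null(spec$compartments)) {
    bs <- spec$compartments$block_size
    truth$compartments <- do.call(rbind, lapply(seq_len(nrow(asm)), function(k) {
      L <- asm$length[k]
      starts <- seq(0, L - 1, by = bs)
      ends <- pmin(starts + bs, L)
      data.frame(chrom = asm$chrom[k], start = starts, end = ends,
                 label = ifelse(seq_along(starts) %% 2 == 1, "A", "B"),
                 stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(spec$hinges)) {
    h <- spec$hinges
    truth$hinges <- do.call(rbind, lapply(seq_len(nrow(asm)), function(k) {
      L <- asm$length[k]
      data.frame(chrom = asm$chrom[k],
                 pivot = seq(h$spacing / 2, L - h$spacing / 2,
                             by = h$spacing),
                 half_width = h$half_width, stringsAsFactors = FALSE)
    }))
  }
  truth
}

#' Compartment truth labels at a given resolution
#'
#' @param truth a TruthSet from [generate_contact_pairs()].
#' @param chrom chromosome.
#' @param resolution bin size (bp).
#' @param n_bins number of bins.
#' @return Character vector of A/B labels per bin (by bin midpoint).
#' @export
truth_compartment_labels <- function(truth, chrom, resolution, n_bins) {
  blocks <- truth$compartments[truth$compartments$chrom == chrom, ,
                               drop = FALSE]
  if (nrow(blocks) == 0) stopf("no compartment truth on %s", chrom)
  mids <- (seq_len(n_bins) - 0.5) * resolution
  idx <- findInterval(mids, blocks$start)
  blocks$label[idx]
}

# ---- pair sampling --------------------------------------------------------

sample_distances <- function(k, decay, L) {
  alpha <- decay$alpha
  smin <- decay$min_dist
  smax <- decay$max_dist %||% L
  bw <- decay$bump_weight %||% 0
  u <- stats::runif(k)
  from_bump <- bw > 0 & stats::runif(k) < bw
  d <- numeric(k)
  npl <- sum(!from_bump)
  if (npl > 0) {
    upl <- u[!from_bump]
    d[!from_bump] <- if (abs(alpha - 1) < 1e-12) {
      smin * (smax / smin)^upl
    } else {
      (smin^(1 - alpha) + upl * (smax^(1 - alpha) - smin^(1 - alpha)))^(1 / (1 - alpha))
    }
  }
  nbu <- sum(from_bump)
  if (nbu > 0) {
    sdlog <- decay$bump_sdlog %||% 0.35
    meanlog <- log(decay$bump_mode) + sdlog^2   # mode parameterization
    d[from_bump] <- stats::rlnorm(nbu, meanlog = meanlog, sdlog = sdlog)
  }
  d
}

sample_pairs_chrom <- function(chrom, L, n, spec, truth, seed) {
  t_doms <- if (!is.null(truth$tads))
    truth$tads[truth$tads$chrom == chrom, , drop = FALSE] else NULL
  comp_bs <- if (!is.null(spec$compartments)) spec$compartments$block_size
  pivots <- if (!is.null(truth$hinges))
    truth$hinges$pivot[truth$hinges$chrom == chrom] else NULL
  beta <- if (!is.null(spec$tads)) spec$tads$beta %||%
    spec$enhancers$domain_beta else 1
  if (!is.null(spec$enhancers)) beta <- spec$enhancers$domain_beta
  gamma <- if (!is.null(spec$compartments)) spec$compartments$gamma else 1
  eta <- if (!is.null(spec$hinges)) spec$hinges$eta else 1
  wmax <- beta * gamma * eta
  smin <- spec$decay$min_dist
  smax <- spec$decay$max_dist %||% L
  dom_idx <- function(p) {
    if (is.null(t_doms) || nrow(t_doms) == 0) return(rep(0L, length(p)))
    i <- findInterval(p, t_doms$start)
    inside <- i > 0 & p < t_doms$end[pmax(i, 1)]
    ifelse(inside, i, 0L)
  }
  with_local_seed(seed, {
    p1_out <- numeric(0); p2_out <- numeric(0)
    while (length(p1_out) < n) {
      k <- min(2e6, max(1e5, ceiling((n - length(p1_out)) * wmax * 1.3)))
      a <- stats::runif(k, 0, L)
      d <- sample_distances(k, spec$decay, L)
      sgn <- sample(c(-1, 1), k, replace = TRUE)
      b <- a + sgn * d
      keep <- b >= 0 & b < L & d >= smin & d <= smax
      w <- rep(1, k)
      if (beta > 1) {
        i1 <- dom_idx(a); i2 <- dom_idx(b)
        w <- w * ifelse(i1 > 0 & i1 == i2, beta, 1)
      }
      if (gamma > 1) {
        same <- (floor(a / comp_bs) %% 2) == (floor(b / comp_bs) %% 2)
        w <- w * ifelse(same, gamma, 1)
      }
      if (eta > 1 && length(pivots) > 0) {
        mid <- (a + b) / 2
        qi <- pmin(pmax(round((mid - pivots[1]) / spec$hinges$spacing), 0),
                   length(pivots) - 1)
        q <- pivots[1] + qi * spec$hinges$spacing
        hit <- abs(a - q) <= spec$hinges$half_width &
          abs(b - q) <= spec$hinges$half_width &
          abs(a + b - 2 * q) <= spec$hinges$sigma
        w <- w * ifelse(hit, eta, 1)
      }
      acc <- keep & stats::runif(k) < w / wmax
      p1_out <- c(p1_out, floor(a[acc]))
      p2_out <- c(p2_out, floor(b[acc]))
    }
    lo <- pmin(p1_out, p2_out)[seq_len(n)]
    hi <- pmax(p1_out, p2_out)[seq_len(n)]
    data.frame(chrom1 = chrom, pos1 = lo, chrom2 = chrom, pos2 = hi,
               strand1 = ".", strand2 = ".", stringsAsFactors = FALSE)
  })
}

#' Generate synthetic valid pairs with ground truth
#'
#' @param spec a [synthetic_spec()].
#' @return list: `pairs` (canonical cis pairs table) and `truth` (TruthSet:
#'   `tads`, `boundaries`, `compartments`, `hinges`, `enhancers`).
#' @export
generate_contact_pairs <- function(spec) {
  truth <- make_truth(spec)
  asm <- spec$assembly
  alloc <- floor(spec$n_pairs * asm$length / sum(asm$length))
  rem <- spec$n_pairs - sum(alloc)
  if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1
  pairs <- do.call(rbind, lapply(seq_len(nrow(asm)), function(k) {
    sample_pairs_chrom(asm$chrom[k], asm$length[k], alloc[k], spec, truth,
                       seed = sub_seed(spec$seed, 1000 + k))
  }))
  rownames(pairs) <- NULL
  list(pairs = pairs, truth = truth)
}

# ---- signal-track rendering ----------------------------------------------

#' Render enhancer truth as peaks, signal and TSS tracks
#'
#' Each enhancer becomes a Gaussian signal kernel of group-dependent height
#' on a fixed-bin track plus constituent peaks (super-enhancers render as a
#' cluster of three nearby peaks so that stitching produces one large
#' high-score region). TSS decoys carry their own kernels and peaks fully
#' inside the TSS exclusion window, exercising the exclusion step.
#'
#' @param truth TruthSet with `enhancers`.
#' @param heights named kernel heights per group; SE heights are drawn
#'   uniformly from `se_height_range` per constituent.
#' @param se_height_range range of SE constituent heights.
#' @param noise_sd Gaussian noise sd added per signal bin.
#' @param seed RNG seed.
#' @param bin signal bin size (default 10 kb).
#' @param kernel_sd Gaussian kernel sd in bp.
#' @param peak_halfwidth constituent peak half-width in bp.
#' @param n_tss_decoys TSS decoys per chromosome.
#' @return list: `peaks` (BED-like, name = enhancer id), `signal`
#'   (`signal_track`), `tss` (interval table), `truth_groups` (data.frame
#'   enhancer id -> group).
#' @export
generate_signal_tracks <- function(truth,
                                   heights = c(G1 = 2, G2 = 4, G3 = 8),
                                   se_height_range = c(10, 20),
                                   noise_sd = 0.5, seed = 1, bin = 10e3,
                                   kernel_sd = 15e3, peak_halfwidth = 3e3,
                                   n_tss_decoys = 10) {
  enh <- truth$enhancers
  if (is.null(enh)) stopf("truth contains no enhancer placements")
  asm <- truth$assembly
  with_local_seed(sub_seed(seed, 33), {
    peak_rows <- list(); tss_rows <- list(); kernels <- list()
    pid <- 0
    for (r in seq_len(nrow(enh))) {
      grp <- enh$group[r]
      centers <- if (grp == "SE")
        enh$center[r] + c(-12e3, 0, 12e3) else enh$center[r]
      hts <- if (grp == "SE")
        stats::runif(3, se_height_range[1], se_height_range[2])
      else rep(heights[[grp]], 1)
      for (j in seq_along(centers)) {
        pid <- pid + 1
        peak_rows[[pid]] <- data.frame(
          chrom = enh$chrom[r], start = centers[j] - peak_halfwidth,
          end = centers[j] + peak_halfwidth,
          name = sprintf("enh%d_%s", r, grp), stringsAsFactors = FALSE)
        kernels[[pid]] <- data.frame(chrom = enh$chrom[r],
                                     center = centers[j], height = hts[j])
      }
    }
    # TSS decoys with their own signal, away from enhancers
    for (k in seq_len(nrow(asm))) {
      L <- asm$length[k]
      cand <- stats::runif(5 * n_tss_decoys, 0.02 * L, 0.98 * L)
      ec <- enh$center[enh$chrom == asm$chrom[k]]
      ok <- vapply(cand, function(p) all(abs(p - ec) > 100e3), logical(1))
      tpos <- cand[ok][seq_len(min(n_tss_decoys, sum(ok)))]
      for (p in tpos) {
        pid <- pid + 1
        peak_rows[[pid]] <- data.frame(chrom = asm$chrom[k], start = p - 800,
                                       end = p + 800, name = "tss_decoy",
                                       stringsAsFactors = FALSE)
        kernels[[pid]] <- data.frame(chrom = asm$chrom[k], center = p,
                                     height = 5)
        tss_rows[[length(tss_rows) + 1]] <-
          data.frame(chrom = asm$chrom[k], start = p - 50, end = p + 50,
                     stringsAsFactors = FALSE)
      }
    }
    kern <- do.call(rbind, kernels)
    sig <- do.call(rbind, lapply(seq_len(nrow(asm)), function(k) {
      L <- asm$length[k]
      starts <- seq(0, L - bin, by = bin)
      x <- starts + bin / 2
      v <- stats::rnorm(length(x), 0, noise_sd)
      kk <- kern[kern$chrom == asm$chrom[k], , drop = FALSE]
      for (j in seq_len(nrow(kk)))
        v <- v + kk$height[j] * exp(-(x - kk$center[j])^2 / (2 * kernel_sd^2))
      data.frame(chrom = asm$chrom[k], start = starts, end = starts + bin,
                 value = v, stringsAsFactors = FALSE)
    }))
    peaks <- do.call(rbind, peak_rows)
    tss <- if (length(tss_rows)) do.call(rbind, tss_rows) else NULL
    list(peaks = intervals(peaks$chrom, pmax(0, peaks$start), peaks$end,
                           name = peaks$name),
         signal = signal_track(sig$chrom, sig$start, sig$end, sig$value),
         tss = if (!is.null(tss)) intervals(tss$chrom, tss$start, tss$end)
         else NULL,
         truth_groups = data.frame(id = sprintf("enh%d_%s", seq_len(nrow(enh)),
                                                enh$group),
                                   chrom = enh$chrom, center = enh$center,
                                   group = enh$group,
                                   stringsAsFactors = FALSE))
  })
}

#' Deterministic fixture contact matrices
#'
#' Noise-free matrices for unit tests: `constant` (all entries `value`),
#' `two_block` (two equal blocks with `within`/`between` values),
#' `checkerboard` (alternating blocks of `block_bins` bins at
#' `hi`/`lo`), `hinge` (ones plus an anti-diagonal of `eta` through the
#' center, reach `half_width_bins`).
#'
#' @param pattern one of `"constant"`, `"two_block"`, `"checkerboard"`,
#'   `"hinge"`.
#' @param n_bins matrix size (>= 8).
#' @param resolution bp per bin (default 25 kb).
#' @param value,within,between,block_bins,hi,lo,eta,half_width_bins
#'   pattern parameters.
#' @return A `contact_matrix` (marked balanced; entries are exact).
#' @export
make_fixture_matrix <- function(pattern = c("constant", "two_block",
                                            "checkerboard", "hinge"),
                                n_bins, resolution = 25e3, value = 1,
                                within = 10, between = 1, block_bins = NULL,
                                hi = 2, lo = 0.5, eta = 5,
                                half_width_bins = NULL) {
  pattern <- match.arg(pattern)
  if (n_bins < 8) stopf("n_bins must be >= 8")
  n <- as.integer(n_bins)
  m <- switch(pattern,
    constant = matrix(value, n, n),
    two_block = {
      half <- n %/% 2
      blk <- c(rep(1L, half), rep(2L, n - half))
      ifelse(outer(blk, blk, "=="), within, between)
    },
    checkerboard = {
      bb <- block_bins %||% max(2L, n %/% 8)
      lab <- (ceiling(seq_len(n) / bb) %% 2)
      ifelse(outer(lab, lab, "=="), hi, lo)
    },
    hinge = {
      hw <- half_width_bins %||% (n %/% 4)
      p <- (n + 1) %/% 2
      m <- matrix(1, n, n)
      d <- seq_len(min(hw, p - 1, n - p))
      m[cbind(p - d, p + d)] <- eta
      m[cbind(p + d, p - d)] <- eta
      m
    })
  new_contact_matrix("fixture", resolution, m, mask = rep(TRUE, n),
                     weights = rep(1, n), balanced = TRUE)
}
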
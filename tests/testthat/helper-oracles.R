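# Independent brute-force oracles. These deliberately re-derive every
# quantity with naive loops and textbook formulas, sharing no code with the
# package implementations they check.

oracle_zscore <- function(x) {
  ok <- is.finite(x)
  m <- sum(x[ok]) / sum(ok)
  v <- sum((x[ok] - m)^2) / (sum(ok) - 1)
  out <- rep(NA_real_, length(x))
  out[ok] <- if (v <= 0 || is.na(v)) 0 else (x[ok] - m) / sqrt(v)
  out
}

# diamond insulation z-scores, one window, naive triple loop
oracle_insulation <- function(counts, w_bins, eps = 1e-6,
                              mask = rep(TRUE, nrow(counts))) {
  n <- nrow(counts)
  raw <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - w_bins < 1 || i + w_bins > n || !mask[i]) next
    acc <- c()
    for (a in (i - w_bins):(i - 1))
      for (b in (i + 1):(i + w_bins))
        if (!is.na(counts[a, b])) acc <- c(acc, counts[a, b])
    if (length(acc)) raw[i] <- sum(acc) / length(acc)
  }
  oracle_zscore(log2(raw + eps))
}

# per-diagonal expected and O/E, naive loops
oracle_oe <- function(counts) {
  n <- nrow(counts)
  exp_d <- rep(NA_real_, n)
  for (d in 0:(n - 1)) {
    acc <- c()
    for (i in seq_len(n - d)) {
      v <- counts[i, i + d]
      if (!is.na(v)) acc <- c(acc, v)
    }
    if (length(acc)) exp_d[d + 1] <- mean(acc)
  }
  oe <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    e <- exp_d[abs(i - j) + 1]
    if (!is.na(counts[i, j]) && !is.na(e) && e > 0) oe[i, j] <- counts[i, j] / e
  }
  list(oe = oe, expected = exp_d)
}

# pairwise Pearson over mutually defined entries, textbook formula
oracle_cor <- function(x) {
  n <- nrow(x)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    ok <- !is.na(x[i, ]) & !is.na(x[j, ])
    if (sum(ok) < 2) next
    a <- x[i, ok]; b <- x[j, ok]
    sa <- sqrt(sum((a - mean(a))^2)); sb <- sqrt(sum((b - mean(b))^2))
    if (sa == 0 || sb == 0) next
    r <- sum((a - mean(a)) * (b - mean(b))) / (sa * sb)
    out[i, j] <- out[j, i] <- r
  }
  for (i in seq_len(n)) if (any(!is.na(x[i, ]))) out[i, i] <- 1
  out
}

# alternating row/column Sinkhorn scaling, marginals to mean 1
oracle_sinkhorn <- function(counts, iters = 5000, tol = 1e-12) {
  a <- counts
  for (k in seq_len(iters)) {
    r <- rowSums(a)
    a <- a / (r / mean(r))
    cs <- colSums(a)
    a <- t(t(a) / (cs / mean(cs)))
    if (max(abs(rowSums(a) / mean(rowSums(a)) - 1)) < tol &&
        max(abs(colSums(a) / mean(colSums(a)) - 1)) < tol) break
  }
  a / mean(rowSums(a))   # unit mean marginal
}

# interval-sum score with per-bin flooring, naive loop over track rows
oracle_region_sum <- function(signal, control, chrom, s, e, bin) {
  tot <- 0
  for (r in seq_len(nrow(signal))) {
    if (signal$chrom[r] != chrom) next
    ov <- min(e, signal$end[r]) - max(s, signal$start[r])
    if (ov <= 0) next
    v <- signal$value[r]
    if (!is.null(control)) {
      cmatch <- which(control$chrom == chrom & control$start == signal$start[r])
      if (length(cmatch)) v <- v - control$value[cmatch[1]]
    }
    tot <- tot + max(v, 0) * ov / bin
  }
  tot
}

# all-pairs overlap filter
oracle_drop_overlapping <- function(x, bl) {
  keep <- rep(TRUE, nrow(x))
  for (i in seq_len(nrow(x))) for (j in seq_len(nrow(bl))) {
    if (x$chrom[i] == bl$chrom[j] &&
        x$start[i] < bl$end[j] && bl$start[j] < x$end[i]) keep[i] <- FALSE
  }
  x[keep, , drop = FALSE]
}

# repeated pairwise merging until fixpoint
oracle_merge <- function(x, gap) {
  rows <- lapply(seq_len(nrow(x)),
                 function(i) list(chrom = x$chrom[i], start = x$start[i],
                                  end = x$end[i]))
  repeat {
    merged <- FALSE
    for (i in seq_along(rows)) {
      if (merged) break
      for (j in seq_along(rows)) {
        if (i == j) next
        a <- rows[[i]]; b <- rows[[j]]
        if (a$chrom == b$chrom &&
            max(a$start, b$start) - min(a$end, b$end) <= gap) {
          rows[[i]] <- list(chrom = a$chrom, start = min(a$start, b$start),
                            end = max(a$end, b$end))
          rows[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  out <- do.call(rbind, lapply(rows, as.data.frame))
  out[order(out$chrom, out$start), , drop = FALSE]
}

# exhaustive slope-one scan on the rescaled ranked curve
oracle_se_cutoff <- function(scores) {
  n <- length(scores)
  s <- sort(scores)
  ys <- (s - s[1]) / (s[n] - s[1])
  xs <- seq(0, 1, length.out = n)
  cut_i <- NA
  for (i in seq_len(n - 1)) {   # find the highest segment with slope < 1
    sl <- (ys[i + 1] - ys[i]) / (xs[i + 1] - xs[i])
    if (sl < 1) cut_i <- i + 1
  }
  cutoff <- if (is.na(cut_i)) s[n] else s[cut_i]
  sum(scores > cutoff)
}

# random symmetric non-negative matrix with optional masked bins,
# wrapped as a balanced contact_matrix for definition-level checks
random_cm <- function(n, resolution = 25e3, mask_k = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rexp(n * n), n, n)
  m <- (m + t(m)) / 2
  mask <- rep(TRUE, n)
  if (mask_k > 0) {
    off <- sample(n, mask_k)
    mask[off] <- FALSE
    m[off, ] <- NA
    m[, off] <- NA
  }
  structure(list(chrom = "chrR", resolution = resolution, counts = m,
                 mask = mask, weights = rep(1, n), balanced = TRUE),
            class = "contact_matrix")
}
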
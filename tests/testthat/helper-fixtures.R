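# Shared synthetic fixtures, generated once per test run and cached across
# test files (the suite's presets all use seed 7 at the desk-scale depth).

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env, inherits = FALSE))
    assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env, inherits = FALSE)
}

FIXTURE_SEED <- 7
DESK_N <- 2e6

synth_data <- function(preset, seed = FIXTURE_SEED, n = DESK_N) {
  cached(sprintf("synth_%s_%d_%g", preset, seed, n),
         generate_contact_pairs(synthetic_preset(preset, seed = seed,
                                                 n_pairs = n)))
}

# balanced matrices for a cached preset
preset_matrices <- function(preset, resolution, seed = FIXTURE_SEED,
                            n = DESK_N) {
  cached(sprintf("mats_%s_%d_%g_%g", preset, seed, n, resolution), {
    g <- synth_data(preset, seed, n)
    lapply(bin_pairs(g$pairs, default_assembly(), resolution),
           balance_matrix)
  })
}

# insulation tracks for a cached preset
preset_tracks <- function(preset, resolution, windows, seed = FIXTURE_SEED,
                          n = DESK_N) {
  cached(sprintf("trk_%s_%d_%g_%g_%s", preset, seed, n, resolution,
                 paste(windows, collapse = "_")), {
    lapply(preset_matrices(preset, resolution, seed, n), insulation_scores,
           windows = windows)
  })
}

FLARE_WINDOWS <- c(50e3, 200e3)   # flare operating point (10-kb matrices)

preset_flares <- function(preset, seed = FIXTURE_SEED, n = DESK_N) {
  cached(sprintf("flares_%s_%d_%g", preset, seed, n), {
    trs <- preset_tracks(preset, 10e3, FLARE_WINDOWS, seed, n)
    do.call(rbind, lapply(trs, call_flares))
  })
}

preset_boundaries <- function(preset, seed = FIXTURE_SEED, n = DESK_N) {
  cached(sprintf("bnd_%s_%d_%g", preset, seed, n), {
    trs <- preset_tracks(preset, 25e3, default_windows, seed, n)
    do.call(rbind, lapply(trs, call_boundaries))
  })
}

# recall/precision of called vs true boundary bins at a bin tolerance
match_rates <- function(called_chrom, called_bin, true_chrom, true_bin,
                        tol = 1) {
  recall <- mean(mapply(function(ch, b)
    any(abs(called_bin[called_chrom == ch] - b) <= tol),
    true_chrom, true_bin))
  precision <- mean(mapply(function(ch, b)
    any(abs(true_bin[true_chrom == ch] - b) <= tol),
    called_chrom, called_bin))
  list(recall = recall, precision = precision)
}

# hand-built insulation track for toy caller tests
toy_track <- function(summary, resolution = 25e3, chrom = "chrT",
                      largest = summary, windows = c(2, 4) * resolution,
                      log2_dev = NULL) {
  structure(list(chrom = chrom, resolution = resolution, windows = windows,
                 scores = cbind(summary, largest), summary = summary,
                 largest = largest,
                 log2_dev = NULL,
                 summary_log2 = log2_dev %||% summary,
                 largest_log2 = log2_dev %||% largest),
            class = "insulation_track")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
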
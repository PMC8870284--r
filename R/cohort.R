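# Synthetic multichannel EEG cohorts with group-dependent inter-channel
# coupling. The generator mixes independent band-limited sources through a
# per-subject channel-coupling (correlation) matrix, so the Pearson
# connectivity consumed downstream is planted by construction: the
# "middle_aged" group couples at strength `coupling_mid`, the "elderly" group
# at `coupling_mid - coupling_delta`. It is a statistical stand-in for
# recorded EEG, not a biophysical model.

#' Configuration for a synthetic EEG cohort
#'
#' Describes a two-group (middle-aged-like vs elderly-like) cohort recorded in
#' up to three states (eyes open, eyes closed, visual working-memory task).
#' Channel signals are sums of alpha- and beta-band oscillations plus
#' band-limited noise, linearly mixed so that the expected inter-channel
#' correlation has mean off-diagonal strength \code{coupling_mid} (middle-aged)
#' or \code{coupling_mid - coupling_delta} (elderly), modulated by a fixed
#' spatial profile (nearby electrodes couple more strongly, in two
#' hemispheric blocks).
#'
#' @param n_per_group subjects per group (default 20).
#' @param n_channels number of electrodes (default 8; labelled FP1, FP2, C3,
#'   C4, P7, P8, O1, O2 when 8).
#' @param fs sampling rate in Hz (default 250).
#' @param duration_s named or unnamed duration(s) in seconds per state.
#'   Default: 300 s for resting states, 120 s for the working-memory task.
#' @param states subset of \code{c("eyes_open","eyes_closed","wm_task")}.
#' @param coupling_mid mean off-diagonal coupling strength in [0,1) for the
#'   middle-aged-like group.
#' @param coupling_delta coupling reduction (>= 0) applied to the elderly-like
#'   group; \code{coupling_mid - coupling_delta} must be >= 0.
#' @param coupling_jitter_sd per-subject SD of the coupling strength, so group
#'   distributions overlap and rank tests are non-degenerate.
#' @param structure_sd per-subject SD of edgewise perturbations of the spatial
#'   coupling profile; larger values make individual network topologies more
#'   idiosyncratic.
#' @param noise_sd additive white sensor-noise SD (channel signals have unit
#'   variance before noise).
#' @param seed master integer seed; per-recording seeds are derived from it by
#'   a stable hash of (seed, subject, group, state).
#' @return an object of class \code{cohort_config} (a validated list).
#' @examples
#' cfg <- cohort_config(n_per_group = 2, duration_s = c(60, 60, 60))
#' @export
cohort_config <- function(n_per_group = 20, n_channels = 8, fs = 250,
                          duration_s = c(eyes_open = 300, eyes_closed = 300,
                                         wm_task = 120),
                          states = STATES,
                          coupling_mid = 0.6, coupling_delta = 0.3,
                          coupling_jitter_sd = 0.05, structure_sd = 0.08,
                          noise_sd = 0.4, seed = 42L) {
  if (n_per_group < 1) stop_input("'n_per_group' must be >= 1")
  if (n_channels < 2) stop_input("'n_channels' must be >= 2")
  if (fs <= 0) stop_input("'fs' must be positive")
  states <- vapply(states, check_state, "")
  if (is.null(names(duration_s))) {
    duration_s <- rep_len(duration_s, length(states))
    names(duration_s) <- states
  }
  missing_states <- setdiff(states, names(duration_s))
  if (length(missing_states))
    stop_input("no duration_s given for state(s): ",
               paste(missing_states, collapse = ", "))
  if (any(duration_s <= 0)) stop_input("durations must be positive")
  if (coupling_mid < 0 || coupling_mid >= 1)
    stop_input("'coupling_mid' must be in [0, 1)")
  if (coupling_delta < 0) stop_input("'coupling_delta' must be >= 0")
  if (coupling_mid - coupling_delta < 0)
    stop_input("'coupling_mid' - 'coupling_delta' must be >= 0")
  if (noise_sd < 0) stop_input("'noise_sd' must be >= 0")
  labels <- if (n_channels == 8) DEFAULT_CHANNELS else
    sprintf("CH%02d", seq_len(n_channels))
  structure(list(
    n_per_group = as.integer(n_per_group), n_channels = as.integer(n_channels),
    fs = fs, duration_s = duration_s[states], states = unname(states),
    channel_labels = labels,
    coupling_mid = coupling_mid, coupling_delta = coupling_delta,
    coupling_jitter_sd = coupling_jitter_sd, structure_sd = structure_sd,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "cohort_config")
}

# Approximate 10-20 scalp coordinates for the default montage, used to build
# the spatial coupling profile (unit head radius, x = right, y = anterior).
montage_positions <- function(labels) {
  known <- rbind(
    FP1 = c(-0.31, 0.95), FP2 = c(0.31, 0.95),
    C3  = c(-0.50, 0.00), C4  = c(0.50, 0.00),
    P7  = c(-0.81, -0.59), P8 = c(0.81, -0.59),
    O1  = c(-0.31, -0.95), O2 = c(0.31, -0.95))
  if (all(labels %in% rownames(known))) return(known[labels, , drop = FALSE])
  # generic montage: equally spaced on a circle
  ang <- seq(0, 2 * pi, length.out = length(labels) + 1L)[seq_along(labels)]
  cbind(cos(ang), sin(ang))
}

# Fixed spatial coupling profile, normalised to mean 1 over off-diagonal
# pairs: strong within-hemisphere coupling (lateralised clusters), moderate
# homologous (mirror-electrode) bridges, weak diagonal cross-hemisphere
# coupling. High-coupling subjects therefore yield clustered thresholded
# topologies, with the homologous pairs keeping the network weight-connected.
coupling_profile <- function(labels) {
  pos <- montage_positions(labels)
  n <- nrow(pos)
  side <- sign(pos[, 1])
  same_side <- outer(side, side, function(a, b) a == b & a != 0)
  homolog <- outer(seq_len(n), seq_len(n), function(i, j)
    abs(pos[i, 1] + pos[j, 1]) < 1e-9 & abs(pos[i, 2] - pos[j, 2]) < 1e-9 & i != j)
  w <- matrix(0.45, n, n)
  w[homolog] <- 1.1
  w[same_side] <- 1.4
  diag(w) <- 0
  w * (n * (n - 1)) / sum(w)
}

# Draw one subject's channel correlation matrix: coupling * profile plus
# edgewise jitter, projected back to a valid correlation matrix.
subject_correlation <- function(coupling, profile, structure_sd) {
  n <- nrow(profile)
  eta <- matrix(0, n, n)
  eta[upper.tri(eta)] <- stats::rnorm(n * (n - 1) / 2, 0, structure_sd)
  eta <- eta + t(eta)
  r <- coupling * profile + eta
  r[r > 0.97] <- 0.97
  r[r < 0] <- 0
  diag(r) <- 1
  # nearest PSD projection (eigenvalue clamp), then rescale to unit diagonal
  e <- eigen(r, symmetric = TRUE)
  if (min(e$values) < 1e-8) {
    v <- pmax(e$values, 1e-8)
    r <- e$vectors %*% (v * t(e$vectors))
    r <- stats::cov2cor(r)
  }
  r
}

# One independent band-limited source: nonstationary narrowband activity
# (alpha- and beta-band filtered noise, the alpha rhythm waxing and waning as
# in resting EEG) plus weaker broadband background, standardised to unit
# variance. Narrowband noise keeps the effective number of independent
# samples per 20-s epoch modest, so epoch-level connectivity estimates
# fluctuate realistically instead of repeating a frozen oscillation.
bandlimited_source <- function(n_samples, fs) {
  bp <- function(lo, hi) signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  unit <- function(x) x / stats::sd(x)
  f_alpha <- stats::runif(1, 9, 12)
  f_beta <- stats::runif(1, 16, 28)
  alpha <- unit(signal::filtfilt(bp(f_alpha - 0.5, f_alpha + 0.5),
                                 stats::rnorm(n_samples)))
  beta <- unit(signal::filtfilt(bp(f_beta - 2, f_beta + 2),
                                stats::rnorm(n_samples)))
  broad <- unit(signal::filtfilt(bp(0.5, 45), stats::rnorm(n_samples)))
  s <- alpha + 0.5 * beta + 0.2 * broad
  (s - mean(s)) / stats::sd(s)
}

#' Generate one synthetic EEG recording
#'
#' Produces a single subject/state recording from a \code{\link{cohort_config}}.
#' Identical \code{(config, group, state, subject_seed)} reproduce the data
#' bit-for-bit; the caller's RNG state is left untouched.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param group \code{"middle_aged"} or \code{"elderly"}.
#' @param state one of \code{"eyes_open"}, \code{"eyes_closed"}, \code{"wm_task"}.
#' @param subject_seed integer seed for this recording (see
#'   \code{\link{simulate_cohort}} for the derivation used at cohort scale).
#' @param subject_id optional identifier stored on the recording.
#' @return an \code{eeg_recording}: list with \code{data} (channels x samples
#'   matrix), \code{fs}, \code{channel_labels}, \code{subject_id}, \code{group},
#'   \code{state}.
#' @examples
#' cfg <- cohort_config(duration_s = c(30, 30, 30))
#' rec <- simulate_subject(cfg, "middle_aged", "eyes_open", subject_seed = 1)
#' dim(rec$data)
#' @export
simulate_subject <- function(config, group, state, subject_seed,
                             subject_id = paste0(group, "_s1")) {
  stopifnot(inherits(config, "cohort_config"))
  check_group(group)
  check_state(state)
  if (!state %in% config$states)
    stop_input("state '", state, "' not in config$states")
  n_samples <- round(config$duration_s[[state]] * config$fs)
  n <- config$n_channels
  base <- if (group == "middle_aged") config$coupling_mid else
    config$coupling_mid - config$coupling_delta
  profile <- coupling_profile(config$channel_labels)
  data <- with_seed(as.integer(subject_seed), {
    coupling <- min(max(base + stats::rnorm(1, 0, config$coupling_jitter_sd), 0), 0.95)
    r <- subject_correlation(coupling, profile, config$structure_sd)
    mixing <- chol(r)  # upper-triangular; x = t(chol) %*% sources
    sources <- vapply(seq_len(n), function(i) bandlimited_source(n_samples, config$fs),
                      numeric(n_samples))
    x <- t(mixing) %*% t(sources)
    x + config$noise_sd * matrix(stats::rnorm(n * n_samples), n, n_samples)
  })
  rownames(data) <- config$channel_labels
  structure(list(data = data, fs = config$fs,
                 channel_labels = config$channel_labels,
                 subject_id = subject_id, group = group, state = state),
            class = "eeg_recording")
}

#' Generate a full synthetic cohort
#'
#' Generates \code{n_per_group} subjects per group in every configured state.
#' Per-recording seeds are a stable hash of (master seed, subject index, group,
#' state), so regeneration under the same config is bit-identical and
#' independent of generation order.
#'
#' @param config a \code{\link{cohort_config}}.
#' @return list of class \code{eeg_cohort}: \code{recordings} (list of
#'   \code{eeg_recording}), \code{config}, and a \code{manifest} data frame
#'   (subject_id, group, state).
#' @examples
#' cfg <- cohort_config(n_per_group = 1, states = "eyes_open",
#'                      duration_s = c(eyes_open = 30))
#' coh <- simulate_cohort(cfg)
#' length(coh$recordings)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  recs <- list()
  for (group in GROUPS) {
    for (i in seq_len(config$n_per_group)) {
      sid <- sprintf("%s_%02d", group, i)
      for (state in config$states) {
        seed_i <- derive_seed(config$seed, i, group, state)
        recs[[paste(sid, state, sep = ".")]] <-
          simulate_subject(config, group, state, seed_i, subject_id = sid)
      }
    }
  }
  manifest <- data.frame(
    subject_id = vapply(recs, `[[`, "", "subject_id"),
    group = vapply(recs, `[[`, "", "group"),
    state = vapply(recs, `[[`, "", "state"),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(recordings = recs, config = config, manifest = manifest),
            class = "eeg_cohort")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s | %s | %s: %d channels x %d samples @ %g Hz\n",
              x$subject_id, x$group, x$state, nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cat(sprintf("<eeg_cohort> %d recordings (%d per group x 2 groups x %d states)\n",
              length(x$recordings), x$config$n_per_group, length(x$config$states)))
  cat("  states:", paste(x$config$states, collapse = ", "), "\n")
  invisible(x)
}

#' Write a cohort to a directory of CSV files
#'
#' One CSV per recording (rows = samples, columns = channels, header = channel
#' labels) plus a \code{manifest.csv} with columns subject_id, group, state,
#' path.
#'
#' @param cohort an \code{eeg_cohort}.
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest data frame with file paths.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "eeg_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(cohort$recordings))
  for (k in seq_along(cohort$recordings)) {
    rec <- cohort$recordings[[k]]
    fn <- sprintf("%s_%s.csv", rec$subject_id, rec$state)
    utils::write.csv(as.data.frame(t(rec$data)), file.path(dir, fn),
                     row.names = FALSE)
    paths[k] <- fn
  }
  manifest <- cbind(cohort$manifest, path = paths,
                    fs = cohort$config$fs, stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort from a manifest directory written by \code{write_cohort_csv}
#'
#' @param dir directory containing \code{manifest.csv} and per-recording CSVs.
#' @return an \code{eeg_cohort} (config slot holds only fs and channel labels).
#' @export
read_cohort_csv <- function(dir) {
  mf <- utils::read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  recs <- vector("list", nrow(mf))
  for (k in seq_len(nrow(mf))) {
    d <- utils::read.csv(file.path(dir, mf$path[k]), check.names = FALSE)
    recs[[k]] <- structure(list(
      data = t(as.matrix(d)), fs = mf$fs[k], channel_labels = colnames(d),
      subject_id = mf$subject_id[k], group = mf$group[k], state = mf$state[k]),
      class = "eeg_recording")
    names(recs)[k] <- paste(mf$subject_id[k], mf$state[k], sep = ".")
  }
  structure(list(recordings = recs, config = NULL,
                 manifest = mf[c("subject_id", "group", "state")]),
            class = "eeg_cohort")
}
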
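#' Generate a pair of constant-phase-lag oscillations
#'
#' Fixture for the phase-locking estimator: two sinusoids at carrier frequency
#' `f_c` whose instantaneous phase difference is exactly `lag` radians, plus
#' optional additive white noise. With `noise_sd = 0` and an integer number of
#' carrier cycles in the recording, the downstream imaginary phase-locking
#' value equals `|sin(lag)|` to numerical precision.
#'
#' @param duration Length in seconds (must cover at least 10 carrier cycles).
#' @param fs Sampling rate in Hz.
#' @param f_c Carrier frequency in Hz.
#' @param lag Planted phase lag in radians (x leads y by `lag`).
#' @param noise_sd Additive white-noise standard deviation (amplitude units).
#' @param seed Optional seed.
#' @return List with numeric vectors `x` and `y` and the sampling rate `fs`.
#' @export
generatePhaseCoupledPair <- function(duration, fs, f_c, lag, noise_sd = 0, seed = NULL) {
  stopifnot_scalar(duration, "duration")
  stopifnot_scalar(fs, "fs")
  stopifnot_scalar(f_c, "f_c")
  if (duration * f_c < 10)
    stop("recording must span at least 10 cycles of f_c", call. = FALSE)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  withSeed(seed, {
    phi0 <- if (is.null(seed)) 0 else runif(1, -pi, pi)
    x <- cos(2 * pi * f_c * t + phi0)
    y <- cos(2 * pi * f_c * t + phi0 - lag)
    if (noise_sd > 0) {
      x <- x + rnorm(n, sd = noise_sd)
      y <- y + rnorm(n, sd = noise_sd)
    }
    list(x = x, y = y, fs = fs)
  })
}

# Band-limited unit-variance noise carrier.
bandNoise <- function(n, band, fs) {
  w <- rnorm(n)
  b <- bandpass(w, band, fs)
  b / sd(b)
}

# Slow positive modulator built from low-pass noise; `cutoff` in Hz.
slowModulator <- function(n, fs, cutoff) {
  w <- rnorm(n)
  bf <- signal::butter(2, min(0.99, cutoff / (fs / 2)), type = "low")
  m <- as.numeric(signal::filtfilt(bf, w))
  (m - mean(m)) / sd(m)
}

# Constant-envelope carrier: keeps the phase dynamics of band-filtered noise
# but normalizes the instantaneous amplitude to 1, so a planted slow envelope
# is the signal's envelope.
phaseNoiseCarrier <- function(n, band, fs) {
  z <- analyticSignal(bandNoise(n, band, fs))
  Re(z / Mod(z))
}

#' Generate a pair of envelope-correlated signals on orthogonal carriers
#'
#' Fixture for the orthogonalized envelope-correlation estimator: two
#' band-limited carriers with independent filtered-noise phase dynamics
#' (amplitude-normalized and mutually orthogonalized) are modulated by slow
#' log-normal envelopes whose underlying Gaussian mixes correlate at `rho`.
#' Because the carriers share no linear component, leakage correction leaves
#' the planted envelope coupling intact.
#'
#' @param duration,fs Recording length (s) and sampling rate (Hz).
#' @param band A [bandSpec()] for the carriers.
#' @param rho Planted envelope correlation in `[-1, 1]`.
#' @param noise_sd Additive white-noise standard deviation.
#' @param seed Optional seed.
#' @param mod_cutoff Low-pass cutoff of the envelope modulators in Hz
#'   (default `min(0.2, f_low / 4)`, a realistic ultra-slow envelope rate).
#' @param env_sigma Log-scale depth of the envelope modulation (default 0.4).
#' @return List with `x`, `y`, `fs`, `band` and the planted envelopes
#'   `env_x`, `env_y`.
#' @export
generateEnvelopeCoupledPair <- function(duration, fs, band, rho, noise_sd = 0,
                                        seed = NULL,
                                        mod_cutoff = min(0.2, band$f_low / 4),
                                        env_sigma = 0.4) {
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]", call. = FALSE)
  n <- round(duration * fs)
  withSeed(seed, {
    c1raw <- bandNoise(n, band, fs)
    c2raw <- bandNoise(n, band, fs)
    c2raw <- c2raw - sum(c2raw * c1raw) / sum(c1raw * c1raw) * c1raw
    z1 <- analyticSignal(c1raw); z2 <- analyticSignal(c2raw)
    c1 <- Re(z1 / Mod(z1)); c2 <- Re(z2 / Mod(z2))
    ms <- slowModulator(n, fs, mod_cutoff)
    m1 <- slowModulator(n, fs, mod_cutoff)
    m2 <- slowModulator(n, fs, mod_cutoff)
    a <- sqrt(abs(rho))
    mix1 <- a * ms + sqrt(1 - abs(rho)) * m1
    mix2 <- sign(rho + (rho == 0)) * a * ms + sqrt(1 - abs(rho)) * m2
    env1 <- exp(env_sigma * mix1)
    env2 <- exp(env_sigma * mix2)
    x <- env1 * c1
    y <- env2 * c2
    if (noise_sd > 0) {
      x <- x + rnorm(n, sd = noise_sd)
      y <- y + rnorm(n, sd = noise_sd)
    }
    list(x = x, y = y, fs = fs, band = band, env_x = env1, env_y = env2)
  })
}

#' Expand a ROI time series into a correlated voxel block
#'
#' Each voxel is `shared_fraction` of the (unit-variance scaled) ROI signal
#' plus independent white noise, then scaled to unit variance; with
#' `shared_fraction = 1` and `noise_sd = 0` the voxels are exact copies of the
#' input.
#'
#' @param roi_signal Numeric vector.
#' @param n_voxels Number of voxels (`>= 1`).
#' @param shared_fraction Fraction in `[0, 1]` of the common signal.
#' @param noise_sd Independent noise standard deviation.
#' @param seed Optional seed.
#' @return `n_voxels x n_samples` numeric matrix.
#' @export
generateVoxelCluster <- function(roi_signal, n_voxels, shared_fraction = 0.7,
                                 noise_sd = 0.5, seed = NULL) {
  if (n_voxels < 1) stop("n_voxels must be >= 1", call. = FALSE)
  if (shared_fraction < 0 || shared_fraction > 1)
    stop("shared_fraction must lie in [0, 1]", call. = FALSE)
  n <- length(roi_signal)
  if (shared_fraction == 1 && noise_sd == 0)
    return(matrix(rep(roi_signal, each = n_voxels), nrow = n_voxels))
  base <- roi_signal / sd(roi_signal)
  withSeed(seed, {
    block <- matrix(0, n_voxels, n)
    for (k in seq_len(n_voxels)) {
      v <- shared_fraction * base + noise_sd * rnorm(n)
      s <- sd(v)
      block[k, ] <- if (s > 0) v / s else v
    }
    block
  })
}

#' Default planted state coupling templates
#'
#' States are designed to be distinguishable through the Laplacian
#' eigenspectrum of their connectivity snapshots. Spectra are
#' permutation-invariant, so relabeled copies of one topology are
#' indistinguishable; and a state whose strong edges admit several
#' alternative spanning trees yields unstable tree selections and noisy
#' spectra. Every state therefore couples all ROIs into the *same* star
#' (hub = ROI 1): the star is the unique strong spanning tree (any two
#' leaves have zero lag difference, which the imaginary phase-locking
#' estimator suppresses), while the planted hub-leaf lag shrinks from pi/2
#' (edge weight `|sin| = 1`) for state 1 toward pi/6 (weight 0.5) for the
#' last state, giving each state a distinct, low-variance eigenspectrum.
#'
#' @param n_rois Number of ROIs.
#' @param state_count Number of states.
#' @return List of per-state templates, each with an `n_rois x n_rois`
#'   antisymmetric `lag` matrix (radians; 0 = uncoupled; `lag[i, j] > 0`
#'   means i leads j) and an `env_rho` matrix.
#' @export
defaultStateTemplates <- function(n_rois, state_count = 2L) {
  lags <- if (state_count == 1L) pi / 2 else
    seq(pi / 2, pi / 6, length.out = state_count)
  lapply(seq_len(state_count), function(s) {
    lag <- matrix(0, n_rois, n_rois)
    for (r in seq(2, length.out = n_rois - 1)) {
      lag[1, r] <- lags[s]
      lag[r, 1] <- -lags[s]
    }
    list(lag = lag, env_rho = matrix(0, n_rois, n_rois))
  })
}

# For one state template, decompose the coupling graph into components and
# return, per ROI, the component root and the cumulative phase lag from the
# root (breadth-first propagation along tree edges).
templateLagPlan <- function(lag) {
  n <- nrow(lag)
  g <- igraph::graph_from_adjacency_matrix(lag != 0, mode = "undirected")
  comp <- igraph::components(g)$membership
  root <- integer(n); cum <- numeric(n)
  for (cm in unique(comp)) {
    members <- which(comp == cm)
    r0 <- min(members)
    root[members] <- r0
    cum[r0] <- 0
    if (length(members) > 1) {
      visited <- r0
      frontier <- r0
      while (length(frontier)) {
        nxt <- integer(0)
        for (i in frontier) {
          kids <- setdiff(which(lag[i, ] != 0), visited)
          for (j in kids) cum[j] <- cum[i] + lag[i, j]
          visited <- c(visited, kids)
          nxt <- c(nxt, kids)
        }
        frontier <- nxt
      }
    }
  }
  list(root = root, cum_lag = cum)
}

#' Default per-subject Markov transition matrices
#'
#' Per-state persistence (diagonal) probabilities are swept over `stay_range`
#' across subjects, with the sweep direction alternating between states
#' (ascending for odd states, descending for even). This plants
#' between-subject spread in *both* chronnectomic targets: transition rates
#' (through the overall persistence level) and per-state occupancy times
#' (through the asymmetry between state persistences -- with a symmetric
#' chain every subject would sit at the uniform stationary occupancy and
#' occupancy reliability would be undefined). Off-diagonal mass is uniform.
#'
#' @param n_subjects,state_count Cohort dimensions.
#' @param stay_range Range of the subject's persistence level (the mean
#'   diagonal).
#' @param asym_max Maximal relative asymmetry between state persistences
#'   (default 0.5; `0` gives symmetric chains and hence uniform planted
#'   occupancies for every subject).
#' @return List of `state_count x state_count` row-stochastic matrices.
#' @export
defaultSubjectTP <- function(n_subjects, state_count = 2L,
                             stay_range = c(0.5, 0.95), asym_max = 0.5) {
  fr <- if (n_subjects == 1L) 0.5 else
    (seq_len(n_subjects) - 1) / (n_subjects - 1)
  lapply(fr, function(f) {
    if (state_count == 1L) return(matrix(1, 1, 1))
    L <- stay_range[1] + f * (stay_range[2] - stay_range[1])
    cc <- asym_max * cos(pi * f)
    tp <- matrix(0, state_count, state_count)
    for (j in seq_len(state_count)) {
      g <- cos(pi * (j - 1) / (state_count - 1))
      d <- min(0.99, max(0.01, 1 - (1 - L) * (1 + cc * g)))
      tp[j, ] <- (1 - d) / (state_count - 1)
      tp[j, j] <- d
    }
    tp
  })
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the acquisition conditions the pipeline is designed for:
#' 40 subjects scanned twice, 5-minute recordings at 600 Hz, 90 ROIs, the
#' eight canonical bands and two planted connectivity states. Tests and
#' examples pass smaller values explicitly.
#'
#' @param n_subjects,n_sessions Cohort dimensions (sessions default 2).
#' @param duration Recording length in seconds (default 300).
#' @param fs Sampling rate in Hz (default 600).
#' @param n_rois Number of ROIs (default 90).
#' @param bands List of [bandSpec()]s (default [defaultBands()]).
#' @param state_count Number of planted states (default 2).
#' @param state_graphs Per-state coupling templates
#'   (default [defaultStateTemplates()]).
#' @param subject_tp Per-subject row-stochastic `k x k` transition matrices
#'   (default [defaultSubjectTP()]).
#' @param session_jitter Nonnegative perturbation scale applied to each
#'   subject's transition matrix before session 2; `0` makes session 2 an
#'   exact replay of session 1.
#' @param noise_sd Additive noise on coupled followers (default 0.1).
#' @param segment_samples Planted state-dwell granularity in samples; states
#'   switch only at multiples of this interval so planted labels align with
#'   analysis windows of the same width/step (default `fs`, i.e. 1 s).
#' @param seed Integer master seed.
#' @return A validated config list of class `CohortConfig`.
#' @export
cohortConfig <- function(n_subjects = 40L, n_sessions = 2L, duration = 300,
                         fs = 600, n_rois = 90L, bands = defaultBands(),
                         state_count = 2L, state_graphs = NULL,
                         subject_tp = NULL, session_jitter = 0.02,
                         noise_sd = 0.1, segment_samples = round(fs), seed = 1L) {
  if (session_jitter < 0) stop("session_jitter must be >= 0", call. = FALSE)
  if (abs(duration * fs - round(duration * fs)) > 1e-9)
    stop("duration * fs must be integral", call. = FALSE)
  if (is.null(state_graphs)) state_graphs <- defaultStateTemplates(n_rois, state_count)
  if (length(state_graphs) != state_count)
    stop("state_graphs count must equal state_count", call. = FALSE)
  if (is.null(subject_tp)) subject_tp <- defaultSubjectTP(n_subjects, state_count)
  for (tp in subject_tp) {
    if (!all(dim(tp) == c(state_count, state_count)) ||
        any(abs(rowSums(tp) - 1) > 1e-12) || any(tp < 0))
      stop("subject_tp matrices must be row-stochastic k x k", call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_sessions = as.integer(n_sessions),
                 duration = duration, fs = fs, n_rois = as.integer(n_rois),
                 bands = bands, state_count = as.integer(state_count),
                 state_graphs = state_graphs, subject_tp = subject_tp,
                 session_jitter = session_jitter, noise_sd = noise_sd,
                 segment_samples = as.integer(segment_samples),
                 seed = as.integer(seed)),
            class = "CohortConfig")
}

# Simulate a first-order Markov chain of given length.
simulateChain <- function(tp, n, seed) {
  k <- nrow(tp)
  withSeed(seed, {
    s <- integer(n)
    s[1] <- sample.int(k, 1)
    if (n > 1) for (i in 2:n) s[i] <- sample.int(k, 1, prob = tp[s[i - 1], ])
    s
  })
}

# Perturb a row-stochastic matrix by additive noise of scale `jitter`.
perturbTP <- function(tp, jitter, seed) {
  if (jitter == 0) return(tp)
  withSeed(seed, {
    k <- nrow(tp)
    tp2 <- pmax(tp + matrix(rnorm(k * k, sd = jitter), k, k), 1e-3)
    tp2 / rowSums(tp2)
  })
}

#' Generate a synthetic two-session cohort with planted dynamics
#'
#' Every ROI carries an independent band-limited noise carrier; within each
#' planted state dwell, coupled follower ROIs are overwritten with a
#' phase-lagged copy of their driver (derived from the driver's analytic
#' signal, so the lag is exact) plus additive noise, and envelope-coupled
#' pairs are co-modulated by a shared slow envelope. State dwell sequences are
#' drawn from each subject's transition matrix; session 2 uses the matrix
#' perturbed by `session_jitter`. With `session_jitter = 0` session 2 replays
#' session 1's sub-seeds exactly, making the two sessions identical recordings
#' (a noise-free test-retest).
#'
#' @param config A [cohortConfig()].
#' @return A [Cohort-class]. Its ground truth holds, per subject and session,
#'   the planted per-segment state `labels`, `planted_tr`, `planted_oc`, and
#'   the transition matrix actually used; plus the shared `templates`.
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  n <- round(config$duration * config$fs)
  n_seg <- n %/% config$segment_samples
  if (n_seg < 2) stop("recording too short for the segment grid", call. = FALSE)
  truth <- list(templates = config$state_graphs, per_recording = list())
  signals <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    tp1 <- config$subject_tp[[s]]
    signals[[s]] <- vector("list", config$n_sessions)
    for (e in seq_len(config$n_sessions)) {
      tag <- if (config$session_jitter == 0) 1L else e
      tp <- if (tag == 1L) tp1 else
        perturbTP(tp1, config$session_jitter, mixSeed(config$seed, s, tag, 11L))
      labels <- simulateChain(tp, n_seg, mixSeed(config$seed, s, tag, 22L))
      signals[[s]][[e]] <- lapply(config$bands, function(bd)
        synthRecording(labels, tp, config, bd, s, tag))
      names(signals[[s]][[e]]) <- vapply(config$bands, `[[`, "", "name")
      rec <- list(subject = s, session = e, labels = labels,
                  planted_tr = if (n_seg > 1) sum(diff(labels) != 0) / (n_seg - 1) else 0,
                  planted_oc = as.numeric(tabulate(labels, config$state_count)) / n_seg,
                  tp = tp)
      truth$per_recording[[sprintf("sub%d_ses%d", s, e)]] <- rec
    }
  }
  new("Cohort", signals = signals, config = unclass(config), truth = truth)
}

# Synthesize one samples x n_rois recording for one band.
synthRecording <- function(labels, tp, config, band, subject, tag) {
  n <- round(config$duration * config$fs)
  n_rois <- config$n_rois
  seg <- config$segment_samples
  carriers <- matrix(0, n, n_rois)
  analytic <- vector("list", n_rois)
  for (r in seq_len(n_rois)) {
    carriers[, r] <- withSeed(mixSeed(config$seed, subject, tag, band$f_low * 100, r),
                              bandNoise(n, band, config$fs))
    analytic[[r]] <- analyticSignal(carriers[, r])
  }
  out <- carriers
  plans <- lapply(config$state_graphs, function(t) templateLagPlan(t$lag))
  noise_seed <- mixSeed(config$seed, subject, tag, band$f_low * 100, 9999L)
  withSeed(noise_seed, {
    for (g in seq_along(labels)) {
      idx <- ((g - 1L) * seg + 1L):(g * seg)
      tmpl <- config$state_graphs[[labels[g]]]
      plan <- plans[[labels[g]]]
      followers <- which(plan$root != seq_len(config$n_rois))
      for (j in followers) {
        lagged <- Re(analytic[[plan$root[j]]][idx] * exp(-1i * plan$cum_lag[j]))
        out[idx, j] <- lagged +
          if (config$noise_sd > 0) rnorm(length(idx), sd = config$noise_sd) else 0
      }
      ep <- which(tmpl$env_rho != 0 & upper.tri(tmpl$env_rho), arr.ind = TRUE)
      if (nrow(ep)) {
        for (p in seq_len(nrow(ep))) {
          i <- ep[p, 1]; j <- ep[p, 2]
          m <- slowModulator(length(idx), config$fs, min(0.2, band$f_low / 4))
          rho <- tmpl$env_rho[i, j]
          env <- exp(0.4 * sqrt(abs(rho)) * m)
          out[idx, i] <- out[idx, i] * env
          out[idx, j] <- out[idx, j] * (if (rho >= 0) env else 1 / env)
        }
      }
    }
  })
  out
}
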
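#' Simulation configuration
#'
#' Parameters of the linear-nonlinear calcium forward model. Defaults
#' describe a GCaMP6f-like indicator imaged at 15.625 Hz (64 ms frame,
#' 2 ms line speed x 32 lines) under the 258-s noise stimulus.
#'
#' @param n_rois Number of ROIs to simulate.
#' @param seed Integer seed; fixes all randomness of a simulation.
#' @param event_rate_scale Mean calcium-event rate in events/s.
#' @param indicator_decay Indicator decay time constant in seconds.
#' @param noise_sd Additive Gaussian noise SD, relative to the clean
#'   trace's SD (dimensionless).
#' @param trace_rate Fluorescence sampling rate in Hz.
#' @param duration Recording duration in seconds.
#' @param spont_frac Fraction of the event rate that is spontaneous
#'   (stimulus-independent), in `[0, 1]`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_rois = 1L, seed = 1L, event_rate_scale = 8,
                       indicator_decay = 0.4, noise_sd = 0.2,
                       trace_rate = 15.625, duration = 258,
                       spont_frac = 0.1) {
  for (nm in c("n_rois", "event_rate_scale", "indicator_decay",
               "trace_rate", "duration")) {
    check_positive_scalar(get(nm), nm)
  }
  if (noise_sd < 0) abort_invalid("`noise_sd` must be >= 0.")
  if (spont_frac < 0 || spont_frac > 1) abort_invalid("`spont_frac` must be in [0, 1].")
  structure(
    list(n_rois = as.integer(n_rois), seed = as.integer(seed),
         event_rate_scale = event_rate_scale,
         indicator_decay = indicator_decay, noise_sd = noise_sd,
         trace_rate = trace_rate, duration = duration,
         spont_frac = spont_frac),
    class = "sim_config"
  )
}

# Linear-convolution helper: out[i] = sum_m k[m] * s[i + o_min + m - 1],
# with s zero-padded outside its support. FFT-based; offsets in samples.
lagged_inner_sum <- function(s, k, o_min) {
  n <- length(s)
  m <- length(k)
  big <- stats::nextn(n + m)
  S <- fft(c(s, numeric(big - n)))
  K <- fft(c(rev(k), numeric(big - m)))
  conv <- Re(fft(S * K, inverse = TRUE)) / big
  idx <- seq_len(n) + o_min + m - 1
  out <- numeric(n)
  ok <- idx >= 1 & idx <= big
  out[ok] <- conv[idx[ok]]
  out
}

#' Simulate a fluorescence trace from planted kernels
#'
#' The forward model is chosen so the reverse-correlation estimator is
#' invertible on it: (1) the centred binary stimulus (+/-1 per channel) is
#' filtered by the planted kernels on the 500 Hz alignment clock to give a
#' linear drive; (2) the drive is rectified and scaled so the mean event
#' rate equals `cfg$event_rate_scale`, with a `cfg$spont_frac` floor of
#' spontaneous rate; (3) calcium events are drawn Bernoulli per 2-ms bin;
#' (4) events are convolved with a single-exponential indicator decay;
#' (5) the result is sampled at `cfg$trace_rate` and Gaussian noise of SD
#' `cfg$noise_sd` times the clean trace SD is added. With all-zero
#' kernels the rate is constant, so events carry no stimulus-locked
#' structure.
#'
#' @param truth A [ground_truth_roi()].
#' @param stim A [noise_stimulus()]; its span must cover `cfg$duration`.
#' @param cfg A [sim_config()].
#' @param seed Optional seed overriding `cfg$seed`.
#'
#' @return A tibble of class `fluor_trace` with columns `time_s`, `f`,
#'   attribute `rate` (Hz), and attribute `true_event_times` holding the
#'   generated event times (seconds) for recovery scoring.
#' @export
simulate_trace <- function(truth, stim, cfg = sim_config(), seed = NULL) {
  stopifnot(inherits(truth, "ground_truth_roi"), inherits(stim, "noise_stimulus"))
  fr <- stim_frame_rate(stim)
  stim_dur <- nrow(stim) / fr
  if (cfg$duration > stim_dur + 1 / fr) {
    abort_invalid("stimulus is shorter than the configured duration: clocks mismatch.")
  }
  seed <- seed %||% cfg$seed
  clock <- 500
  dt <- 1 / clock
  n500 <- floor(cfg$duration * clock)
  t500 <- (seq_len(n500) - 1) * dt
  sval <- stim_at(stim, t500)           # zero-order hold lookup
  sval[is.na(sval)] <- 0.5
  sc <- 2 * sval - 1                    # centred +/-1
  tau <- lag_grid()
  o <- round(tau * clock)
  drive <- numeric(n500)
  for (ch in 1:4) {
    k <- truth$true_kernels[, ch]
    if (all(k == 0)) next
    drive <- drive + lagged_inner_sum(sc[, ch], k, o[1])
  }
  d_pos <- pmax(drive, 0)
  if (mean(d_pos) > 0) {
    m <- (1 - cfg$spont_frac) * d_pos / mean(d_pos) + cfg$spont_frac
  } else {
    m <- rep(1, n500)
  }
  rate <- cfg$event_rate_scale * m
  withr::with_seed(seed, {
    events <- rbinom(n500, 1L, pmin(rate * dt, 1))
    decay <- exp(-dt / cfg$indicator_decay)
    c500 <- as.numeric(stats::filter(events, decay, method = "recursive"))
    n_tr <- floor(cfg$duration * cfg$trace_rate)
    ts <- (seq_len(n_tr) - 1) / cfg$trace_rate
    idx <- pmin(floor(ts * clock) + 1, n500)
    clean <- c500[idx]
    ref <- sd(clean)
    if (!is.finite(ref) || ref == 0) ref <- 1
    f <- clean + rnorm(n_tr, 0, cfg$noise_sd * ref)
  })
  out <- tibble::tibble(time_s = ts, f = f)
  attr(out, "rate") <- cfg$trace_rate
  attr(out, "true_event_times") <- t500[events == 1L]
  class(out) <- c("fluor_trace", class(out))
  out
}

#' Build a fluorescence trace from raw samples
#'
#' @param f Numeric vector of fluorescence samples.
#' @param rate Sampling rate in Hz.
#' @return A `fluor_trace` tibble.
#' @export
fluor_trace <- function(f, rate) {
  check_positive_scalar(rate, "rate")
  out <- tibble::tibble(time_s = (seq_along(f) - 1) / rate, f = as.numeric(f))
  attr(out, "rate") <- rate
  class(out) <- c("fluor_trace", class(out))
  out
}

trace_rate <- function(trace) attr(trace, "rate")

#' Default planted cluster specification
#'
#' Three functionally distinct archetypes: an achromatic fast Off type, a
#' red/green-On versus blue-Off opponent type, and a UV-dominated slow On
#' type — caricatures of common larval zebrafish RGC response classes.
#'
#' @param k Number of clusters (1 to 3 of the archetypes, recycled beyond 3).
#' @param props Mixing proportions (must sum to 1); default uniform.
#' @return A list of per-cluster specs (fields `kernels`, `prop`,
#'   `eye_range`, `ipl_range`, `compartment`).
#' @export
default_cluster_spec <- function(k = 3, props = NULL) {
  archetypes <- list(
    kernel_template("Off", "biphasic", 0.06, c(1, 1, 0.8, 0)),
    kernel_template(c("On", "On", "Off", "On"), "biphasic", c(0.08, 0.08, 0.14, 0.08),
                    c(1, 0.9, 0.7, 0.2)),
    kernel_template("On", "monophasic", 0.12, c(0.2, 0.3, 0, 1))
  )
  props <- props %||% rep(1 / k, k)
  if (abs(sum(props) - 1) > 1e-8) abort_invalid("`props` must sum to 1.")
  lapply(seq_len(k), function(i) {
    list(kernels = archetypes[[(i - 1) %% 3 + 1]], prop = props[i],
         eye_range = c(-pi, pi), ipl_range = c(0.05, 0.95),
         compartment = "dendrite")
  })
}

#' Simulate a planted-cluster ROI population
#'
#' Draws cluster labels from the spec's mixing proportions, samples eye
#' position and IPL depth uniformly within each cluster's ranges, and
#' simulates one fluorescence trace per ROI. Ground-truth labels are kept
#' for adjusted-Rand scoring of downstream clustering.
#'
#' @param cfg A [sim_config()]; `cfg$n_rois` ROIs are generated and all
#'   randomness flows from `cfg$seed`.
#' @param cluster_spec A list as returned by [default_cluster_spec()].
#' @param stim Optional shared [noise_stimulus()]; defaults to one built
#'   from `cfg` with the canonical 6.4 Hz rate.
#'
#' @return A tibble with one row per ROI: `roi_id`, `true_cluster`,
#'   `compartment`, `eye_pos`, `ipl_depth`, and list-columns
#'   `true_kernels` (649 x 4 matrices) and `trace` (`fluor_trace`s).
#' @export
make_population <- function(cfg = sim_config(n_rois = 50), cluster_spec = default_cluster_spec(),
                            stim = NULL) {
  props <- vapply(cluster_spec, `[[`, numeric(1), "prop")
  if (abs(sum(props) - 1) > 1e-8) {
    abort_invalid("cluster proportions must sum to 1.")
  }
  stim <- stim %||% noise_stimulus(duration_s = cfg$duration, seed = cfg$seed)
  n <- cfg$n_rois
  meta <- withr::with_seed(cfg$seed, {
    labels <- sample.int(length(cluster_spec), n, replace = TRUE, prob = props)
    list(labels = labels,
         eye = runif(n), depth = runif(n),
         roi_seeds = sample.int(.Machine$integer.max - 1L, n))
  })
  rows <- purrr::map(seq_len(n), function(i) {
    spec_i <- cluster_spec[[meta$labels[i]]]
    eye <- spec_i$eye_range[1] + meta$eye[i] * diff(spec_i$eye_range)
    depth <- spec_i$ipl_range[1] + meta$depth[i] * diff(spec_i$ipl_range)
    truth <- ground_truth_roi(spec_i$kernels, eye_position = eye,
                              ipl_depth = depth,
                              compartment = spec_i$compartment,
                              cluster_label = meta$labels[i])
    trace <- simulate_trace(truth, stim, cfg, seed = meta$roi_seeds[i])
    tibble::tibble(
      roi_id = i, true_cluster = meta$labels[i],
      compartment = spec_i$compartment, eye_pos = eye,
      ipl_depth = if (spec_i$compartment == "soma") NA_real_ else depth,
      true_kernels = list(spec_i$kernels), trace = list(trace)
    )
  })
  dplyr::bind_rows(rows)
}
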
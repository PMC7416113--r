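#' Ground-truth spectral kernel templates
#'
#' Builds a planted 4-channel kernel set on the canonical lag grid
#' (see [lag_grid()]). Each channel is a difference of two Gaussian lobes
#' in lag: a main lobe close to the event and an earlier, opposite-signed
#' lobe. For `shape = "monophasic"` the early lobe is small (25% of the
#' main lobe); for `"biphasic"` it is nearly as large (85%). With the main
#' (positive) lobe later than the (negative) early lobe, the minimum
#' precedes the maximum, i.e. the constructed polarity agrees with the
#' timing rule used by [classify_polarity()]. `"Off"` channels are the
#' negation. Smaller `time_const` compresses both lobes toward the event,
#' raising the kernel's spectral centroid.
#'
#' @param polarity `"On"` or `"Off"`; length 1 or one per channel.
#' @param shape `"monophasic"` or `"biphasic"`; length 1 or 4.
#' @param time_const Main-lobe time constant in seconds (length 1 or 4).
#' @param channel_gains Non-negative gain per channel; a gain of 0 yields
#'   a flat zero waveform (an unconnected channel).
#'
#' @return 649 x 4 numeric matrix, columns `R`, `G`, `B`, `UV`, each
#'   channel max-abs-normalized to its gain.
#' @export
#' @examples
#' k <- kernel_template("On", "biphasic", time_const = 0.08)
#' which.min(k[, "R"]) < which.max(k[, "R"]) # min precedes max: On
kernel_template <- function(polarity = "On", shape = "biphasic",
                            time_const = 0.08,
                            channel_gains = c(1, 1, 1, 1)) {
  polarity <- rep_len(polarity, 4L)
  shape <- rep_len(shape, 4L)
  time_const <- rep_len(time_const, 4L)
  if (!all(polarity %in% c("On", "Off"))) {
    abort_invalid("`polarity` entries must be \"On\" or \"Off\".")
  }
  if (!all(shape %in% c("monophasic", "biphasic"))) {
    abort_invalid("`shape` entries must be \"monophasic\" or \"biphasic\".")
  }
  if (length(channel_gains) != 4L || any(channel_gains < 0)) {
    abort_invalid("`channel_gains` must be 4 non-negative values.")
  }
  tau <- lag_grid()
  out <- matrix(0, nrow = length(tau), ncol = 4L,
                dimnames = list(NULL, channel_order()))
  for (ch in 1:4) {
    if (channel_gains[ch] == 0) next
    tc <- time_const[ch]
    t_main <- -tc                 # main lobe centre
    t_early <- -tc - 1.8 * tc     # opposite early lobe
    s_main <- 0.6 * tc
    s_early <- 0.9 * tc
    a_early <- if (shape[ch] == "monophasic") 0.25 else 0.85
    w <- exp(-(tau - t_main)^2 / (2 * s_main^2)) -
      a_early * exp(-(tau - t_early)^2 / (2 * s_early^2))
    w <- w / max(abs(w)) * channel_gains[ch]
    if (polarity[ch] == "Off") w <- -w
    out[, ch] <- w
  }
  out
}

#' Ground-truth ROI descriptor
#'
#' Bundles the planted kernels with the metadata every ROI carries:
#' eye position (radians, `[-pi, pi)`), compartment, IPL depth (fraction
#' in `[0, 1]` from the GCL border to the INL border; `NA` for somata),
#' and a planted cluster label for recovery scoring.
#'
#' @param true_kernels 649 x 4 kernel matrix (see [kernel_template()]).
#' @param eye_position Radians in `[-pi, pi)`.
#' @param ipl_depth Fraction in `[0, 1]`, or `NA` for somatic ROIs.
#' @param compartment `"dendrite"` or `"soma"`.
#' @param cluster_label Integer ground-truth cluster id.
#' @return A list of class `ground_truth_roi`.
#' @export
ground_truth_roi <- function(true_kernels, eye_position = 0,
                             ipl_depth = 0.5, compartment = "dendrite",
                             cluster_label = 1L) {
  if (!is.matrix(true_kernels) || nrow(true_kernels) != 649L ||
      ncol(true_kernels) != 4L) {
    abort_invalid("`true_kernels` must be a 649 x 4 matrix on the canonical lag grid.")
  }
  compartment <- match.arg(compartment, c("dendrite", "soma"))
  if (compartment == "dendrite" &&
      (!is.finite(ipl_depth) || ipl_depth < 0 || ipl_depth > 1)) {
    abort_invalid("dendritic ROIs need `ipl_depth` in [0, 1].")
  }
  structure(
    list(true_kernels = true_kernels, eye_position = eye_position,
         ipl_depth = if (compartment == "soma") NA_real_ else ipl_depth,
         compartment = compartment, cluster_label = as.integer(cluster_label)),
    class = "ground_truth_roi"
  )
}
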
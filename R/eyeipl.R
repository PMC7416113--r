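#' Allocate an ROI to its Eye-IPL bin
#'
#' Eye position in `[-pi, pi)` is divided into eight equal bins of width
#' pi/4 (circular axis). IPL depth is divided into 20 bins: somatic ROIs
#' all go to depth bin 1 regardless of GCL depth, bin 2 is always empty
#' (a visual barrier between GCL and IPL), and dendritic ROIs map
#' linearly onto bins 3-20 by their relative depth between the IPL
#' borders (`d = 0` the GCL side, `d = 1` the INL side).
#'
#' @param eye_position Radians; wrapped into `[-pi, pi)`.
#' @param ipl_depth Fraction in `[0, 1]` (dendrites) or `NA` (somata).
#' @param compartment `"dendrite"` or `"soma"` (vectorized).
#' @return A tibble with columns `eye_bin` (1-8) and `depth_bin` (1-20).
#' @export
bin_roi <- function(eye_position, ipl_depth, compartment = "dendrite") {
  n <- length(eye_position)
  compartment <- rep_len(compartment, n)
  ipl_depth <- rep_len(ipl_depth, n)
  if (any(!is.finite(eye_position))) abort_invalid("`eye_position` must be finite.")
  is_soma <- compartment == "soma"
  if (any(!is_soma & (!is.finite(ipl_depth) | ipl_depth < 0 | ipl_depth > 1))) {
    abort_invalid("dendritic ROIs need `ipl_depth` in [0, 1].")
  }
  theta <- (eye_position + pi) %% (2 * pi)    # 0 .. 2*pi
  eye_bin <- (floor(theta / (pi / 4)) %% 8) + 1L
  depth_bin <- ifelse(is_soma, 1L,
                      pmin(3L + floor(ipl_depth * 18), 20L))
  tibble::tibble(eye_bin = as.integer(eye_bin),
                 depth_bin = as.integer(depth_bin))
}

new_eye_ipl_map <- function(values, counts, stat = "value") {
  stopifnot(identical(dim(values), c(8L, 20L)))
  structure(list(values = values, counts = counts, stat = stat),
            class = "eye_ipl_map")
}

#' Build an Eye-IPL map (constructor)
#'
#' Low-level constructor for an 8 x 20 map; mostly used by
#' [aggregate_map()] and in tests.
#'
#' @param values 8 (eye) x 20 (depth) numeric matrix (`NA` = empty bin).
#' @param counts Optional matching matrix of ROI counts per bin.
#' @param stat Name of the binned statistic.
#' @return An `eye_ipl_map`.
#' @export
eye_ipl_map <- function(values, counts = NULL, stat = "value") {
  counts <- counts %||% matrix(1L, 8L, 20L)
  new_eye_ipl_map(values, counts, stat)
}

#' Aggregate a per-ROI statistic into the Eye-IPL grid
#'
#' Bins each ROI with [bin_roi()] and takes the arithmetic mean of
#' `value_extractor(roi)` within each bin; empty bins are `NA`.
#' Permutation-invariant over ROIs.
#'
#' @param rois A tibble with columns `eye_pos`, `ipl_depth`,
#'   `compartment`, plus whatever `value_extractor` reads.
#' @param value_extractor Either a column name (string) or a function of
#'   one ROI row returning a scalar.
#' @param stat Name recorded on the map.
#' @return An `eye_ipl_map`.
#' @export
aggregate_map <- function(rois, value_extractor, stat = NULL) {
  if (is.character(value_extractor)) {
    stat <- stat %||% value_extractor
    vals <- rois[[value_extractor]]
  } else {
    stat <- stat %||% "value"
    vals <- purrr::map_dbl(seq_len(nrow(rois)),
                           function(i) value_extractor(rois[i, ]))
  }
  bins <- bin_roi(rois$eye_pos, rois$ipl_depth, rois$compartment)
  sums <- matrix(0, 8L, 20L)
  counts <- matrix(0L, 8L, 20L)
  for (i in seq_along(vals)) {
    if (!is.finite(vals[i])) next
    e <- bins$eye_bin[i]; d <- bins$depth_bin[i]
    sums[e, d] <- sums[e, d] + vals[i]
    counts[e, d] <- counts[e, d] + 1L
  }
  values <- ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_)
  new_eye_ipl_map(values, counts, stat)
}

# (1,2,1)/4 smoothing along a vector; circular or reflecting boundary;
# NA entries are excluded with weight renormalization and stay NA.
binomial_smooth_1d <- function(v, circular) {
  n <- length(v)
  if (n < 2L) return(v)
  taps <- c(1, 2, 1) / 4
  out <- v
  for (i in seq_len(n)) {
    if (is.na(v[i])) next
    idx <- i + (-1:1)
    if (circular) {
      idx <- ((idx - 1L) %% n) + 1L
    } else {
      # half-sample reflection: the out-of-range neighbour folds back onto
      # the edge bin itself, which keeps the filter mass-conserving
      idx[idx < 1L] <- 1L
      idx[idx > n] <- n
    }
    w <- taps
    ok <- !is.na(v[idx])
    if (!any(ok)) next
    out[i] <- sum(w[ok] * v[idx[ok]]) / sum(w[ok])
  }
  out
}

#' Smooth an Eye-IPL map
#'
#' Applies a circular (1,2,1)/4 binomial filter along the eye axis
#' (support +/- one pi/4 bin, i.e. the pi/3-scale smoothing) and the same
#' binomial filter over +/- one depth bin (5% of IPL depth) restricted to
#' the dendritic bins 3-20 with a reflecting boundary. The somatic bin 1
#' and the barrier bin 2 are never mixed with dendritic bins. Missing
#' bins are excluded with weight renormalization. On a fully populated
#' grid the filter conserves total mass.
#'
#' @param map An `eye_ipl_map`.
#' @return The smoothed `eye_ipl_map`.
#' @export
smooth_map <- function(map) {
  v <- map$values
  # eye axis (rows), circular, all depth bins
  for (d in 1:20) v[, d] <- binomial_smooth_1d(v[, d], circular = TRUE)
  # depth axis, dendritic bins 3:20 only, reflecting at 3 and 20
  for (e in 1:8) v[e, 3:20] <- binomial_smooth_1d(v[e, 3:20], circular = FALSE)
  new_eye_ipl_map(v, map$counts, map$stat)
}

#' On-Off index map
#'
#' Counts On and Off kernels per Eye-IPL bin and computes the On-Off
#' index `(nOn - nOff)/(nOn + nOff)` in each; bins without responsive
#' ROIs are `NA`.
#'
#' @param rois A tibble with `eye_pos`, `ipl_depth`, `compartment` and a
#'   `polarity` column over `"On"`/`"Off"` (`NA` = non-responsive).
#' @return An `eye_ipl_map` with `stat = "ooi"`.
#' @export
ooi_map <- function(rois) {
  bins <- bin_roi(rois$eye_pos, rois$ipl_depth, rois$compartment)
  n_on <- matrix(0L, 8L, 20L)
  n_off <- matrix(0L, 8L, 20L)
  for (i in seq_len(nrow(rois))) {
    p <- rois$polarity[i]
    if (is.na(p)) next
    e <- bins$eye_bin[i]; d <- bins$depth_bin[i]
    if (p == "On") n_on[e, d] <- n_on[e, d] + 1L
    if (p == "Off") n_off[e, d] <- n_off[e, d] + 1L
  }
  total <- n_on + n_off
  values <- ifelse(total > 0, (n_on - n_off) / pmax(total, 1L), NA_real_)
  new_eye_ipl_map(values, total, stat = "ooi")
}

#' Tidy an Eye-IPL map
#'
#' @param x An `eye_ipl_map`.
#' @param ... Unused.
#' @return A tibble with columns `eye_bin`, `depth_bin`, `value`,
#'   `n_rois`.
#' @export
tidy.eye_ipl_map <- function(x, ...) {
  tibble::tibble(
    eye_bin = rep(1:8, times = 20L),
    depth_bin = rep(1:20, each = 8L),
    value = as.vector(x$values),
    n_rois = as.vector(x$counts)
  )
}

#' Plot an Eye-IPL map
#'
#' @param object An `eye_ipl_map`.
#' @param ... Unused.
#' @return A ggplot raster of the 8 x 20 grid (eye position horizontal,
#'   IPL depth vertical with the GCL at the bottom).
#' @export
autoplot.eye_ipl_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$eye_bin, y = .data$depth_bin,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "black", mid = "grey85",
                                  high = "orange", na.value = "white",
                                  name = object$stat) +
    ggplot2::labs(x = "eye-position bin", y = "IPL depth bin") +
    ggplot2::theme_minimal()
}
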
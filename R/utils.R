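#' Canonical kernel lag grid
#'
#' The lag axis on which all spectral kernels live: 649 samples spaced
#' dt = 2 ms, starting at -973.5 ms and ending at +322.5 ms relative to the
#' calcium event. This matches the layout of the deposited population data
#' and spans roughly -1000 to +350 ms.
#'
#' @return Numeric vector of 649 lags in seconds.
#' @export
lag_grid <- function() {
  seq(-0.9735, by = 0.002, length.out = 649L)
}

#' Spectral channel names in canonical order
#'
#' Channels are always ordered by decreasing wavelength: red, green, blue,
#' ultraviolet — the order in which zero crossings are counted for
#' opponency classification.
#'
#' @return Character vector `c("R", "G", "B", "UV")`.
#' @export
channel_order <- function() c("R", "G", "B", "UV")

# Relative photon weights of the four LEDs under the "natural white"
# calibration: red 100%, green 50%, blue 13%, UV 6%.
natural_white_weights <- function() c(R = 1, G = 0.5, B = 0.13, UV = 0.06)

# internal: stop unless x is a single finite positive number
check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number.", name),
          class = "chromarg_invalid_argument")
  }
  invisible(x)
}

abort_invalid <- function(msg) {
  abort(msg, class = "chromarg_invalid_argument")
}
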
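#' Classify kernel polarity by extremum timing
#'
#' A kernel's dominant trajectory in time determines its polarity: if the
#' global minimum precedes the global maximum on the lag axis the kernel
#' is On; if the maximum precedes the minimum it is Off.
#'
#' @param kernel Numeric waveform on the lag grid.
#' @return `"On"` or `"Off"`.
#' @export
classify_polarity <- function(kernel) {
  i_max <- which.max(kernel)
  i_min <- which.min(kernel)
  if (i_max == i_min) {
    abort("kernel is constant: polarity undefined", class = "chromarg_degenerate")
  }
  if (i_min < i_max) "On" else "Off"
}

ternary_levels <- function() c("NR", "On", "Off")

#' Ternary wiring state of a 4-channel kernel set
#'
#' Each channel is labelled `NR` (non-responding) when its peak-to-peak
#' quality falls below `threshold` baseline SDs, otherwise On or Off by
#' the sign of the largest transition in the kernel — the signed
#' difference from the temporally earlier to the later global extremum
#' (upward: On, downward: Off), which coincides with the extremum-timing
#' rule of [classify_polarity()].
#'
#' @param kernel_set A `kernel_set` (see [normalize_kernels()]).
#' @param threshold Responsiveness gate in baseline SDs (default 10).
#' @return A list of class `ternary_state`: `state` (named character
#'   4-vector over On/Off/NR) and `index` (0-80, base-3 with digit order
#'   R, G, B, UV and NR = 0, On = 1, Off = 2).
#' @export
ternary_state <- function(kernel_set, threshold = 10) {
  state <- vapply(1:4, function(ch) {
    if (kernel_set$quality[ch] < threshold) return("NR")
    k <- kernel_set$kernels[, ch]
    i_max <- which.max(k)
    i_min <- which.min(k)
    if (i_max == i_min) return("NR")
    if (i_min < i_max) "On" else "Off"   # upward largest transition: On
  }, character(1))
  names(state) <- channel_order()
  new_ternary_state(state)
}

new_ternary_state <- function(state) {
  digits <- match(state, ternary_levels()) - 1L
  index <- sum(digits * 3L^(3:0))
  structure(list(state = state, index = as.integer(index)),
            class = "ternary_state")
}

#' Decode a ternary state index
#'
#' Inverse of the base-3 encoding used by [ternary_state()].
#'
#' @param index Integer in 0-80.
#' @return A `ternary_state`.
#' @export
ternary_from_index <- function(index) {
  if (index < 0 || index > 80) abort_invalid("`index` must be in 0..80.")
  digits <- (index %/% 3L^(3:0)) %% 3L
  state <- setNames(ternary_levels()[digits + 1L], channel_order())
  new_ternary_state(state)
}

#' Chromatic opponency class of a ternary state
#'
#' Non-responding channels are dropped; sign changes of the remaining
#' On/Off sequence are counted along decreasing wavelength (R, G, B, UV).
#' No responsive channel gives `none_connected`; zero sign changes gives
#' `non_opponent_on`/`non_opponent_off`; exactly one gives
#' `simple_opponent` with the flanking channel pair recorded; more than
#' one gives `complex_opponent`.
#'
#' @param state A `ternary_state` (or its `state` 4-vector).
#' @return A list of class `opponency_label`: `category`,
#'   `crossing_pair` (e.g. `"G/B"`, simple only, else `NA`),
#'   `n_sign_changes`.
#' @export
opponency_class <- function(state) {
  if (inherits(state, "ternary_state")) state <- state$state
  resp <- which(state != "NR")
  if (length(resp) == 0L) {
    return(new_opponency("none_connected", NA_character_, 0L))
  }
  signs <- ifelse(state[resp] == "On", 1L, -1L)
  flips <- which(diff(signs) != 0L)
  n_changes <- length(flips)
  if (n_changes == 0L) {
    cat_ <- if (signs[1] > 0) "non_opponent_on" else "non_opponent_off"
    return(new_opponency(cat_, NA_character_, 0L))
  }
  if (n_changes == 1L) {
    pair <- paste(channel_order()[resp[flips]],
                  channel_order()[resp[flips + 1L]], sep = "/")
    return(new_opponency("simple_opponent", pair, 1L))
  }
  new_opponency("complex_opponent", NA_character_, n_changes)
}

new_opponency <- function(category, pair, n) {
  structure(list(category = category, crossing_pair = pair,
                 n_sign_changes = as.integer(n)),
            class = "opponency_label")
}

#' Enumerate the 3^4 = 81 cone-wiring combinatorial space
#'
#' Each of the four cone channels can be wired On, Off, or not at all,
#' giving 81 states: 50 colour-opponent (at least one On and one Off),
#' 30 non-opponent (15 all-On, 15 all-Off subsets), and 1 fully
#' disconnected.
#'
#' @return A tibble with one row per state: `index`, channel columns
#'   `R`, `G`, `B`, `UV`, `category`, `crossing_pair`, `n_sign_changes`,
#'   and an attribute `counts` (named totals per category plus
#'   `opponent`, `non_opponent`, `total`).
#' @export
enumerate_wiring_space <- function() {
  rows <- purrr::map(0:80, function(i) {
    ts <- ternary_from_index(i)
    op <- opponency_class(ts)
    tibble::tibble(index = i, R = ts$state[["R"]], G = ts$state[["G"]],
                   B = ts$state[["B"]], UV = ts$state[["UV"]],
                   category = op$category, crossing_pair = op$crossing_pair,
                   n_sign_changes = op$n_sign_changes)
  })
  out <- dplyr::bind_rows(rows)
  tab <- table(out$category)
  counts <- c(
    total = nrow(out),
    opponent = sum(out$category %in% c("simple_opponent", "complex_opponent")),
    non_opponent = sum(out$category %in% c("non_opponent_on", "non_opponent_off")),
    as.list(tab)
  )
  attr(out, "counts") <- counts
  out
}

#' On-Off index
#'
#' `OOi = (nOn - nOff) / (nOn + nOff)`: +1 for a bin composed exclusively
#' of On kernels, -1 for all-Off, 0 for equal numbers. Undefined (NaN)
#' when both counts are zero.
#'
#' @param n_on,n_off Non-negative counts of On and Off kernels.
#' @return A list of class `oo_index`: `value`, `n_on`, `n_off`,
#'   `defined`.
#' @export
ooi <- function(n_on, n_off) {
  if (n_on < 0 || n_off < 0) abort_invalid("counts must be non-negative.")
  total <- n_on + n_off
  value <- if (total == 0) NaN else (n_on - n_off) / total
  structure(list(value = value, n_on = n_on, n_off = n_off,
                 defined = total > 0),
            class = "oo_index")
}

#' Spectral centroid of a kernel
#'
#' The amplitude-weighted mean frequency of the mean-subtracted kernel's
#' discrete Fourier magnitude spectrum, over strictly positive
#' frequencies: `sum(f * |A(f)|) / sum(|A(f)|)`. Invariant to positive
#' scaling of the kernel.
#'
#' @param kernel Numeric waveform on a uniform grid.
#' @param dt Sample spacing in seconds (default 2 ms, the lag grid).
#' @return Centroid frequency in Hz, or `NaN` (with a warning) for a
#'   zero spectrum.
#' @export
spectral_centroid <- function(kernel, dt = 0.002) {
  x <- kernel - mean(kernel)
  n <- length(x)
  amp <- Mod(fft(x))
  n_pos <- floor(n / 2)
  f <- (1:n_pos) / (n * dt)
  a <- amp[2:(n_pos + 1)]
  if (sum(a) == 0) {
    warn("zero spectrum: spectral centroid undefined")
    return(NaN)
  }
  sum(f * a) / sum(a)
}

#' Classify every ROI of a population
#'
#' Applies the ternary wiring classification, opponency labelling, and
#' per-channel polarity/centroid extraction to a kernel table.
#'
#' @param kernel_tbl Output of [estimate_population_kernels()] (any
#'   tibble with a `kernel_set` list-column).
#' @param threshold Ternary responsiveness gate in baseline SDs
#'   (default 10).
#' @return The input tibble plus columns `ternary_index`, `category`,
#'   `crossing_pair`, `n_sign_changes`, `dominant_polarity` (polarity of
#'   the highest-quality responsive channel, `NA` if none), and
#'   list-column `ternary` of `ternary_state`s.
#' @export
classify_rois <- function(kernel_tbl, threshold = 10) {
  ts <- purrr::map(kernel_tbl$kernel_set, ternary_state, threshold = threshold)
  op <- purrr::map(ts, opponency_class)
  kernel_tbl$ternary <- ts
  kernel_tbl$ternary_index <- purrr::map_int(ts, "index")
  kernel_tbl$category <- purrr::map_chr(op, "category")
  kernel_tbl$crossing_pair <- purrr::map_chr(op, "crossing_pair")
  kernel_tbl$n_sign_changes <- purrr::map_int(op, "n_sign_changes")
  kernel_tbl$dominant_polarity <- purrr::map2_chr(
    kernel_tbl$kernel_set, ts,
    function(ks, t) {
      resp <- which(t$state != "NR")
      if (length(resp) == 0L) return(NA_character_)
      t$state[[resp[which.max(ks$quality[resp])]]]
    }
  )
  kernel_tbl
}

#' Tidy a kernel set into long format
#'
#' @param x A `kernel_set`.
#' @param ... Unused.
#' @return A tibble with columns `channel`, `lag_s`, `value`, `quality`,
#'   `polarity`.
#' @export
tidy.kernel_set <- function(x, ...) {
  purrr::map_dfr(channel_order(), function(ch) {
    tibble::tibble(channel = ch, lag_s = x$lag_s, value = x$kernels[, ch],
                   quality = x$quality[[ch]], polarity = x$polarity[[ch]])
  }) |>
    dplyr::mutate(channel = factor(.data$channel, channel_order()))
}

#' One-row summary of a kernel set
#'
#' @param x A `kernel_set`.
#' @param ... Unused.
#' @return A one-row tibble: `n_events`, per-channel qualities and the
#'   max quality across channels.
#' @export
glance.kernel_set <- function(x, ...) {
  tibble::tibble(
    n_events = x$n_events,
    quality_R = x$quality[["R"]], quality_G = x$quality[["G"]],
    quality_B = x$quality[["B"]], quality_UV = x$quality[["UV"]],
    quality_max = max(x$quality), quality_sd_max = max(x$quality_sd)
  )
}
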
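#' Round half away from zero
#'
#' Base [round()] uses banker's rounding; league-table percentages are
#' conventionally rounded half up (98.5 -> 99).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

new_empty_tibble <- function(...) {
  tibble::tibble(...)
}

abort_rtindex <- function(msg, class) {
  rlang::abort(msg, class = paste0("rtindex_", class))
}
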
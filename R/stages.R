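#' AASM sleep stage vocabulary
#'
#' The five-class American Academy of Sleep Medicine scoring vocabulary, in
#' the fixed order used throughout the package for labels, confusion matrices
#' and logit vectors.
#'
#' @format Character vector `c("W", "N1", "N2", "N3", "REM")`.
#' @export
SLEEP_STAGES <- c("W", "N1", "N2", "N3", "REM")

#' Coerce labels to the canonical stage factor
#'
#' @param x character vector (or factor) of stage labels.
#' @return factor with levels [SLEEP_STAGES]. Unknown labels are an error.
#' @export
stage_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), SLEEP_STAGES)
  if (length(bad) > 0) {
    stop("unknown sleep stage label(s): ", paste(bad, collapse = ", "))
  }
  factor(x, levels = SLEEP_STAGES)
}

# internal: derive a reproducible 32-bit substream seed from a base seed
substream_seed <- function(seed, offset) {
  s <- (as.double(seed) %% 2147483647) + 1
  o <- (as.double(offset) %% 2147483647) + 1
  as.integer((s * 48271 + o * 16807) %% 2147483647)
}
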
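#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

# substream seeds derived from one master seed, kept below 2^31
substream_seed <- function(seed, stage) {
  offsets <- c(timecourse = 101L, cells = 211L, fit = 307L, recover = 401L)
  stopifnot(stage %in% names(offsets))
  as.integer((as.numeric(seed) * 48271 + offsets[[stage]]) %% 2147483647)
}
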
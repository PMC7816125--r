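#' IRT2 transcription rate
#'
#' In the wildtype regime IRT2 transcription closely follows Ime1 protein:
#' I2 = Ip - k2 once Ip reaches the threshold k2, and 0 below it. The
#' counterfactual modes clamp I2 at the activating level A
#' (`"activating_only"`) or at 0 (`"null"`).
#'
#' @param Ip Ime1 protein concentration(s), >= 0. Vectorized.
#' @param params [circuit_params()] object.
#' @param mode IRT2 regime, see [irt2_mode()].
#' @return I2, the IRT2 transcription rate (same length as `Ip`).
#' @examples
#' irt2_rate(0.15, circuit_params())   # 0.10
#' irt2_rate(0.03, circuit_params())   # 0 (below k2)
#' @export
irt2_rate <- function(Ip, params = circuit_params(), mode = "wildtype") {
  mode <- irt2_mode(mode)
  if (any(Ip < 0)) stop("Ip must be >= 0", call. = FALSE)
  switch(mode,
    wildtype        = pmax(Ip - params$k2, 0),
    activating_only = rep_len(params$A, length(Ip)),
    null            = rep_len(0, length(Ip))
  )
}

#' Update the hysteretic latch chi
#'
#' chi is the discrete indicator that licenses IRT1 transcription: it is set
#' to 1 when the IRT2 rate I2 reaches the activation threshold A, and stays
#' at 1 as long as IRT1 transcription itself remains positive, even if I2
#' later falls below A. Because I1 > 0 requires chi = 1 and r > 0, the latch
#' persists indefinitely for any constant r > 0 once triggered, and releases
#' only when both I2 < A and I1 = 0.
#'
#' @param chi_prev Previous latch state, 0 or 1.
#' @param I2 Current IRT2 rate, >= 0.
#' @param I1_prev IRT1 rate at the previous step, >= 0.
#' @param params [circuit_params()] object (supplies the threshold A).
#' @return 0 or 1.
#' @export
update_chi <- function(chi_prev, I2, I1_prev, params = circuit_params()) {
  stopifnot(chi_prev %in% c(0, 1), I2 >= 0, I1_prev >= 0)
  as.numeric(I2 >= params$A | I1_prev > 0)
}

#' IRT1 transcription rate
#'
#' Once licensed by the latch (chi = 1), IRT1 transcription is driven by the
#' Rme1 concentration r and repressed dose-dependently by IRT2:
#' I1 = chi * r / (r + k1 * I2). When both r = 0 and I2 = 0 the rate is 0
#' (the 0/0 case is defined as the off state). The result lies in \[0, 1\].
#'
#' @param chi Latch state, 0 or 1. Vectorized with `I2`.
#' @param I2 IRT2 transcription rate, >= 0.
#' @param params [circuit_params()] object (supplies r and k1).
#' @return I1, the IRT1 transcription rate.
#' @export
irt1_rate <- function(chi, I2, params = circuit_params()) {
  stopifnot(all(chi %in% c(0, 1)), all(I2 >= 0), params$r >= 0)
  r <- params$r
  denom <- r + params$k1 * I2
  out <- ifelse(denom > 0, chi * r / denom, 0)
  as.numeric(out)
}

#' IME1 transcription rate
#'
#' The IME1 promoter is driven by the starvation signal s and repressed by
#' IRT1 transcription: It = s / (s + k3 * I1) for s > 0, and 0 when s = 0
#' (no synthesis without the starvation input).
#'
#' @param s Starvation signal level(s), >= 0.
#' @param I1 IRT1 transcription rate(s), >= 0.
#' @param params [circuit_params()] object (supplies k3).
#' @return It, the IME1 transcription rate.
#' @export
ime1_transcription_rate <- function(s, I1, params = circuit_params()) {
  stopifnot(all(s >= 0), all(I1 >= 0))
  ifelse(s > 0, s / (s + params$k3 * I1), 0)
}

#' Instantaneous rates and derivatives of the circuit
#'
#' Evaluates all algebraic rates and the two time derivatives at a given
#' state, holding the latch chi fixed at its supplied value (chi is a
#' discrete mode of the hybrid system; it is updated by the event logic of
#' the simulator, not inside this pure function). I1 is computed
#' consistently with the supplied chi.
#'
#' The continuous dynamics are
#' dIm/dt = It - k4 * Im (with It = 0 when s = 0) and
#' dIp/dt = k5 * Im - k6 * Ip.
#'
#' @param state Named list or vector with `t`, `Im`, `Ip`, `chi`.
#' @param params [circuit_params()] object.
#' @param mode IRT2 regime, see [irt2_mode()].
#' @return A one-row tibble with `s`, `I1`, `I2`, `It`, `dIm`, `dIp`.
#' @examples
#' circuit_derivatives(list(t = 0, Im = 0, Ip = 0, chi = 0))  # dIm = 1
#' @export
circuit_derivatives <- function(state, params = circuit_params(),
                                mode = "wildtype") {
  state <- as.list(state)
  vals <- c(state$t, state$Im, state$Ip, state$chi)
  if (length(vals) != 4 || any(!is.finite(vals))) {
    stop("state must supply finite t, Im, Ip, chi", call. = FALSE)
  }
  s  <- starvation_signal(state$t, params$s_schedule)
  I2 <- irt2_rate(state$Ip, params, mode)
  I1 <- irt1_rate(state$chi, I2, params)
  It <- ime1_transcription_rate(s, I1, params)
  tibble::tibble(
    s = s, I1 = I1, I2 = I2, It = It,
    dIm = It - params$k4 * state$Im,
    dIp = params$k5 * state$Im - params$k6 * state$Ip
  )
}
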
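#' Circuit parameters for the IME1 promoter model
#'
#' Constructs the parameter set of the IRT2/Rme1/IRT1/IME1 regulatory circuit.
#' All state variables are dimensionless and scaled to lie in \[0, 1\] under
#' the defaults; time is in hours. The defaults are the values used for the
#' published simulations of the circuit.
#'
#' @param k1 Dimensionless constant controlling the strength of IRT1 (I1)
#'   inhibition by IRT2 (I2). Default 5.
#' @param k2 Ime1-protein (Ip) threshold for activating IRT2 transcription.
#'   Default 0.05.
#' @param k3 Dimensionless constant controlling the strength of IME1
#'   transcription (It) inhibition by IRT1 (I1). Default 10.
#' @param k4 Degradation rate of IME1 mRNA (Im), per hour. Default 1.
#' @param k5 Synthesis rate of Ime1 protein (Ip), per hour. Default 1.
#' @param k6 Degradation rate of Ime1 protein (Ip), per hour. Default 1.
#' @param A IRT2-rate (I2) threshold that latches IRT1 transcription on.
#'   Default 0.01.
#' @param r Rme1 concentration (dimensionless). High in cells of a single
#'   mating type (haploids), low in MATa/alpha diploids. The simulated range
#'   is \[0, 5\]. Default 5.
#' @param s_schedule Piecewise-constant starvation signal: a two-column
#'   data frame (`time`, `level`) of steps, each level holding from its time
#'   until the next step. Default: constant 1 from t = 0 (starvation applied
#'   at time zero and maintained).
#'
#' @return An object of class `ime_params`: a named list of the validated
#'   parameters.
#' @examples
#' p <- circuit_params()            # published defaults, haploid r = 5
#' circuit_params(r = 0.1)          # diploid-like Rme1 level
#' @export
circuit_params <- function(k1 = 5, k2 = 0.05, k3 = 10,
                           k4 = 1, k5 = 1, k6 = 1,
                           A = 0.01, r = 5,
                           s_schedule = default_schedule()) {
  stopifnot(is.numeric(k1), is.numeric(k2), is.numeric(k3),
            is.numeric(k4), is.numeric(k5), is.numeric(k6),
            is.numeric(A), is.numeric(r))
  vals <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5, k6 = k6,
            A = A, r = r)
  if (any(!is.finite(vals))) {
    stop("circuit parameters must be finite", call. = FALSE)
  }
  if (k1 < 0 || k3 < 0) stop("k1 and k3 must be >= 0", call. = FALSE)
  if (k4 <= 0 || k5 <= 0 || k6 <= 0) {
    stop("rates k4, k5, k6 must be > 0", call. = FALSE)
  }
  if (k2 < 0 || k2 >= 1) stop("k2 must lie in [0, 1)", call. = FALSE)
  if (A < 0) stop("A must be >= 0", call. = FALSE)
  if (r < 0) stop("r must be >= 0", call. = FALSE)
  s_schedule <- validate_schedule(s_schedule)
  structure(
    list(k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5, k6 = k6,
         A = A, r = r, s_schedule = s_schedule),
    class = "ime_params"
  )
}

default_schedule <- function() {
  tibble::tibble(time = 0, level = 1)
}

validate_schedule <- function(schedule) {
  if (is.list(schedule) && !is.data.frame(schedule) &&
      all(vapply(schedule, length, 1L) == 2L)) {
    # accept list of (time, level) pairs
    schedule <- tibble::tibble(
      time  = vapply(schedule, function(x) as.numeric(x[[1]]), 1),
      level = vapply(schedule, function(x) as.numeric(x[[2]]), 1)
    )
  }
  schedule <- tibble::as_tibble(schedule)
  if (!all(c("time", "level") %in% names(schedule)) || nrow(schedule) == 0) {
    stop("s_schedule needs non-empty columns `time` and `level`", call. = FALSE)
  }
  if (is.unsorted(schedule$time)) {
    stop("s_schedule times must be non-decreasing", call. = FALSE)
  }
  if (schedule$time[1] > 0) {
    stop("s_schedule must define a level at t = 0", call. = FALSE)
  }
  if (any(schedule$level < 0) || any(!is.finite(schedule$level))) {
    stop("s_schedule levels must be finite and >= 0", call. = FALSE)
  }
  schedule[, c("time", "level")]
}

#' @export
print.ime_params <- function(x, ...) {
  cat("<ime_params>\n")
  nm <- c("k1", "k2", "k3", "k4", "k5", "k6", "A", "r")
  cat(paste0("  ", nm, " = ", unlist(x[nm]), collapse = "\n"), "\n")
  sch <- x$s_schedule
  cat("  s_schedule: ",
      paste0("(", sch$time, ", ", sch$level, ")", collapse = " "), "\n")
  invisible(x)
}

#' IRT2 operating modes
#'
#' The circuit can be simulated under three IRT2 regimes: `"wildtype"`
#' (IRT2 transcription follows Ime1 protein above the k2 threshold),
#' `"activating_only"` (IRT2 clamped at the low activating level A for
#' t > 0, mimicking a promoter that fires just enough to license IRT1 but
#' never represses it), and `"null"` (no IRT2 transcription at all,
#' mimicking an IRT2 promoter deletion).
#'
#' @param mode Character scalar, one of `"wildtype"`, `"activating_only"`,
#'   `"null"`.
#' @return The matched mode string.
#' @export
irt2_mode <- function(mode = c("wildtype", "activating_only", "null")) {
  match.arg(mode)
}

#' Starvation signal s(t)
#'
#' Evaluates the piecewise-constant starvation step input at time `t`:
#' the level of the most recent step at or before `t`. The default schedule
#' is s = 1 for all t >= 0 (starvation applied at time zero).
#'
#' @param t Time(s) in hours, >= 0. Vectorized.
#' @param schedule Step schedule as in [circuit_params()]; default constant 1.
#' @return Numeric vector of signal levels.
#' @examples
#' starvation_signal(c(0, 10))                          # 1 1
#' step_down <- data.frame(time = c(0, 3), level = c(1, 0))
#' starvation_signal(4, step_down)                      # 0
#' @export
starvation_signal <- function(t, schedule = default_schedule()) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  schedule <- validate_schedule(schedule)
  idx <- findInterval(t, schedule$time)
  schedule$level[idx]
}
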
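#' Simulate the hybrid IME1 promoter circuit
#'
#' Integrates the two continuous variables (IME1 mRNA `Im`, Ime1 protein
#' `Ip`) from the initial conditions Im(0) = Ip(0) = 0 with the discrete
#' latch `chi` carried as a mode of the integration. Between switching
#' events the smooth ODE is integrated with an adaptive Runge-Kutta 4(5)
#' solver; threshold crossings (Ip reaching k2, the IRT2 rate reaching A,
#' and, when the latch can release, falling back below A) are localized by
#' bisection on the crossing time and the integration is restarted there.
#'
#' @param params [circuit_params()] object.
#' @param mode IRT2 regime, see [irt2_mode()].
#' @param t_end End of the simulated interval, hours (> 0). 50 h is ample
#'   for steady state at the default rates (>= 50 relaxation times).
#' @param grid_dt Spacing of the uniform output grid, hours.
#' @param rtol,atol Relative/absolute tolerance of the adaptive integrator.
#' @param event_tol Tolerance (hours) of the bisection that localizes
#'   switching times.
#' @param stepper `"ode45"` (adaptive, default) or `"rk4"` (fixed-step
#'   fallback with step `dt`, for cross-checking).
#' @param dt Step size of the fixed-step fallback, hours.
#' @param extra_times Additional output times (e.g. an observation design)
#'   merged into the output grid.
#'
#' @return A tibble of class `ime_trajectory` with columns
#'   `time, s, chi, I1, I2, It, Im, Ip`, one row per output-grid time plus
#'   the located event times. Attributes: `events` (tibble `name`, `time`
#'   with names among `i2_onset`, `chi_activation`, `chi_deactivation`),
#'   `params`, `mode`.
#' @examples
#' tr <- simulate_circuit(circuit_params(r = 5), t_end = 5)
#' circuit_events(tr)
#' @export
simulate_circuit <- function(params = circuit_params(), mode = "wildtype",
                             t_end = 50, grid_dt = 0.01,
                             rtol = 1e-9, atol = 1e-12, event_tol = 1e-6,
                             stepper = c("ode45", "rk4"), dt = 1e-3,
                             extra_times = NULL) {
  mode <- irt2_mode(mode)
  stopifnot(inherits(params, "ime_params"))
  if (!is.finite(t_end) || t_end <= 0) {
    stop("t_end must be > 0", call. = FALSE)
  }
  stepper <- match.arg(stepper)
  if (stepper == "rk4") {
    return(simulate_rk4(params, mode, t_end, grid_dt, dt))
  }

  grid <- seq(0, t_end, by = grid_dt)
  if (grid[length(grid)] < t_end) grid <- c(grid, t_end)
  if (!is.null(extra_times)) {
    stopifnot(all(extra_times >= 0), all(extra_times <= t_end))
    grid <- sort(unique(c(grid, extra_times)))
  }

  # schedule breakpoints partition [0, t_end] into constant-s windows
  breaks <- sort(unique(c(0, params$s_schedule$time, t_end)))
  breaks <- breaks[breaks >= 0 & breaks <= t_end]
  if (breaks[length(breaks)] < t_end) breaks <- c(breaks, t_end)

  chi <- 0
  y <- c(Im = 0, Ip = 0)
  events <- list()
  rows <- list(make_rows(0, y["Im"], y["Ip"], chi, params, mode))

  # initial latch evaluation at t = 0+ (one-step lag: I1_prev from chi = 0);
  # fires immediately for the activating_only clamp (I2 = A >= A)
  I2_0 <- irt2_rate(unname(y["Ip"]), params, mode)
  chi_new <- update_chi(chi, I2_0, irt1_rate(chi, I2_0, params), params)
  if (chi_new != chi) {
    events <- add_event(events, "chi_activation", 0)
    chi <- chi_new
  }

  for (w in seq_len(length(breaks) - 1)) {
    t0 <- breaks[w]; t1 <- breaks[w + 1]
    if (t1 <= t0) next
    s_lev <- starvation_signal(t0, params$s_schedule)
    t_cur <- t0
    # the latch may flip several times inside one window (only when r = 0)
    repeat {
      seg <- integrate_segment(y, t_cur, t1, chi, s_lev, params, mode,
                               grid, rtol, atol, event_tol)
      rows <- c(rows, list(seg$rows))
      events <- c(events, seg$events)
      y <- seg$y_end
      t_cur <- seg$t_end
      chi <- seg$chi_end
      if (t_cur >= t1 - 1e-12) break
    }
  }

  traj <- dplyr::bind_rows(rows)
  traj <- traj[order(traj$time), ]
  traj <- traj[!duplicated(round(traj$time, 9)), ]
  ev <- if (length(events)) {
    dplyr::bind_rows(events)
  } else {
    tibble::tibble(name = character(), time = numeric())
  }
  ev <- ev[order(ev$time), ]
  # i2_onset is the FIRST time Ip reaches k2; drop any later re-crossings
  ev <- ev[!(ev$name == "i2_onset" & cumsum(ev$name == "i2_onset") > 1), ]
  new_trajectory(traj, ev, params, mode)
}

new_trajectory <- function(tbl, events, params, mode) {
  tbl <- tibble::as_tibble(tbl)
  structure(tbl,
            events = events, params = params, mode = mode,
            class = c("ime_trajectory", class(tbl)))
}

#' Switching events of a simulated trajectory
#'
#' @param trajectory An `ime_trajectory` from [simulate_circuit()].
#' @return Tibble with columns `name` (`i2_onset`, `chi_activation`,
#'   `chi_deactivation`) and `time` (hours).
#' @export
circuit_events <- function(trajectory) {
  stopifnot(inherits(trajectory, "ime_trajectory"))
  attr(trajectory, "events")
}

add_event <- function(events, name, time) {
  c(events, list(tibble::tibble(name = name, time = time)))
}

# RHS of the smooth ODE for a fixed latch state and starvation level
rhs_factory <- function(chi, s_lev, params, mode) {
  k1 <- params$k1; k2 <- params$k2; k3 <- params$k3
  k4 <- params$k4; k5 <- params$k5; k6 <- params$k6
  A <- params$A; r <- params$r
  function(t, y, parms) {
    Ip <- y[2]
    I2 <- switch(mode,
                 wildtype = max(Ip - k2, 0),
                 activating_only = A,
                 null = 0)
    denom <- r + k1 * I2
    I1 <- if (denom > 0) chi * r / denom else 0
    It <- if (s_lev > 0) s_lev / (s_lev + k3 * I1) else 0
    list(c(It - k4 * y[1], k5 * y[1] - k6 * Ip))
  }
}

# Integrate one smooth segment, watching the Ip thresholds that can fire
# while chi is in its current state. Returns rows on the output grid up to
# the first latch-flipping event (or the segment end).
integrate_segment <- function(y0, t0, t1, chi, s_lev, params, mode,
                              grid, rtol, atol, event_tol) {
  f <- rhs_factory(chi, s_lev, params, mode)
  out_times <- sort(unique(c(t0, grid[grid > t0 & grid < t1], t1)))

  # threshold watches for the current (mode, chi, r) regime
  watches <- list()
  if (mode == "wildtype") {
    if (chi == 0) {
      watches <- list(
        list(name = "i2_onset", th = params$k2, dir = "up", flips = FALSE),
        list(name = "chi_activation", th = params$k2 + params$A,
             dir = "up", flips = TRUE)
      )
    } else if (params$r == 0) {
      # latch can only release when I1 = 0, i.e. r = 0
      watches <- list(
        list(name = "chi_deactivation", th = params$k2 + params$A,
             dir = "down", flips = TRUE)
      )
    }
  }

  # internal sampling fine enough to bracket crossings; segments with no
  # watchable threshold only need the requested output times
  dense <- if (length(watches)) {
    sort(unique(c(out_times, seq(t0, t1, length.out =
                                   max(2, ceiling((t1 - t0) / 0.01))))))
  } else {
    out_times
  }
  sol <- deSolve::ode(y = y0, times = dense, func = f, parms = NULL,
                      method = "ode45", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("integration failed at t = ", utils::tail(sol[, 1], 1),
         " (state: Im = ", utils::tail(sol[, 2], 1),
         ", Ip = ", utils::tail(sol[, 3], 1), ")", call. = FALSE)
  }
  tt <- unname(sol[, 1]); Im <- unname(sol[, 2]); Ip <- unname(sol[, 3])

  hits <- purrr::compact(purrr::map(watches, function(wch) {
    i <- first_crossing(Ip, wch$th, wch$dir)
    if (is.null(i)) return(NULL)
    t_star <- locate_crossing(tt[i], c(Im = Im[i], Ip = Ip[i]), tt[i + 1],
                              wch$th, f, rtol, atol, event_tol)
    list(name = wch$name, time = t_star, flips = wch$flips)
  }))

  flip <- NULL
  if (length(hits)) {
    hits <- hits[order(vapply(hits, `[[`, 1, "time"))]
    flips <- purrr::keep(hits, "flips")
    if (length(flips)) flip <- flips[[1]]
  }
  seg_end <- if (is.null(flip)) t1 else flip$time
  kept_hits <- purrr::keep(hits, ~ .x$time <= seg_end + event_tol)
  evs <- purrr::map(kept_hits,
                    ~ tibble::tibble(name = .x$name, time = .x$time))

  keep <- tt <= seg_end + 1e-15
  keep_t <- tt[keep]; keep_Im <- Im[keep]; keep_Ip <- Ip[keep]
  on_grid <- keep_t %in% out_times | keep_t == t0
  rows <- make_rows(keep_t[on_grid], keep_Im[on_grid], keep_Ip[on_grid],
                    chi, params, mode)
  # a row at each located event time (non-flip events do not end the
  # segment, so they would otherwise fall between grid points)
  for (h in kept_hits) {
    if (!is.null(flip) && h$time >= flip$time) next
    i <- max(which(tt <= h$time))
    y_h <- state_at(f, tt[i], c(Im = Im[i], Ip = Ip[i]), h$time,
                    rtol, atol)
    rows <- dplyr::bind_rows(rows, make_rows(h$time, y_h[1], y_h[2],
                                             chi, params, mode))
  }
  # state at the segment end (event time or window end)
  if (is.null(flip)) {
    n <- length(tt)
    y_end <- c(Im = Im[n], Ip = Ip[n]); t_end <- tt[n]; chi_end <- chi
  } else {
    i <- max(which(tt <= flip$time))
    if (flip$time - tt[i] < 1e-14) {
      y_end <- c(Im = unname(Im[i]), Ip = unname(Ip[i]))
    } else {
      sol2 <- deSolve::ode(y = c(Im = Im[i], Ip = Ip[i]),
                           times = c(tt[i], flip$time), func = f,
                           parms = NULL,
                           method = "ode45", rtol = rtol, atol = atol)
      y_end <- c(Im = unname(sol2[2, 2]), Ip = unname(sol2[2, 3]))
    }
    t_end <- flip$time
    chi_end <- if (flip$name == "chi_activation") 1 else 0
    rows <- dplyr::bind_rows(rows,
                             make_rows(t_end, y_end["Im"], y_end["Ip"],
                                       chi, params, mode))
  }
  list(rows = rows, events = evs, y_end = y_end, t_end = t_end,
       chi_end = chi_end)
}

first_crossing <- function(x, th, dir) {
  n <- length(x)
  if (n < 2) return(NULL)
  a <- x[-n]; b <- x[-1]
  idx <- if (dir == "up") which(a < th & b >= th) else which(a >= th & b < th)
  if (!length(idx)) NULL else idx[1]
}

# state at time t_to, restarting from (t_from, y_from)
state_at <- function(f, t_from, y_from, t_to, rtol, atol) {
  if (t_to - t_from < 1e-14) return(unname(y_from))
  sol <- deSolve::ode(y = y_from, times = c(t_from, t_to), func = f,
                      parms = NULL, method = "ode45",
                      rtol = rtol, atol = atol)
  c(unname(sol[2, 2]), unname(sol[2, 3]))
}

# bisection on the crossing time (re-integrating from the last
# pre-crossing state), then one Newton polish so the trigger sits on its
# threshold far below the bisection tolerance
locate_crossing <- function(ta, ya, tb, th, f, rtol, atol, event_tol) {
  g <- function(tq) {
    if (tq <= ta) return(unname(ya["Ip"]) - th)
    sol <- deSolve::ode(y = ya, times = c(ta, tq), func = f, parms = NULL,
                        method = "ode45", rtol = rtol, atol = atol)
    unname(sol[2, 3]) - th
  }
  if (abs(g(ta)) < 1e-14) return(ta)
  root <- stats::uniroot(g, c(ta, tb), tol = event_tol)$root
  st <- state_at(f, ta, ya, root, rtol, atol)
  dIp <- unlist(f(root, st, NULL))[2]
  if (is.finite(dIp) && abs(dIp) > 1e-12) {
    root <- min(max(root - (st[2] - th) / dIp, ta), tb)
  }
  root
}

make_rows <- function(time, Im, Ip, chi, params, mode) {
  Im <- unname(Im); Ip <- unname(Ip)
  s <- starvation_signal(time, params$s_schedule)
  I2 <- irt2_rate(pmax(Ip, 0), params, mode)
  I1 <- irt1_rate(rep(chi, length(time)), I2, params)
  It <- ime1_transcription_rate(s, I1, params)
  tibble::tibble(time = time, s = s, chi = chi, I1 = I1, I2 = I2, It = It,
                 Im = Im, Ip = Ip)
}

# fixed-step classical RK4 with per-step latch update (cross-check path)
simulate_rk4 <- function(params, mode, t_end, grid_dt, dt) {
  n <- ceiling(t_end / dt)
  chi <- 0; Im <- 0; Ip <- 0; I1_prev <- 0
  events <- list()
  out_every <- max(1L, round(grid_dt / dt))
  times <- numeric(); Ims <- numeric(); Ips <- numeric(); chis <- numeric()
  k1 <- params$k1; k2 <- params$k2; k3 <- params$k3
  k4 <- params$k4; k5 <- params$k5; k6 <- params$k6
  i2_of <- function(Ip) switch(mode, wildtype = max(Ip - k2, 0),
                               activating_only = params$A, null = 0)
  seen_i2 <- FALSE
  for (i in 0:n) {
    t <- i * dt
    I2 <- i2_of(Ip)
    chi_new <- update_chi(chi, I2, I1_prev, params)
    if (chi_new != chi) {
      events <- add_event(events,
                          if (chi_new == 1) "chi_activation"
                          else "chi_deactivation", t)
      chi <- chi_new
    }
    if (!seen_i2 && mode == "wildtype" && Ip >= k2) {
      events <- add_event(events, "i2_onset", t)
      seen_i2 <- TRUE
    }
    I1_prev <- irt1_rate(chi, I2, params)
    if (i %% out_every == 0 || i == n) {
      times <- c(times, t); Ims <- c(Ims, Im); Ips <- c(Ips, Ip)
      chis <- c(chis, chi)
    }
    if (i == n) break
    s_lev <- starvation_signal(t, params$s_schedule)
    deriv <- function(Im, Ip) {
      I2 <- i2_of(Ip)
      denom <- params$r + k1 * I2
      I1 <- if (denom > 0) chi * params$r / denom else 0
      It <- if (s_lev > 0) s_lev / (s_lev + k3 * I1) else 0
      c(It - k4 * Im, k5 * Im - k6 * Ip)
    }
    d1 <- deriv(Im, Ip)
    d2 <- deriv(Im + dt / 2 * d1[1], Ip + dt / 2 * d1[2])
    d3 <- deriv(Im + dt / 2 * d2[1], Ip + dt / 2 * d2[2])
    d4 <- deriv(Im + dt * d3[1], Ip + dt * d3[2])
    Im <- Im + dt / 6 * (d1[1] + 2 * d2[1] + 2 * d3[1] + d4[1])
    Ip <- Ip + dt / 6 * (d1[2] + 2 * d2[2] + 2 * d3[2] + d4[2])
  }
  rows <- purrr::pmap(list(times, Ims, Ips, chis),
                      function(t, im, ip, ch) make_rows(t, im, ip, ch,
                                                        params, mode))
  ev <- if (length(events)) dplyr::bind_rows(events) else
    tibble::tibble(name = character(), time = numeric())
  new_trajectory(dplyr::bind_rows(rows), ev, params, mode)
}

#' Locate the switching events of the circuit
#'
#' Runs the hybrid simulation and returns the located threshold crossings:
#' `i2_onset` (first time Ip reaches k2, where IRT2 transcription turns on)
#' and `chi_activation` (first time the IRT2 rate reaches A, i.e. Ip reaches
#' k2 + A in the wildtype regime, latching IRT1 transcription on). Under
#' `mode = "null"` no events occur; under `mode = "activating_only"` the
#' latch fires at t = 0 (IRT2 is clamped at A from the start).
#'
#' @inheritParams simulate_circuit
#' @return Tibble with columns `name`, `time`; zero rows where no threshold
#'   is reached by `t_end`.
#' @export
locate_events <- function(params = circuit_params(), mode = "wildtype",
                          t_end = 5, ...) {
  circuit_events(simulate_circuit(params, mode, t_end = t_end, ...))
}

#' Simulate a yeast cell type
#'
#' Haploid (single mating type, MATa or MATalpha) cells have high Rme1;
#' MATa/alpha diploids have low Rme1. This wrapper sets the Rme1 level `r`
#' to a cell-type preset and delegates to [simulate_circuit()]. Defaults:
#' haploid r = 5 (top of the simulated range), diploid r = 0.1.
#'
#' @param cell_type `"haploid"` or `"diploid"`.
#' @param r_presets Named numeric vector of Rme1 presets.
#' @inheritParams simulate_circuit
#' @param ... Passed to [simulate_circuit()].
#' @return An `ime_trajectory`.
#' @examples
#' tr <- simulate_cell_type("diploid", t_end = 50, grid_dt = 0.1)
#' tail(tr$Ip, 1)  # ~0.79: Ime1 active, meiosis licensed
#' @export
simulate_cell_type <- function(cell_type = c("haploid", "diploid"),
                               params = circuit_params(), mode = "wildtype",
                               t_end = 50,
                               r_presets = c(haploid = 5, diploid = 0.1),
                               ...) {
  cell_type <- match.arg(cell_type)
  params$r <- unname(r_presets[[cell_type]])
  simulate_circuit(params, mode, t_end = t_end, ...)
}

#' Closed-form solution of the unrepressed cascade
#'
#' Before the latch fires (chi = 0, so I1 = 0) and for constant starvation
#' signal, the circuit reduces to a linear two-stage cascade with full
#' transcriptional drive: dIm/dt = 1 - k4 Im, dIp/dt = k5 Im - k6 Ip from
#' Im(0) = Ip(0) = 0. This analytic solution serves as an independent
#' oracle for the numerical integrator: with the default rates it is
#' Im(t) = 1 - exp(-t), Ip(t) = 1 - (1 + t) exp(-t). The degenerate
#' repeated-eigenvalue form is used when k4 = k6.
#'
#' @param t Times, hours (>= 0). Vectorized.
#' @param params [circuit_params()] object.
#' @param s Constant starvation level on \[0, t\] (only its sign matters:
#'   the unrepressed transcription rate is s/(s + 0) = 1 for s > 0).
#' @return Tibble with columns `time`, `Im`, `Ip`.
#' @examples
#' closed_form_cascade(1)  # Im = 0.63212, Ip = 0.26424
#' @export
closed_form_cascade <- function(t, params = circuit_params(), s = 1) {
  stopifnot(all(t >= 0), s >= 0)
  k4 <- params$k4; k5 <- params$k5; k6 <- params$k6
  It0 <- if (s > 0) 1 else 0
  M <- It0 / k4
  Im <- M * (1 - exp(-k4 * t))
  if (abs(k4 - k6) < 1e-12) {
    Ip <- k5 * M * ((1 - exp(-k6 * t)) / k6 - t * exp(-k6 * t))
  } else {
    Ip <- k5 * M * ((1 - exp(-k6 * t)) / k6 -
                      (exp(-k4 * t) - exp(-k6 * t)) / (k6 - k4))
  }
  tibble::tibble(time = t, Im = Im, Ip = Ip)
}
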
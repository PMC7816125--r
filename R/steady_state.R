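#' Steady state of the circuit
#'
#' Solves for the fixed point of the hybrid system under a constant
#' starvation signal. In the unrepressed regimes (latch never fires, or
#' r = 0) the steady state is the linear-cascade plateau
#' Ip* = k5/(k4 k6). Once the latch has fired, Ip* solves the
#' self-consistency equation
#' \deqn{I_p = \frac{k_5}{k_4 k_6}\,\frac{s}{s + k_3 I_1(I_p)}}
#' with \eqn{I_1(I_p) = r/(r + k_1 \max(I_p - k_2, 0))} in the wildtype
#' regime (a quadratic on the branch Ip >= k2) or the constant
#' \eqn{I_1 = r/(r + k_1 A)} under the activating-only clamp. Where the
#' branch structure admits several algebraic roots, branch consistency
#' (the Ip >= k2 assumption must hold at the root) eliminates the spurious
#' ones, and any residual ambiguity is resolved by the fixed point actually
#' reached by forward integration from Im(0) = Ip(0) = 0; all roots are
#' recorded.
#'
#' @param params [circuit_params()] object; the starvation schedule must be
#'   constant.
#' @param mode IRT2 regime, see [irt2_mode()].
#' @param method `"analytic"` (branch-resolved closed form, default) or
#'   `"integration"` (read the state off a long-horizon simulation).
#' @param t_end Horizon for `method = "integration"` and for the
#'   reachability cross-check, hours.
#' @return A list of class `ime_steady_state`: `Ip_star`, `Im_star`
#'   (= (k6/k5) Ip_star), `I1_star`, `I2_star`, `chi_star`, `method`,
#'   `residual` (self-consistency residual |Ip - target(Ip)|), `roots`
#'   (all branch-consistent candidates), `chi_activated` (FALSE with a
#'   warning when the latch threshold is unreachable and the cascade
#'   plateau is returned).
#' @examples
#' fixed_point(circuit_params(r = 0.25))$Ip_star   # exactly 0.5
#' fixed_point(circuit_params(r = 5))$Ip_star      # ~0.0946 (repressed)
#' @export
fixed_point <- function(params = circuit_params(), mode = "wildtype",
                        method = c("analytic", "integration"), t_end = 50) {
  mode <- irt2_mode(mode)
  method <- match.arg(method)
  stopifnot(inherits(params, "ime_params"))
  lev <- unique(params$s_schedule$level)
  if (length(lev) != 1) {
    stop("fixed_point requires a constant starvation signal", call. = FALSE)
  }
  s <- lev

  if (method == "integration") {
    tr <- simulate_circuit(params, mode, t_end = t_end, grid_dt = 0.05)
    n <- nrow(tr)
    return(new_steady_state(tr$Ip[n], tr$chi[n], params, mode, s,
                            method = "integration",
                            roots = tr$Ip[n], chi_activated = tr$chi[n] == 1))
  }

  C <- params$k5 / (params$k4 * params$k6)  # unrepressed plateau (s > 0)
  if (s == 0) {
    return(new_steady_state(0, 0, params, mode, s, roots = 0,
                            chi_activated = FALSE))
  }

  # does the latch ever fire? the unrepressed trajectory climbs
  # monotonically toward C, so the peak achievable I2 is its value at C
  if (mode == "null" && params$A > 0) {
    # no IRT2 transcription: the latch never fires, by design
    return(new_steady_state(C, 0, params, mode, s, roots = C,
                            chi_activated = FALSE))
  }
  I2_max <- switch(mode,
                   wildtype = max(C - params$k2, 0),
                   activating_only = params$A,
                   null = 0)
  if (I2_max < params$A ||
      (mode == "wildtype" && C - params$k2 <= params$A)) {
    # threshold unreachable (only approached asymptotically at equality)
    warning("latch threshold A is not reachable; returning the ",
            "unrepressed cascade steady state (chi = 0)", call. = FALSE)
    return(new_steady_state(C, 0, params, mode, s, roots = C,
                            chi_activated = FALSE))
  }

  if (params$r == 0 && mode != "activating_only") {
    # wildtype r = 0: I1 = 0 even with the latch set
    return(new_steady_state(C, 1, params, mode, s, roots = C,
                            chi_activated = TRUE))
  }

  k1 <- params$k1; k2 <- params$k2; k3 <- params$k3; r <- params$r
  cands <- switch(mode,
    activating_only = {
      I1 <- irt1_rate(1, params$A, params)
      C * s / (s + k3 * I1)
    },
    null = C,  # A = 0 edge: latch set but I2 = 0 -> I1 = r/r
    wildtype = {
      # branch Ip >= k2: s k1 Ip^2 + (s r - s k1 k2 + k3 r - C s k1) Ip
      #                  - C s (r - k1 k2) = 0
      a <- s * k1
      b <- s * r - s * k1 * k2 + k3 * r - C * s * k1
      cc <- -C * s * (r - k1 * k2)
      disc <- b^2 - 4 * a * cc
      roots_hi <- if (a == 0) {
        if (b != 0) -cc / b else numeric()
      } else if (disc >= 0) {
        (-b + c(1, -1) * sqrt(disc)) / (2 * a)
      } else numeric()
      roots_hi <- roots_hi[roots_hi >= k2 & roots_hi <= C + 1e-12]
      # branch Ip < k2: I2 = 0 so I1 = 1 (r > 0)
      lo <- C * s / (s + k3)
      roots_lo <- if (lo < k2) lo else numeric()
      sort(unique(c(roots_hi, roots_lo)))
    }
  )
  if (mode == "null" && params$A == 0 && r > 0) {
    cands <- C * s / (s + k3)  # I1 = r/(r + 0) = 1
  }

  if (!length(cands)) {
    stop("no branch-consistent fixed point found (r = ", r, ", mode = ",
         mode, ")", call. = FALSE)
  }
  if (length(cands) > 1) {
    # reachability cross-check: the fixed point attained from (0, 0)
    tr <- simulate_circuit(params, mode, t_end = t_end, grid_dt = 0.05)
    Ip_dyn <- tr$Ip[nrow(tr)]
    pick <- cands[which.min(abs(cands - Ip_dyn))]
  } else {
    pick <- cands
  }
  new_steady_state(pick, 1, params, mode, s, roots = cands,
                   chi_activated = TRUE)
}

new_steady_state <- function(Ip_star, chi_star, params, mode, s,
                             method = "analytic", roots, chi_activated) {
  I2 <- irt2_rate(max(Ip_star, 0), params, mode)
  I1 <- irt1_rate(chi_star, I2, params)
  target <- if (s > 0) {
    params$k5 / (params$k4 * params$k6) * s / (s + params$k3 * I1)
  } else 0
  structure(
    list(Ip_star = unname(Ip_star),
         Im_star = unname(params$k6 / params$k5 * Ip_star),
         I1_star = unname(I1), I2_star = unname(I2),
         chi_star = chi_star, method = method,
         residual = abs(unname(Ip_star - target)),
         roots = unname(roots), chi_activated = chi_activated,
         params = params, mode = mode),
    class = "ime_steady_state"
  )
}

#' @export
print.ime_steady_state <- function(x, ...) {
  cat("<ime_steady_state> mode =", x$mode, " method =", x$method, "\n")
  cat(sprintf("  Ip* = %.6g  Im* = %.6g  I1* = %.6g  I2* = %.6g  chi* = %d\n",
              x$Ip_star, x$Im_star, x$I1_star, x$I2_star, as.integer(x$chi_star)))
  cat(sprintf("  residual = %.3g  roots: %s\n", x$residual,
              paste(signif(x$roots, 6), collapse = ", ")))
  invisible(x)
}

#' Default Rme1 grid for dose-response sweeps
#'
#' 101 linearly spaced points on \[0, 5\] (the simulated Rme1 range)
#' augmented with 20 log-spaced points on \[1e-3, 1\] to resolve the
#' switch transition.
#' @return Increasing numeric vector.
#' @export
default_r_grid <- function() {
  sort(unique(c(seq(0, 5, length.out = 101),
                10^seq(-3, 0, length.out = 20))))
}

#' Steady-state dose-response over Rme1
#'
#' Sweeps the Rme1 concentration r over a grid and records the Ime1
#' protein steady state per r ([fixed_point()]). A configurable fraction of
#' grid points is verified against long-horizon forward integration.
#'
#' @param r_grid Increasing, nonnegative Rme1 grid;
#'   default [default_r_grid()].
#' @param params [circuit_params()] object (its `r` is overridden).
#' @param mode IRT2 regime, see [irt2_mode()].
#' @param verify_fraction Fraction of grid points cross-checked by
#'   integration (default 0.1; 0 disables).
#' @param verify_tol Allowed |analytic - integrated| at checked points.
#' @return Tibble of class `ime_dose_response` with columns `r`, `Ip_star`,
#'   `Im_star`, `I1_star`, `I2_star`, `chi_star`; attributes `mode`,
#'   `params`, `verified` (tibble of checked points and deviations).
#' @examples
#' dr <- dose_response(c(0, 0.25, 5), verify_fraction = 0)
#' dr$Ip_star  # 1.0, 0.5, ~0.0946
#' @export
dose_response <- function(r_grid = default_r_grid(),
                          params = circuit_params(), mode = "wildtype",
                          verify_fraction = 0.1, verify_tol = 1e-4) {
  mode <- irt2_mode(mode)
  if (!length(r_grid)) stop("r_grid must be non-empty", call. = FALSE)
  if (any(r_grid < 0) || is.unsorted(r_grid, strictly = TRUE)) {
    stop("r_grid must be strictly increasing and nonnegative", call. = FALSE)
  }
  sol <- purrr::map(r_grid, function(rv) {
    p <- params; p$r <- rv
    fp <- fixed_point(p, mode)
    tibble::tibble(r = rv, Ip_star = fp$Ip_star, Im_star = fp$Im_star,
                   I1_star = fp$I1_star, I2_star = fp$I2_star,
                   chi_star = fp$chi_star)
  })
  out <- dplyr::bind_rows(sol)

  verified <- tibble::tibble(r = numeric(), analytic = numeric(),
                             integrated = numeric(), abs_diff = numeric())
  if (verify_fraction > 0) {
    n_chk <- max(1L, ceiling(verify_fraction * length(r_grid)))
    idx <- unique(round(seq(1, length(r_grid), length.out = n_chk)))
    verified <- dplyr::bind_rows(purrr::map(idx, function(i) {
      p <- params; p$r <- r_grid[i]
      fp <- fixed_point(p, mode, method = "integration")
      tibble::tibble(r = r_grid[i], analytic = out$Ip_star[i],
                     integrated = fp$Ip_star,
                     abs_diff = abs(out$Ip_star[i] - fp$Ip_star))
    }))
    if (any(verified$abs_diff > verify_tol)) {
      warning("analytic and integrated steady states disagree beyond ",
              verify_tol, " at r = ",
              paste(verified$r[verified$abs_diff > verify_tol],
                    collapse = ", "), call. = FALSE)
    }
  }
  structure(tibble::as_tibble(out),
            mode = mode, params = params, verified = verified,
            class = c("ime_dose_response", class(out)))
}

#' Switch-shape metrics of a dose-response curve
#'
#' Quantifies how switch-like the Rme1 -> Ime1 steady-state relationship
#' is. `r_half` is the Rme1 level at which Ip* crosses half of its low-r
#' plateau value (the half-maximal response; refined by root-finding on
#' the underlying fixed-point map when the curve carries its parameter
#' snapshot, otherwise by monotone interpolation on the grid).
#' `dynamic_range` is Ip*(r_min)/Ip*(r_max); `max_abs_slope` is the
#' steepest |d Ip* / d log10 r| over the grid. The curve is classified
#' `switch_like` when the dynamic range reaches `dr_min` and `r_half` sits
#' at or above `r_half_min` — a high-contrast switch positioned inside the
#' physiological Rme1 window. Flat curves get `r_half = NA` and
#' `switch_like = FALSE`.
#'
#' @param curve An `ime_dose_response` (or a tibble with `r`, `Ip_star`).
#' @param dr_min Minimum dynamic range for a switch (default 5).
#' @param r_half_min Minimum r_half for a switch (default 0.05).
#' @return One-row tibble: `r_half`, `dynamic_range`, `max_abs_slope`,
#'   `switch_like`, `mode`.
#' @export
sigmoid_metrics <- function(curve, dr_min = 5, r_half_min = 0.05) {
  stopifnot(nrow(curve) >= 3, all(c("r", "Ip_star") %in% names(curve)))
  mode <- attr(curve, "mode") %||% NA_character_
  params <- attr(curve, "params")
  top <- curve$Ip_star[1]
  bottom <- curve$Ip_star[nrow(curve)]
  dynamic_range <- if (bottom > 0) top / bottom else Inf

  rng <- diff(range(curve$Ip_star))
  flat <- rng < 1e-9 * max(abs(curve$Ip_star), 1e-300)

  r_half <- NA_real_
  if (!flat) {
    half <- top / 2
    below <- which(curve$Ip_star <= half)
    if (length(below)) {
      j <- below[1]
      if (j > 1 && !is.null(params) && !is.na(mode)) {
        g <- function(rv) {
          p <- params; p$r <- rv
          fixed_point(p, mode)$Ip_star - half
        }
        r_half <- stats::uniroot(g, c(curve$r[j - 1], curve$r[j]),
                                 tol = 1e-12)$root
      } else if (j > 1) {
        # monotone (non-increasing) segment: linear interpolation
        r_half <- stats::approx(curve$Ip_star[c(j - 1, j)],
                                curve$r[c(j - 1, j)], xout = half)$y
      } else {
        r_half <- curve$r[1]
      }
    }
  }

  pos <- curve$r > 0
  max_abs_slope <- if (sum(pos) >= 2) {
    lr <- log10(curve$r[pos]); ip <- curve$Ip_star[pos]
    max(abs(diff(ip) / diff(lr)))
  } else NA_real_

  tibble::tibble(
    r_half = r_half,
    dynamic_range = dynamic_range,
    max_abs_slope = max_abs_slope,
    switch_like = !flat && is.finite(dynamic_range) &&
      dynamic_range >= dr_min && !is.na(r_half) && r_half >= r_half_min,
    mode = mode
  )
}
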
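# Synthetic observations with the statistical structure the analysis
# assumes: noisy bulk time courses (the analogue of blot quantifications,
# which are positive and ratio-scaled, hence multiplicative lognormal
# noise) and single-cell mRNA copy-number populations (the analogue of an
# smFISH readout, with Poisson counting noise and the 30-copies-per-cell
# high-expresser threshold).

with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Generate a synthetic noisy time course
#'
#' Simulates the circuit, samples the true (Im, Ip) at the design times,
#' and applies independent multiplicative lognormal observation noise:
#' observed = true * exp(eps), eps ~ Normal(0, noise_sigma^2), drawn
#' independently per time point, replicate and variable. The ground truth
#' (parameters, mode, noiseless values) and the seed are stored with the
#' data, and regenerating with the same seed reproduces the observations
#' bit for bit.
#'
#' @param params [circuit_params()] object (the ground truth).
#' @param mode IRT2 regime, see [irt2_mode()].
#' @param times Observation times, hours, increasing and >= 0.
#' @param noise_sigma Standard deviation of the log-scale noise (>= 0).
#'   Default 0.1.
#' @param n_rep Number of replicates per time point (>= 1).
#' @param seed Integer seed (Mersenne-Twister; recorded in the output).
#' @return Tibble of class `ime_timecourse`, long format with columns
#'   `time`, `rep`, `variable` (`"Im"` or `"Ip"`), `true`, `observed`.
#'   Attributes: `params`, `mode`, `noise` (list `family`, `sigma`),
#'   `seed`, `design`.
#' @examples
#' tc <- generate_time_course(times = c(1, 2, 4), noise_sigma = 0.1,
#'                            n_rep = 2, seed = 1)
#' @export
generate_time_course <- function(params = circuit_params(),
                                 mode = "wildtype",
                                 times = seq(0.5, 10, length.out = 20),
                                 noise_sigma = 0.1, n_rep = 3, seed = 1) {
  mode <- irt2_mode(mode)
  if (!length(times) || any(times < 0) || is.unsorted(times, strictly = TRUE)) {
    stop("times must be increasing and >= 0", call. = FALSE)
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (n_rep < 1) stop("n_rep must be >= 1", call. = FALSE)

  tr <- simulate_circuit(params, mode, t_end = max(times, 1),
                         grid_dt = max(times, 1) / 10, extra_times = times)
  idx <- match(times, tr$time)
  truth <- tibble::tibble(time = times, Im = tr$Im[idx], Ip = tr$Ip[idx])

  long <- tidyr::pivot_longer(truth, c("Im", "Ip"),
                              names_to = "variable", values_to = "true")
  design <- tidyr::expand_grid(long, rep = seq_len(n_rep))
  design <- dplyr::arrange(design, .data$time, .data$variable, .data$rep)

  eps <- with_preserved_seed(seed,
                             stats::rnorm(nrow(design), 0, noise_sigma))
  out <- dplyr::mutate(design, observed = .data$true * exp(eps))
  out <- dplyr::select(out, "time", "rep", "variable", "true", "observed")
  structure(tibble::as_tibble(out),
            params = params, mode = mode,
            noise = list(family = "lognormal", sigma = noise_sigma),
            seed = seed, design = list(times = times, n_rep = n_rep),
            class = c("ime_timecourse", class(out)))
}

#' Rme1 samplers for synthetic cell populations
#'
#' Presets for the per-cell Rme1 concentration: a point mass (an isogenic
#' population of one cell type), a lognormal (cell-to-cell Rme1
#' variability), or a mixture of samplers (e.g. a mixed haploid/diploid
#' culture).
#'
#' @param dist `"point"`, `"lognormal"` or `"mixture"`.
#' @param r Point-mass value (`dist = "point"`).
#' @param meanlog,sdlog Lognormal log-scale parameters.
#' @param weights,components Mixture weights (summing to 1) and a list of
#'   component samplers.
#' @return A list of class `ime_r_sampler`.
#' @examples
#' cell_r_sampler("point", r = 5)
#' cell_r_sampler("mixture",
#'                weights = c(0.5, 0.5),
#'                components = list(cell_r_sampler("point", r = 5),
#'                                  cell_r_sampler("point", r = 0.1)))
#' @export
cell_r_sampler <- function(dist = c("point", "lognormal", "mixture"),
                           r = 5, meanlog = log(0.1), sdlog = 0.3,
                           weights = NULL, components = NULL) {
  dist <- match.arg(dist)
  out <- switch(dist,
    point = list(dist = dist, r = r),
    lognormal = list(dist = dist, meanlog = meanlog, sdlog = sdlog),
    mixture = {
      stopifnot(!is.null(weights), !is.null(components),
                length(weights) == length(components),
                abs(sum(weights) - 1) < 1e-12)
      list(dist = dist, weights = weights, components = components)
    })
  structure(out, class = "ime_r_sampler")
}

draw_r <- function(sampler, n) {
  switch(sampler$dist,
    point = rep_len(sampler$r, n),
    lognormal = stats::rlnorm(n, sampler$meanlog, sampler$sdlog),
    mixture = {
      comp <- sample.int(length(sampler$weights), n, replace = TRUE,
                         prob = sampler$weights)
      out <- numeric(n)
      for (k in seq_along(sampler$components)) {
        sel <- comp == k
        if (any(sel)) out[sel] <- draw_r(sampler$components[[k]], sum(sel))
      }
      out
    })
}

#' Generate a synthetic single-cell mRNA population
#'
#' Emulates a single-molecule FISH readout at steady state: each cell
#' draws an Rme1 level from the sampler, its steady-state IME1 mRNA level
#' Im* is computed from the circuit fixed point, and an integer copy
#' number is drawn as Poisson(copy_scale * Im*). Cells with more than
#' `threshold` copies are classified as high IME1 expressers (default 30
#' copies per cell, the standard smFISH criterion for this locus). The
#' mapping from the dimensionless Im to absolute copies (`copy_scale`,
#' default 50 copies per unit Im) is a declared synthetic modeling choice,
#' not an inferred biological quantity.
#'
#' @param n_cells Number of cells (>= 0).
#' @param r_sampler A [cell_r_sampler()].
#' @param params [circuit_params()] object.
#' @param mode IRT2 regime, see [irt2_mode()].
#' @param copy_scale Copies per unit Im (> 0). Default 50.
#' @param threshold Copy count above which a cell is a high expresser.
#'   Default 30.
#' @param seed Integer seed.
#' @return Tibble of class `ime_cell_population` with one row per cell
#'   (`cell`, `r`, `Im_star`, `copies`, `high`). Attributes: `copy_scale`,
#'   `threshold`, `fraction_high` (NA when `n_cells = 0`), `params`,
#'   `mode`, `seed`.
#' @examples
#' pop <- generate_cell_population(200, cell_r_sampler("point", r = 5),
#'                                 mode = "null", seed = 1)
#' attr(pop, "fraction_high")  # ~1: derepressed cells exceed 30 copies
#' @export
generate_cell_population <- function(n_cells,
                                     r_sampler = cell_r_sampler("point", r = 5),
                                     params = circuit_params(),
                                     mode = "wildtype",
                                     copy_scale = 50, threshold = 30,
                                     seed = 1) {
  mode <- irt2_mode(mode)
  stopifnot(n_cells >= 0, copy_scale > 0, threshold >= 0)
  if (n_cells == 0) {
    out <- tibble::tibble(cell = integer(), r = numeric(),
                          Im_star = numeric(), copies = integer(),
                          high = logical())
    return(structure(out, copy_scale = copy_scale, threshold = threshold,
                     fraction_high = NA_real_, params = params, mode = mode,
                     seed = seed,
                     class = c("ime_cell_population", class(out))))
  }
  dat <- with_preserved_seed(seed, {
    r <- draw_r(r_sampler, n_cells)
    # steady state per distinct r (cache: point-mass populations hit once)
    ru <- unique(r)
    im_u <- vapply(ru, function(rv) {
      p <- params; p$r <- rv
      fixed_point(p, mode)$Im_star
    }, 1)
    Im_star <- im_u[match(r, ru)]
    copies <- stats::rpois(n_cells, copy_scale * Im_star)
    tibble::tibble(cell = seq_len(n_cells), r = r, Im_star = Im_star,
                   copies = copies, high = copies > threshold)
  })
  structure(dat, copy_scale = copy_scale, threshold = threshold,
            fraction_high = mean(dat$high), params = params, mode = mode,
            seed = seed,
            class = c("ime_cell_population", class(dat)))
}

#' Fraction of high-expressing cells
#'
#' @param population An `ime_cell_population`.
#' @return Proportion of cells above the copy-number threshold (NA for an
#'   empty population).
#' @export
fraction_high <- function(population) {
  stopifnot(inherits(population, "ime_cell_population"))
  attr(population, "fraction_high")
}
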
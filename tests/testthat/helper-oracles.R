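# Independent oracles used across tests. These deliberately avoid the
# package's own solution paths: closed forms are written out, fixed points
# are found by brute-force bisection on the self-consistency map, and
# Poisson tails are summed term by term.

default_p <- function(...) circuit_params(...)

# Ip(t) of the unrepressed cascade with unit rates (default parameters)
cascade_ip <- function(t) 1 - (1 + t) * exp(-t)
cascade_im <- function(t) 1 - exp(-t)

# brute-force bisection on g(Ip) = Ip - C * s/(s + k3 * I1(Ip)) with the
# wildtype I1; independent of the package's quadratic solution
bisect_fixed_point <- function(r, k1 = 5, k2 = 0.05, k3 = 10, C = 1,
                               s = 1, lo = 1e-12, hi = NULL, iters = 200) {
  if (is.null(hi)) hi <- C
  I1_of <- function(Ip) {
    I2 <- max(Ip - k2, 0)
    if (r > 0 || I2 > 0) r / (r + k1 * I2) else 0
  }
  g <- function(Ip) Ip - C * s / (s + k3 * I1_of(Ip))
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (g(lo) * g(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# term-by-term Poisson upper tail P(X > k)
pois_tail_gt <- function(k, lambda) {
  terms <- vapply(0:k, function(j) exp(-lambda + j * log(lambda) -
                                         lgamma(j + 1)), 1)
  1 - sum(terms)
}

traj_at <- function(tr, times) {
  idx <- match(times, round(tr$time, 9))
  stopifnot(!anyNA(idx))
  tr[idx, ]
}
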
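# Independent oracles used across the suite.  These deliberately share no
# code with the package: the enumeration oracle walks isotope-count
# compositions with dmultinom, and the dosing oracle integrates the
# one-compartment ODE numerically with deSolve.

# abundance table restated independently (same literature values)
oracleAbundances <- list(
  H = c(0.999885, 0.000115),
  C = c(0.9893, 0.0107),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  F = 1,
  S = c(0.9499, 0.0075, 0.0425, 0, 0.0001),
  P = 1
)

# all compositions of n into m parts (counts per isotope)
oracleCompositions <- function(n, m) {
  if (m == 1L) return(matrix(n, 1L, 1L))
  out <- list()
  for (first in 0:n) {
    rest <- oracleCompositions(n - first, m - 1L)
    out[[length(out) + 1L]] <- cbind(first, rest)
  }
  do.call(rbind, out)
}

# exhaustive mass-shift distribution of n atoms of one element
oracleElement <- function(n, probs) {
  m <- length(probs)
  maxShift <- n * (m - 1L)
  out <- numeric(maxShift + 1L)
  comps <- oracleCompositions(n, m)
  for (i in seq_len(nrow(comps))) {
    cnt <- comps[i, ]
    shift <- sum(cnt * (seq_len(m) - 1L))
    out[shift + 1L] <- out[shift + 1L] + dmultinom(cnt, prob = probs)
  }
  out
}

# full outer combination of per-element shift distributions
oracleCombine <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a))
    out[i + seq_along(b) - 1L] <- out[i + seq_along(b) - 1L] + a[i] * b
  out
}

# exhaustive natural-abundance distribution of a formula given as a named
# count vector; returns fractions M0..Mk
oracleNatural <- function(counts, K) {
  dist <- 1
  for (el in names(counts)) {
    if (counts[[el]] == 0) next
    dist <- oracleCombine(dist, oracleElement(counts[[el]],
                                              oracleAbundances[[el]]))
  }
  out <- numeric(K + 1L)
  n <- min(length(dist), K + 1L)
  out[seq_len(n)] <- dist[seq_len(n)]
  out
}

# exhaustive labeled distribution: nSites hydrogens carry deuterium with
# probability (natural 2H + exch * p); the rest of the molecule is natural
oracleLabeled <- function(counts, nSites, exch, p, K) {
  q <- oracleAbundances$H[2] + exch * p
  sites <- oracleElement(nSites, c(1 - q, q))
  rest <- counts
  rest[["H"]] <- rest[["H"]] - nSites
  restDist <- 1
  for (el in names(rest)) {
    if (rest[[el]] == 0) next
    restDist <- oracleCombine(restDist, oracleElement(rest[[el]],
                                                      oracleAbundances[[el]]))
  }
  dist <- oracleCombine(sites, restDist)
  out <- numeric(K + 1L)
  n <- min(length(dist), K + 1L)
  out[seq_len(n)] <- dist[seq_len(n)]
  out
}

# numerical ODE solution of the one-compartment impulse-dose model
oracleBodyWater <- function(events, volumeL, rate, times) {
  stopifnot(requireNamespace("deSolve", quietly = TRUE))
  eventData <- data.frame(var = "p", time = events$day,
                          value = events$volumeML * events$purity /
                            (volumeL * 1000),
                          method = "add")
  allTimes <- sort(unique(c(times, events$day)))
  sol <- deSolve::ode(
    y = c(p = 0),
    times = allTimes,
    func = function(t, y, parms) list(-rate * y),
    parms = NULL,
    events = list(data = eventData),
    rtol = 1e-10, atol = 1e-12)
  approx(sol[, "time"], sol[, "p"], xout = times)$y
}

# deterministic small fixture: a three-subject tape-strip table written to
# a temporary cohort directory
makeCohortDir <- function(bundle) {
  dir <- tempfile("cohort")
  writeCohort(bundle, dir)
  dir
}
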
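# fixtures are built in code; nothing is read from disk.

# closed-form Bateman solution for an irreversible chain
# A1 -> A2 -> ... -> An -> ground with P_{A1}(0) = 1 and distinct rates.
bateman_chain <- function(k, times) {
  n <- length(k)
  P <- matrix(0, n, length(times))
  for (i in seq_len(n)) {
    pref <- if (i > 1) prod(k[seq_len(i - 1)]) else 1
    for (j in seq_len(i)) {
      denom <- prod(k[setdiff(seq_len(i), j)] - k[j])
      P[i, ] <- P[i, ] + pref * exp(-k[j] * times) / ifelse(i == 1, 1, denom)
    }
  }
  P
}

chain_scheme <- function(k, states = NULL) {
  n <- length(k)
  if (is.null(states)) states <- paste0("S", seq_len(n))
  rates <- data.frame(from = states,
                      to = c(states[-1], "ground"),
                      k = k, stringsAsFactors = FALSE)
  kinetic_scheme(c(states, "ground"), rates,
                 initial = stats::setNames(1, states[1]))
}

# random irreversible chain with rates spanning several decades
random_chain <- function(n = 4, span = c(-1, 5)) {
  k <- sort(10^stats::runif(n, span[1], span[2]), decreasing = TRUE)
  # enforce pairwise separation so eigen systems stay well-conditioned
  while (any(k[-n] / k[-1] < 3)) k <- sort(10^stats::runif(n, span[1], span[2]),
                                           decreasing = TRUE)
  chain_scheme(k)
}

# small dataset built directly from an explicit exponential model
exp_dataset <- function(amps, rates, times, offset = 0, axis = NULL) {
  n_ch <- nrow(amps)
  if (is.null(axis)) axis <- seq(1000, by = 10, length.out = n_ch)
  E <- exp(-outer(times, rates))
  V <- t(E %*% t(amps)) + offset
  spectral_dataset(axis, times, V)
}

tiny_model <- function() {
  sch <- chain_scheme(c(1000, 10), states = c("A", "B"))
  photocycle_model(sch, list(
    A = list(band(1500, 20, -1), band(1600, 20, 0.5)),
    B = list(band(1500, 20, -1), band(1650, 20, 0.8))))
}
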
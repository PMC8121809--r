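#' First-order kinetic scheme (photocycle graph)
#'
#' A closed photocycle: a set of states including `"ground"`, first-order
#' rate constants on directed edges, the population distribution directly
#' after the flash (at \eqn{t = 0^+}), and per-state conducting flags.
#' Every non-ground state must be reachable from the initially populated
#' states and must drain to ground.
#'
#' @param states character vector of state names; must include `"ground"`.
#' @param rates data frame (or 3-column matrix/list) with columns
#'   `from`, `to`, `k` (first-order rate constants in s\eqn{^{-1}}, > 0).
#' @param initial named numeric vector of post-flash population fractions
#'   summing to 1; omitted states default to 0.
#' @param conducting named logical vector; omitted states default to
#'   `FALSE`.
#' @return An object of class `kinetic_scheme`.
#' @examples
#' s <- kinetic_scheme(c("A", "ground"),
#'                     data.frame(from = "A", to = "ground", k = 1),
#'                     initial = c(A = 1))
#' apparent_rates(s)
#' @export
kinetic_scheme <- function(states, rates, initial, conducting = NULL) {
  states <- as.character(states)
  if (!"ground" %in% states) stop("scheme must contain a 'ground' state")
  if (anyDuplicated(states)) stop("duplicate state names")
  rates <- as.data.frame(rates, stringsAsFactors = FALSE)
  names(rates) <- c("from", "to", "k")
  rates$from <- as.character(rates$from); rates$to <- as.character(rates$to)
  rates$k <- as.numeric(rates$k)
  if (nrow(rates) == 0L) stop("scheme needs at least one rate")
  bad <- !(rates$from %in% states) | !(rates$to %in% states)
  if (any(bad)) stop("rate references unknown state: ",
                     paste(unique(c(rates$from[bad], rates$to[bad])), collapse = ", "))
  if (any(rates$from == rates$to)) stop("self-edges are not allowed")
  if (any(rates$from == "ground")) stop("ground is absorbing; no rates may leave it")
  if (any(!is.finite(rates$k) | rates$k <= 0)) stop("all rate constants must be > 0")
  key <- paste(rates$from, rates$to)
  if (anyDuplicated(key)) stop("duplicate edge: ", key[duplicated(key)][1])

  init <- stats::setNames(numeric(length(states)), states)
  init[names(initial)] <- as.numeric(initial)
  if (any(!names(initial) %in% states)) stop("initial references unknown state")
  if (any(init < 0)) stop("initial fractions must be >= 0")
  if (abs(sum(init) - 1) > 1e-8) stop("initial fractions must sum to 1")

  cond <- stats::setNames(logical(length(states)), states)
  if (!is.null(conducting)) {
    if (any(!names(conducting) %in% states)) stop("conducting references unknown state")
    cond[names(conducting)] <- as.logical(conducting)
  }

  # reachability: forward from initial support; backward from ground
  adj <- split(rates$to, factor(rates$from, levels = states))
  radj <- split(rates$from, factor(rates$to, levels = states))
  bfs <- function(start, nb) {
    seen <- stats::setNames(logical(length(states)), states)
    queue <- start
    while (length(queue)) {
      s <- queue[[1]]; queue <- queue[-1]
      if (seen[s]) next
      seen[s] <- TRUE
      queue <- c(queue, nb[[s]])
    }
    seen
  }
  fwd <- bfs(names(init)[init > 0], adj)
  bwd <- bfs("ground", radj)
  non_ground <- setdiff(states, "ground")
  unreach <- non_ground[!fwd[non_ground]]
  if (length(unreach))
    stop("state(s) not reachable from the initial population: ",
         paste(unreach, collapse = ", "))
  nodrain <- non_ground[!bwd[non_ground]]
  if (length(nodrain))
    stop("state(s) do not drain to ground (open cycle): ",
         paste(nodrain, collapse = ", "))

  structure(list(states = states, rates = rates, initial = init,
                 conducting = cond),
            class = "kinetic_scheme")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat(sprintf("<kinetic_scheme> %d states: %s\n", length(x$states),
              paste(x$states, collapse = " ")))
  for (i in seq_len(nrow(x$rates)))
    cat(sprintf("  %s -> %s  k = %.6g /s  (t1/2 = %.4g s)\n",
                x$rates$from[i], x$rates$to[i], x$rates$k[i],
                log(2) / x$rates$k[i]))
  cond <- names(x$conducting)[x$conducting]
  cat("  conducting:", if (length(cond)) paste(cond, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Rate matrix of a kinetic scheme
#'
#' Builds the generator matrix \eqn{Q} of the mass-action first-order
#' system \eqn{dP/dt = Q P}: `Q[j, i] = k(i -> j)` for \eqn{i \ne j} and
#' `Q[i, i] = -sum_j k(i -> j)`. Columns sum to zero (population
#' conservation); off-diagonal entries are non-negative.
#'
#' @param scheme a [kinetic_scheme()].
#' @return A list with elements `states` and the square matrix `Q`
#'   (dimnames = states), of class `rate_matrix`.
#' @export
rate_matrix <- function(scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  n <- length(scheme$states)
  Q <- matrix(0, n, n, dimnames = list(scheme$states, scheme$states))
  for (i in seq_len(nrow(scheme$rates))) {
    f <- scheme$rates$from[i]; t <- scheme$rates$to[i]; k <- scheme$rates$k[i]
    Q[t, f] <- Q[t, f] + k
    Q[f, f] <- Q[f, f] - k
  }
  structure(list(states = scheme$states, Q = Q), class = "rate_matrix")
}

# eigendecomposition of Q with a guarded fallback; rates span ~7 decades so
# direct stiff integration is avoided entirely.
.decompose_Q <- function(Q) {
  ev <- eigen(Q)
  V <- ev$vectors
  ok <- is.finite(rcond(V)) && rcond(V) > 1e-12
  list(values = ev$values, vectors = V, diagonalizable = ok)
}

#' State populations over time
#'
#' Solves \eqn{P(t) = \exp(Q t) P(0)} by eigendecomposition when \eqn{Q}
#' is diagonalizable, otherwise by scaling-and-squaring matrix exponential
#' ([Matrix::expm()]). Each column sums to 1 and all entries lie in
#' \eqn{[0, 1]} up to round-off.
#'
#' @param scheme a [kinetic_scheme()].
#' @param times positive times in seconds.
#' @return Matrix, states x times, with state dimnames.
#' @export
populations <- function(scheme, times) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  times <- as.numeric(times)
  if (any(times <= 0)) stop("times must be > 0")
  Q <- rate_matrix(scheme)$Q
  P0 <- scheme$initial[scheme$states]
  dec <- .decompose_Q(Q)
  if (dec$diagonalizable) {
    coef <- solve(dec$vectors, P0)
    E <- exp(outer(dec$values, times))          # states x times
    P <- Re(dec$vectors %*% (E * coef))
  } else {
    P <- vapply(times, function(t)
      as.numeric(Matrix::expm(Matrix::Matrix(Q * t)) %*% P0),
      numeric(length(P0)))
  }
  P <- pmin(pmax(P, 0), 1)
  dim(P) <- c(length(P0), length(times))
  rownames(P) <- scheme$states
  P
}

#' Apparent (observable) decay rates of a scheme
#'
#' The negated non-zero eigenvalues of the rate matrix, sorted
#' descending. These are the exponential rates a multi-exponential global
#' fit of data generated under the scheme can recover; for an
#' irreversible chain they equal the individual step rate constants.
#' Near-degenerate rates (relative gap < 1e-9) are reported with a
#' `"multiplicity"` attribute.
#'
#' @param scheme a [kinetic_scheme()].
#' @return Numeric vector of positive rates in s\eqn{^{-1}}, sorted
#'   descending, with attributes `multiplicity` (integer per rate) and
#'   `degenerate` (logical scalar).
#' @export
apparent_rates <- function(scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  Q <- rate_matrix(scheme)$Q
  ev <- eigen(Q, only.values = TRUE)$values
  scale <- max(abs(ev))
  if (any(abs(Im(ev)) > 1e-8 * (abs(Re(ev)) + scale * 1e-10)))
    stop("scheme has complex eigenvalues (oscillatory network); ",
         "out of the multi-exponential model class")
  ev <- Re(ev)
  nonzero <- abs(ev) > 1e-12 * scale
  k <- sort(-ev[nonzero], decreasing = TRUE)
  mult <- rep(1L, length(k))
  if (length(k) > 1L) {
    grp <- cumsum(c(TRUE, abs(diff(k)) > 1e-9 * k[-length(k)]))
    tab <- table(grp)
    mult <- as.integer(tab[as.character(grp)])
  }
  attr(k, "multiplicity") <- mult
  attr(k, "degenerate") <- any(mult > 1L)
  k
}

#' Half-life / time-constant / rate conversions
#'
#' First-order conversions \eqn{t_{1/2} = \tau \ln 2 = \ln 2 / k}. All
#' three are mutually inverse.
#'
#' @param tau time constant in seconds (> 0).
#' @param k rate constant in s\eqn{^{-1}} (> 0).
#' @param h half-life in seconds (> 0).
#' @return A positive numeric value (seconds or s\eqn{^{-1}}).
#' @export
halflife_from_tau <- function(tau) {
  if (any(tau <= 0)) stop("tau must be > 0")
  tau * log(2)
}

#' @rdname halflife_from_tau
#' @export
halflife_from_rate <- function(k) {
  if (any(k <= 0)) stop("k must be > 0")
  log(2) / k
}

#' @rdname halflife_from_tau
#' @export
rate_from_halflife <- function(h) {
  if (any(h <= 0)) stop("half-life must be > 0")
  log(2) / h
}

# -- scheme (de)serialisation -------------------------------------------------

#' Read / write a kinetic scheme as JSON
#'
#' JSON keys: `states`, `rates` (array of `[from, to, k]`), `initial`,
#' `conducting`.
#'
#' @param path file path.
#' @param scheme a [kinetic_scheme()].
#' @return `read_kinetic_scheme` returns a [kinetic_scheme()];
#'   `write_kinetic_scheme` invisibly returns `path`.
#' @export
read_kinetic_scheme <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  rates <- as.data.frame(j$rates, stringsAsFactors = FALSE)
  names(rates) <- c("from", "to", "k")
  rates$k <- as.numeric(rates$k)
  kinetic_scheme(j$states, rates,
                 initial = unlist(j$initial),
                 conducting = if (!is.null(j$conducting)) unlist(j$conducting))
}

#' @rdname read_kinetic_scheme
#' @export
write_kinetic_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  j <- list(states = scheme$states,
            rates = lapply(seq_len(nrow(scheme$rates)), function(i)
              list(scheme$rates$from[i], scheme$rates$to[i], scheme$rates$k[i])),
            initial = as.list(scheme$initial[scheme$initial > 0]),
            conducting = as.list(scheme$conducting))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
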
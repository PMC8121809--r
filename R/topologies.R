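#' Candidate L-state topologies of the anion-channelrhodopsin photocycle
#'
#' The two-step channel opening implies three distinct L states (a
#' non-conducting L1/L1' ahead of the conducting L2), but the data alone
#' do not fix how they are wired. The catalogue returns parameterised
#' scheme templates covering the candidate wirings:
#'
#' * `branched` (T-a): parallel branches K -> L1 -> L2 and K -> L1' -> L2
#'   with branching fraction `phi` toward the fast branch;
#' * `branched_exchange` (T-b): as T-a plus a slow symmetric L1 <-> L1'
#'   exchange with one rate `k_exch`;
#' * `sequential` (T-c): K -> L1 -> L1' -> L2 with L1' already
#'   conducting;
#' * `single_open_state`: the earlier single-L description
#'   K -> L -> M -> N/O, kept as an under-parameterised baseline.
#'
#' All templates continue L2 -> M (with an optional reverse M -> L2 edge
#' at a fixed ratio `r_rev` of the forward rate, reflecting the
#' reversible L2/M reaction behind the two-step observed channel
#' closing), then M -> N/O -> ground, with N/O lumped into one state.
#'
#' @param r_rev fixed ratio of the M -> L2 back rate to the L2 -> M
#'   forward rate; `0` omits the reverse edge.
#' @return Named list of `topology_template` objects. Each has fields
#'   `name`, `description`, `params` (named defaults), `param_types`
#'   (`"rate"` or `"fraction"`, used by fitting code to transform), and
#'   `build(params)` returning a [kinetic_scheme()].
#' @export
l_topology_catalogue <- function(r_rev = 0.3) {
  tmpl <- function(name, description, params, param_types, build) {
    structure(list(name = name, description = description, params = params,
                   param_types = param_types, build = build),
              class = "topology_template")
  }
  # default rate scale: ln2 / {450 ns, 18 us, 1.9 ms, 35 ms, 107 ms, 4.4 s}
  k6 <- log(2) / c(450e-9, 18e-6, 1.9e-3, 35e-3, 107e-3, 4.4)

  closing <- function(k_L2M, k_M, k_NO, from = "L2") {
    r <- rbind(data.frame(from = from, to = "M", k = k_L2M),
               data.frame(from = "M", to = "NO", k = k_M),
               data.frame(from = "NO", to = "ground", k = k_NO))
    if (r_rev > 0)
      r <- rbind(r, data.frame(from = "M", to = from, k = r_rev * k_L2M))
    r
  }
  prune_build <- function(states, rates, initial, conducting) {
    rates <- rates[rates$k > 0, , drop = FALSE]
    # drop states that lost all incoming edges and carry no initial mass
    repeat {
      keep <- states == "ground" |
        states %in% rates$to |
        states %in% names(initial)[unlist(initial) > 0]
      if (all(keep)) break
      drop <- states[!keep]
      states <- states[keep]
      rates <- rates[!(rates$from %in% drop) & !(rates$to %in% drop), , drop = FALSE]
    }
    kinetic_scheme(states, rates, initial,
                   conducting[names(conducting) %in% states])
  }

  out <- list(
    branched = tmpl(
      "branched",
      "parallel K->L1->L2 and K->L1'->L2 with branching fraction phi",
      params = c(k_K = k6[1], phi = 0.7, k_L1 = k6[2], k_L1p = k6[3],
                 k_L2M = k6[4], k_M = k6[5], k_NO = k6[6]),
      param_types = c(k_K = "rate", phi = "fraction", k_L1 = "rate",
                      k_L1p = "rate", k_L2M = "rate", k_M = "rate",
                      k_NO = "rate"),
      build = function(p) {
        rates <- rbind(
          data.frame(from = "K", to = "L1",  k = p[["k_K"]] * p[["phi"]]),
          data.frame(from = "K", to = "L1p", k = p[["k_K"]] * (1 - p[["phi"]])),
          data.frame(from = "L1",  to = "L2", k = p[["k_L1"]]),
          data.frame(from = "L1p", to = "L2", k = p[["k_L1p"]]),
          closing(p[["k_L2M"]], p[["k_M"]], p[["k_NO"]]))
        prune_build(c("K", "L1", "L1p", "L2", "M", "NO", "ground"), rates,
                    c(K = 1), c(L2 = TRUE))
      }),
    branched_exchange = tmpl(
      "branched_exchange",
      "as 'branched' plus slow symmetric L1 <-> L1' exchange",
      params = c(k_K = k6[1], phi = 0.7, k_L1 = k6[2], k_L1p = k6[3],
                 k_exch = k6[3] / 10, k_L2M = k6[4], k_M = k6[5],
                 k_NO = k6[6]),
      param_types = c(k_K = "rate", phi = "fraction", k_L1 = "rate",
                      k_L1p = "rate", k_exch = "rate", k_L2M = "rate",
                      k_M = "rate", k_NO = "rate"),
      build = function(p) {
        rates <- rbind(
          data.frame(from = "K", to = "L1",  k = p[["k_K"]] * p[["phi"]]),
          data.frame(from = "K", to = "L1p", k = p[["k_K"]] * (1 - p[["phi"]])),
          data.frame(from = "L1",  to = "L1p", k = p[["k_exch"]]),
          data.frame(from = "L1p", to = "L1",  k = p[["k_exch"]]),
          data.frame(from = "L1",  to = "L2", k = p[["k_L1"]]),
          data.frame(from = "L1p", to = "L2", k = p[["k_L1p"]]),
          closing(p[["k_L2M"]], p[["k_M"]], p[["k_NO"]]))
        prune_build(c("K", "L1", "L1p", "L2", "M", "NO", "ground"), rates,
                    c(K = 1), c(L2 = TRUE))
      }),
    sequential = tmpl(
      "sequential",
      "K -> L1 -> L1' -> L2 with L1' conducting",
      params = c(k_K = k6[1], k_L1 = k6[2], k_L1p = k6[3],
                 k_L2M = k6[4], k_M = k6[5], k_NO = k6[6]),
      param_types = c(k_K = "rate", k_L1 = "rate", k_L1p = "rate",
                      k_L2M = "rate", k_M = "rate", k_NO = "rate"),
      build = function(p) {
        rates <- rbind(
          data.frame(from = "K",   to = "L1",  k = p[["k_K"]]),
          data.frame(from = "L1",  to = "L1p", k = p[["k_L1"]]),
          data.frame(from = "L1p", to = "L2",  k = p[["k_L1p"]]),
          closing(p[["k_L2M"]], p[["k_M"]], p[["k_NO"]]))
        prune_build(c("K", "L1", "L1p", "L2", "M", "NO", "ground"), rates,
                    c(K = 1), c(L1p = TRUE, L2 = TRUE))
      }),
    single_open_state = tmpl(
      "single_open_state",
      "legacy single-L description: K -> L -> M -> N/O -> ground",
      params = c(k_K = k6[1], k_LM = k6[4], k_M = k6[5], k_NO = k6[6]),
      param_types = c(k_K = "rate", k_LM = "rate", k_M = "rate",
                      k_NO = "rate"),
      build = function(p) {
        rates <- rbind(
          data.frame(from = "K", to = "L", k = p[["k_K"]]),
          closing(p[["k_LM"]], p[["k_M"]], p[["k_NO"]], from = "L"))
        prune_build(c("K", "L", "M", "NO", "ground"), rates,
                    c(K = 1), c(L = TRUE))
      })
  )
  out
}

#' @export
print.topology_template <- function(x, ...) {
  cat(sprintf("<topology_template> %s: %s\n  params: %s\n", x$name,
              x$description, paste(names(x$params), collapse = ", ")))
  invisible(x)
}

#' Build a kinetic scheme from a topology template
#'
#' @param template a `topology_template` from [l_topology_catalogue()].
#' @param params named numeric vector overriding (a subset of) the
#'   template defaults.
#' @return A [kinetic_scheme()].
#' @export
build_topology <- function(template, params = NULL) {
  stopifnot(inherits(template, "topology_template"))
  p <- template$params
  if (!is.null(params)) {
    if (any(!names(params) %in% names(p)))
      stop("unknown parameter(s): ",
           paste(setdiff(names(params), names(p)), collapse = ", "))
    p[names(params)] <- params
  }
  template$build(p)
}
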
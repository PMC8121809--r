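#' Per-channel weights for the global fit
#'
#' The global-fit objective carries noise-dependent per-channel weighting
#' factors \eqn{w(\nu)}. Two estimators are provided: `"uniform"` sets
#' every weight to 1; `"inverse_noise"` sets \eqn{w = 1/\hat\sigma} with
#' \eqn{\hat\sigma} the standard deviation of second differences along
#' the time axis divided by \eqn{\sqrt 6} (a difference-filter noise
#' estimator that suppresses smooth kinetics), floored at the 5th
#' percentile of \eqn{\hat\sigma} across channels so no weight becomes
#' infinite.
#'
#' @param dataset a [spectral_dataset()].
#' @param method `"uniform"` or `"inverse_noise"`.
#' @return An object of class `weight_vector`: list with `values` (one
#'   non-negative weight per channel) and `method`.
#' @export
estimate_weights <- function(dataset, method = c("uniform", "inverse_noise")) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "spectral_dataset"))
  n_ch <- length(dataset$axis)
  if (method == "uniform") {
    w <- rep(1, n_ch)
  } else {
    if (length(dataset$times) < 3L)
      stop("inverse_noise weighting needs at least 3 time points")
    sig <- apply(dataset$values, 1L, function(x) stats::sd(diff(x, differences = 2)) / sqrt(6))
    if (any(sig == 0))
      warning("constant channel(s) with zero noise estimate; floored")
    floor_ <- stats::quantile(sig, 0.05, names = FALSE)
    if (floor_ <= 0) {
      pos <- sig[sig > 0]
      floor_ <- if (length(pos)) min(pos) else 1
      warning("5th-percentile noise floor is zero; using smallest positive estimate")
    }
    w <- 1 / pmax(sig, floor_)
  }
  structure(list(values = w, method = method), class = "weight_vector")
}

.resolve_weights <- function(weights, dataset) {
  if (inherits(weights, "weight_vector")) {
    if (length(weights$values) != length(dataset$axis))
      stop("weight vector length does not match the number of channels")
    return(weights)
  }
  if (is.character(weights)) return(estimate_weights(dataset, weights))
  if (is.numeric(weights)) {
    if (length(weights) != length(dataset$axis))
      stop("weight vector length does not match the number of channels")
    if (any(weights < 0)) stop("weights must be >= 0")
    if (all(weights == 0)) stop("weights must not all be zero")
    return(structure(list(values = as.numeric(weights), method = "user"),
                     class = "weight_vector"))
  }
  stop("weights must be a method name, a numeric vector, or a weight_vector")
}

# design matrix of the exponential model: one column per rate plus an
# optional constant column for the offset a_inf.
.exp_design <- function(rates, times, with_offset) {
  E <- exp(-outer(times, rates))
  if (with_offset) E <- cbind(E, 1)
  E
}

.check_rates_distinct <- function(rates) {
  if (any(rates <= 0)) stop("rates must be positive")
  if (length(rates) > 1L) {
    s <- sort(rates)
    gap <- diff(s) / s[-length(s)]
    if (any(gap < 1e-9)) {
      i <- which.min(gap)
      stop(sprintf("rates %.6g and %.6g are numerically indistinct", s[i], s[i + 1]))
    }
  }
}

#' Exact linear sub-problem of the global fit
#'
#' For fixed rate constants, the amplitude spectra and offsets that
#' minimise the weighted objective are ordinary least-squares solutions
#' channel by channel (the weight is constant along time within a
#' channel, so it cancels from each channel's normal equations; it still
#' enters the aggregated objective).
#'
#' @param dataset a [spectral_dataset()].
#' @param rates positive, pairwise distinct rate constants in
#'   s\eqn{^{-1}}.
#' @param weights ignored by the per-channel solution (see above);
#'   accepted for interface symmetry.
#' @param with_offset fit a constant offset \eqn{a_\infty(\nu)} per
#'   channel.
#' @return List with `amplitude_spectra` (matrix, one row per rate, one
#'   column per channel) and `offset` (vector per channel, or `NULL`).
#' @export
solve_amplitudes <- function(dataset, rates, weights = NULL, with_offset = TRUE) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  .check_rates_distinct(rates)
  E <- .exp_design(rates, dataset$times, with_offset)
  qrE <- qr(E)
  if (qrE$rank < ncol(E)) {
    cors <- stats::cor(E)
    diag(cors) <- 0
    ij <- which(abs(cors) == max(abs(cors)), arr.ind = TRUE)[1, ]
    lbl <- function(j) if (j > length(rates)) "offset" else sprintf("k = %.4g", rates[j])
    stop(sprintf("rank-deficient design on this time grid: %s vs %s",
                 lbl(ij[1]), lbl(ij[2])))
  }
  C <- qr.coef(qrE, t(dataset$values))        # (N [+1]) x channels
  N <- length(rates)
  list(amplitude_spectra = C[seq_len(N), , drop = FALSE],
       offset = if (with_offset) C[N + 1L, ] else NULL)
}

#' The weighted squared-error objective
#'
#' \deqn{F = \sum_n \sum_m w(\nu_n)^2 \left(\Delta E(\nu_n, t_m) -
#'   a_\infty(\nu_n) - \sum_i a_i(\nu_n) e^{-k_i t_m}\right)^2}
#'
#' @param dataset a [spectral_dataset()].
#' @param rates positive rate constants.
#' @param amplitude_spectra matrix, one row per rate, one column per
#'   channel.
#' @param offset per-channel offset vector, or `NULL` for none.
#' @param weights a `weight_vector`, numeric vector, or method name.
#' @return The scalar objective value (0 iff the model reproduces the
#'   data exactly on every channel with non-zero weight).
#' @export
objective_F <- function(dataset, rates, amplitude_spectra, offset = NULL,
                        weights = "uniform") {
  stopifnot(inherits(dataset, "spectral_dataset"))
  w <- .resolve_weights(weights, dataset)$values
  N <- length(rates)
  if (nrow(amplitude_spectra) != N || ncol(amplitude_spectra) != length(dataset$axis))
    stop("amplitude_spectra must be n_rates x n_channels")
  if (!is.null(offset) && length(offset) != length(dataset$axis))
    stop("offset must have one value per channel")
  E <- .exp_design(rates, dataset$times, with_offset = !is.null(offset))
  C <- if (is.null(offset)) amplitude_spectra else rbind(amplitude_spectra, offset)
  R <- dataset$values - t(E %*% C)
  sum(w^2 * rowSums(R^2))
}

# greedy sequential initialisation: starting from the best single rate on
# a log grid, add one component at a time (trying every grid position not
# already occupied) and polish after each addition. Far more reliable than
# random starts when components span many decades and differ in amplitude.
.greedy_start <- function(dataset, n_exp, w2, with_offset, lo, hi, slo, shi,
                          grid_n = 36L) {
  grid <- seq(slo, shi, length.out = grid_n)
  theta <- numeric(0)
  for (j in seq_len(n_exp)) {
    fbest <- Inf; add <- NA_real_
    for (g in grid) {
      if (length(theta) && min(abs(theta - g)) < 0.2) next
      f <- .varpro_objective(sort(c(theta, g)), dataset, w2, with_offset)
      if (f < fbest) { fbest <- f; add <- g }
    }
    theta <- sort(c(theta, add))
    opt <- tryCatch(
      stats::nlminb(theta, .varpro_objective, lower = lo, upper = hi,
                    dataset = dataset, w2 = w2, with_offset = with_offset,
                    control = list(rel.tol = 1e-9, iter.max = 200L,
                                   eval.max = 800L)),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$objective) && opt$objective < 1e29)
      theta <- sort(opt$par)
  }
  theta
}

# projected objective: exact inner linear solve, returns weighted RSS.
.varpro_objective <- function(theta, dataset, w2, with_offset) {
  k <- 10^theta
  E <- .exp_design(k, dataset$times, with_offset)
  qrE <- qr(E)
  if (qrE$rank < ncol(E)) return(1e30 * (1 + sum(theta^2)))
  R <- qr.resid(qrE, t(dataset$values))       # times x channels
  f <- sum(w2 * colSums(R^2))
  if (!is.finite(f)) return(1e30)
  f
}

#' Global multi-exponential fit of a time-resolved dataset
#'
#' Fits the shared-rate multi-exponential model
#' \eqn{\Delta E(\nu, t) = a_\infty(\nu) + \sum_{i=1}^N a_i(\nu)
#' e^{-k_i t}} to all channels simultaneously by minimising the weighted
#' squared-error objective (see [objective_F()]). The problem is
#' separable, so it is solved by variable projection: an outer bounded
#' quasi-Newton search over \eqn{\log_{10} k_i} with the thousands of
#' linear amplitudes eliminated exactly by per-channel least squares at
#' every step. A minimiser of the projected problem is a minimiser of
#' the full objective. Multi-start (log-spaced, jittered, seeded)
#' guards against local minima.
#'
#' @param dataset a [spectral_dataset()].
#' @param n_exp number of exponentials \eqn{N \ge 1}; the dataset must
#'   have at least \eqn{2N + 1} time points.
#' @param weights weighting method name (`"uniform"`,
#'   `"inverse_noise"`), numeric per-channel vector, or
#'   [estimate_weights()] result.
#' @param n_starts number of multi-start rate tuples.
#' @param seed integer seed for the start jitter (private RNG stream).
#' @param rate_bounds length-2 vector of rate bounds in s\eqn{^{-1}};
#'   default `c(1/(10 t_max), 10/t_min)`.
#' @param tol relative convergence tolerance of the outer optimiser.
#' @param with_offset fit the per-channel offset \eqn{a_\infty}
#'   (default), or pin it to zero (a closed photocycle implies
#'   \eqn{a_\infty \approx 0}).
#' @return An object of class `global_fit`: rates (sorted descending),
#'   time constants, half-lives, amplitude spectra, offsets, weights,
#'   the minimised objective `F`, residual matrix, convergence flag and
#'   identifiability notes. Rate pairs closer than a factor 3 are
#'   recorded in `$notes` (the physical resolution limit of exponential
#'   analysis) — a warning attached to the result, not an error.
#' @seealso [select_order()], [amplitude_spectra_to_species()]
#' @examples
#' mod <- default_gtacr1_model()
#' d <- simulate_dataset(mod, axis = seq(1500, 1720, 4),
#'                       times = default_times(60))
#' \donttest{
#' fit <- fit_global(d, n_exp = 6, n_starts = 6, seed = 1)
#' coef(fit)
#' }
#' @export
fit_global <- function(dataset, n_exp, weights = "uniform", n_starts = 20,
                       seed = 1, rate_bounds = NULL, tol = 1e-10,
                       with_offset = TRUE) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  n_exp <- as.integer(n_exp)
  if (n_exp < 1L) stop("n_exp must be >= 1")
  tt <- dataset$times
  if (length(tt) < 2L * n_exp + 1L)
    stop(sprintf("need at least %d time points for N = %d", 2L * n_exp + 1L, n_exp))
  wv <- .resolve_weights(weights, dataset)
  w2 <- wv$values^2
  if (is.null(rate_bounds)) rate_bounds <- c(1 / (10 * max(tt)), 10 / min(tt))
  lo <- log10(rate_bounds[1]); hi <- log10(rate_bounds[2])
  # data-informed span for start placement
  slo <- log10(1 / max(tt)); shi <- log10(1 / min(tt))
  base <- seq(slo, shi, length.out = n_exp + 2L)[2:(n_exp + 1L)]
  greedy <- .greedy_start(dataset, n_exp, w2, with_offset, lo, hi, slo, shi)
  starts <- .with_seed(seed, {
    s <- list(greedy, base)
    while (length(s) < n_starts) {
      cand <- if (length(s) %% 2L == 0L)
        sort(stats::runif(n_exp, slo, shi))
      else
        sort(base + stats::rnorm(n_exp, sd = 0.5))
      s[[length(s) + 1L]] <- pmin(pmax(cand, lo), hi)
    }
    s[seq_len(max(n_starts, 1L))]
  })
  best <- NULL
  n_fail <- 0L
  clean_best <- Inf          # best objective among cleanly converged starts
  ok_msgs <- "X-convergence|relative convergence|absolute function convergence"
  for (st in starts) {
    opt <- tryCatch(
      stats::nlminb(st, .varpro_objective, lower = lo, upper = hi,
                    dataset = dataset, w2 = w2, with_offset = with_offset,
                    control = list(rel.tol = min(tol, 1e-10), abs.tol = 0,
                                   iter.max = 500L, eval.max = 2000L)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective) || opt$objective >= 1e29) {
      n_fail <- n_fail + 1L
      next
    }
    if (opt$convergence == 0 ||
        (!is.null(opt$message) && grepl(ok_msgs, opt$message)))
      clean_best <- min(clean_best, opt$objective)
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best))
    stop("no start converged: N = ", n_exp,
         " is too large for the time support (rank deficiency at every start)")
  k <- sort(10^best$par, decreasing = TRUE)
  lin <- solve_amplitudes(dataset, k, with_offset = with_offset)
  E <- .exp_design(k, tt, with_offset)
  C <- if (with_offset) rbind(lin$amplitude_spectra, lin$offset) else lin$amplitude_spectra
  fitted_vals <- t(E %*% C)
  resid <- dataset$values - fitted_vals
  Fval <- sum(w2 * rowSums(resid^2))
  notes <- character(0)
  if (n_exp > 1L) {
    ratio <- k[-length(k)] / k[-1]
    close_pairs <- which(ratio < 3)
    for (i in close_pairs)
      notes <- c(notes, sprintf(
        "rates %.4g and %.4g /s differ by less than a factor 3; they may not be independently identifiable",
        k[i], k[i + 1]))
    if (any(ratio < 1 + 1e-9))
      notes <- c(notes, "tied rates detected")
  }
  # the winning start counts as converged when it stopped cleanly, or when a
  # cleanly stopped start reached the same objective within tolerance (nlminb
  # reports "false convergence" when started at an already-polished optimum)
  data_scale <- sum(w2 * rowSums(dataset$values^2))
  converged <- best$convergence == 0 ||
    (!is.null(best$message) && grepl(ok_msgs, best$message)) ||
    (clean_best - best$objective) <=
      1e-8 * max(abs(best$objective), 1e-12 * data_scale)
  structure(list(
    rates = k, taus = 1 / k, halflives = log(2) / k,
    amplitude_spectra = lin$amplitude_spectra,
    offset = lin$offset,
    weights = wv, F = Fval, residuals = resid, fitted = fitted_vals,
    n_exponentials = n_exp, converged = converged,
    n_starts = n_starts, n_failed_starts = n_fail, seed = seed,
    with_offset = with_offset, notes = notes,
    axis = dataset$axis, times = tt, axis_unit = dataset$axis_unit,
    modality = dataset$modality, call = match.call()),
    class = "global_fit")
}

#' @export
print.global_fit <- function(x, ...) {
  cat(sprintf("Global multi-exponential fit: N = %d, %d channels x %d times\n",
              x$n_exponentials, length(x$axis), length(x$times)))
  cat(sprintf("  objective F = %.6g   converged: %s   (%d starts, weights: %s)\n",
              x$F, x$converged, x$n_starts, x$weights$method))
  tab <- data.frame(rate = x$rates, tau = x$taus, halflife = x$halflives)
  tab <- tab[order(tab$halflife), ]
  rownames(tab) <- paste0("T", seq_len(nrow(tab)))
  print(format(tab[, c("rate", "halflife")], digits = 4))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' @export
summary.global_fit <- function(object, ...) {
  x <- object
  amp_norm <- sqrt(rowSums(x$amplitude_spectra^2))
  s <- list(fit = x,
            amplitude_norms = amp_norm,
            rms_residual = sqrt(mean(x$residuals^2)),
            offset_range = if (is.null(x$offset)) NULL else range(x$offset))
  class(s) <- "summary.global_fit"
  s
}

#' @export
print.summary.global_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  rms residual: %.4g\n", x$rms_residual))
  ord <- order(x$fit$halflives)
  cat("  amplitude-spectrum norms (fastest first):",
      paste(sprintf("%.3g", x$amplitude_norms[ord]), collapse = ", "), "\n")
  if (!is.null(x$offset_range))
    cat(sprintf("  offset range: [%.3g, %.3g]\n",
                x$offset_range[1], x$offset_range[2]))
  invisible(x)
}

#' @export
coef.global_fit <- function(object, type = c("rates", "halflives", "taus"), ...) {
  type <- match.arg(type)
  v <- object[[type]]
  names(v) <- paste0(if (type == "rates") "k" else "T", seq_along(v))
  v
}

#' @export
fitted.global_fit <- function(object, ...) object$fitted

#' @export
residuals.global_fit <- function(object, ...) object$residuals

#' Model prediction at arbitrary times
#'
#' @param object a `global_fit`.
#' @param times positive times in seconds; defaults to the fitted grid.
#' @param ... unused.
#' @return Matrix, channels x times.
#' @export
predict.global_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) return(object$fitted)
  if (any(times <= 0)) stop("times must be > 0")
  E <- .exp_design(object$rates, as.numeric(times), object$with_offset)
  C <- if (object$with_offset) rbind(object$amplitude_spectra, object$offset)
       else object$amplitude_spectra
  t(E %*% C)
}

#' Simulate datasets from a fitted model
#'
#' Draws parametric-bootstrap replicates: the fitted surface plus
#' Gaussian noise at the per-channel residual standard deviation.
#'
#' @param object a `global_fit`.
#' @param nsim number of replicates.
#' @param seed integer seed (private RNG stream).
#' @param ... unused.
#' @return List of [spectral_dataset()] objects of length `nsim`.
#' @export
simulate.global_fit <- function(object, nsim = 1, seed = 1, ...) {
  sig <- apply(object$residuals, 1L, stats::sd)
  .with_seed(seed, lapply(seq_len(nsim), function(i) {
    noise <- matrix(stats::rnorm(length(object$fitted)),
                    nrow(object$fitted), ncol(object$fitted)) * sig
    spectral_dataset(object$axis, object$times, object$fitted + noise,
                     modality = object$modality, segment = "simulated",
                     axis_unit = object$axis_unit)
  }))
}

#' Plot a global fit
#'
#' Top panel: amplitude spectra (one per resolved transition, fastest
#' first). Bottom panel: data (points) and model (lines) for a few
#' selected channels on a logarithmic time axis.
#'
#' @param x a `global_fit`.
#' @param channels channel positions for the trace panel; defaults to
#'   the channels with the largest amplitude-spectrum magnitude.
#' @param ... unused.
#' @export
plot.global_fit <- function(x, channels = NULL, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  A <- x$amplitude_spectra[order(x$halflives), , drop = FALSE]
  cols <- grDevices::hcl.colors(nrow(A), "Dark 3")
  graphics::matplot(x$axis, t(A), type = "l", lty = 1, col = cols,
                    xlab = x$axis_unit, ylab = "amplitude",
                    main = "amplitude spectra")
  graphics::legend("topleft", bty = "n", lty = 1, col = cols, cex = 0.7,
                   legend = sprintf("t1/2 = %.3g s", sort(x$halflives)))
  if (is.null(channels)) {
    sel <- utils::head(order(-colSums(A^2)), 4L)
  } else {
    sel <- vapply(channels, function(ch) which.min(abs(x$axis - ch)), integer(1))
  }
  obs <- x$fitted + x$residuals
  graphics::matplot(x$times, t(obs[sel, , drop = FALSE]), log = "x", pch = 1,
                    cex = 0.4, col = seq_along(sel), xlab = "time (s)",
                    ylab = "dE", main = "selected channels")
  graphics::matlines(x$times, t(x$fitted[sel, , drop = FALSE]),
                     lty = 1, col = seq_along(sel))
  invisible(x)
}

#' Choose the number of exponentials by information criterion
#'
#' Fits \eqn{N = 1, \dots, n_{max}} and scores each fit by BIC computed
#' from the weighted residual sum, counting the shared rates plus every
#' per-channel amplitude (and offset) as parameters.
#'
#' @param dataset a [spectral_dataset()].
#' @param n_max largest model order to try.
#' @param criterion `"bic"`.
#' @param weights as in [fit_global()].
#' @param n_starts,seed multi-start options passed to [fit_global()].
#' @param ... further options passed to [fit_global()].
#' @return List with `chosen` (the argmin N), `table` (data frame of N,
#'   F, parameter count, BIC), and `fits` (the fitted objects).
#' @export
select_order <- function(dataset, n_max, criterion = "bic",
                         weights = "uniform", n_starts = 8, seed = 1, ...) {
  if (!identical(criterion, "bic")) stop("unsupported criterion: ", criterion)
  stopifnot(n_max >= 1)
  n_obs <- length(dataset$axis) * length(dataset$times)
  fits <- vector("list", n_max)
  rows <- vector("list", n_max)
  for (N in seq_len(n_max)) {
    f <- fit_global(dataset, N, weights = weights, n_starts = n_starts,
                    seed = seed, ...)
    n_ch <- length(dataset$axis)
    p <- N + n_ch * (N + as.integer(f$with_offset))
    bic <- n_obs * log(max(f$F, 1e-300) / n_obs) + p * log(n_obs)
    fits[[N]] <- f
    rows[[N]] <- data.frame(n_exp = N, F = f$F, n_par = p, bic = bic,
                            converged = f$converged)
  }
  tab <- do.call(rbind, rows)
  list(chosen = tab$n_exp[which.min(tab$bic)], table = tab, fits = fits)
}
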
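test_that("uniform weights are all ones; user vectors are validated", {
  d <- exp_dataset(matrix(1:6 / 6, 3, 2), c(100, 1), 10^seq(-4, 1, length.out = 12))
  w <- estimate_weights(d, "uniform")
  expect_equal(w$values, rep(1, 3))
  expect_error(photokin:::.resolve_weights(rep(0, 3), d), "zero")
  expect_error(photokin:::.resolve_weights(c(1, 1), d), "length")
})

test_that("inverse-noise weights recover known per-channel noise ratios", {
  set.seed(314)
  n_t <- 200
  times <- 10^seq(-5, 1, length.out = n_t)
  sig <- c(rep(0.01, 5), rep(0.02, 5))
  V <- matrix(rnorm(10 * n_t), 10, n_t) * sig
  d <- spectral_dataset(seq(1500, 1590, 10), times, V)
  w <- estimate_weights(d, "inverse_noise")
  ratio <- mean(w$values[1:5]) / mean(w$values[6:10])
  expect_equal(ratio, 2, tolerance = 0.1)
  # estimator consistency on a pure-noise channel at 500 points
  x <- rnorm(500) * 0.037
  sig_hat <- sd(diff(x, differences = 2)) / sqrt(6)
  expect_equal(sig_hat, 0.037, tolerance = 0.1)
  # constant channel triggers the floor warning
  V2 <- rbind(V, 0)
  d2 <- spectral_dataset(seq(1500, 1600, 10), times, V2)
  expect_warning(estimate_weights(d2, "inverse_noise"), "floor|constant")
})

test_that("solve_amplitudes is exact on data inside the model class", {
  times <- 10^seq(-3, 1, length.out = 25)
  d <- exp_dataset(matrix(2, 1, 1), 5, times, offset = 0.1)
  out <- solve_amplitudes(d, 5, with_offset = TRUE)
  expect_equal(as.numeric(out$amplitude_spectra), 2, tolerance = 1e-10)
  expect_equal(as.numeric(out$offset), 0.1, tolerance = 1e-10)
})

test_that("solve_amplitudes equals the dense normal-equations solution", {
  set.seed(77)
  for (i in 1:25) {
    n_r <- sample(2:5, 1); n_ch <- sample(2:8, 1); n_t <- sample(20:50, 1)
    rates <- sort(10^runif(n_r, -1, 3), decreasing = TRUE)
    if (any(rates[-n_r] / rates[-1] < 3)) next
    times <- sort(10^runif(n_t, -4, 1))
    E <- cbind(exp(-outer(times, rates)), 1)
    if (kappa(E) > 1e6) next
    V <- matrix(rnorm(n_ch * n_t), n_ch, n_t)
    d <- spectral_dataset(seq_len(n_ch), times, V)
    sol <- solve_amplitudes(d, rates, with_offset = TRUE)
    C <- solve(crossprod(E), crossprod(E, t(V)))     # brute-force oracle
    expect_equal(unname(rbind(sol$amplitude_spectra, sol$offset)), unname(C),
                 tolerance = 1e-8)
  }
})

test_that("offset-free and offset fits agree on mean-free data", {
  times <- 10^seq(-3, 2, length.out = 40)
  rates <- c(50, 0.8)
  amps <- matrix(c(1, -0.6, 0.3, 0.2), 2, 2)
  d <- exp_dataset(amps, rates, times)
  a1 <- solve_amplitudes(d, rates, with_offset = FALSE)$amplitude_spectra
  a2 <- solve_amplitudes(d, rates, with_offset = TRUE)$amplitude_spectra
  expect_equal(a1, a2, tolerance = 1e-8)
})

test_that("near-coincident rates are rejected with the offending pair named", {
  d <- exp_dataset(matrix(1, 1, 2), c(10, 1), 10^seq(-3, 1, length.out = 15))
  expect_error(solve_amplitudes(d, c(5, 5 * (1 + 1e-12))), "indistinct")
})

test_that("objective_F is the printed double sum", {
  set.seed(13)
  n_ch <- 7; n_t <- 9
  times <- sort(10^runif(n_t, -4, 0))
  rates <- c(300, 20, 0.5)
  A <- matrix(rnorm(3 * n_ch), 3, n_ch)
  off <- rnorm(n_ch)
  w <- runif(n_ch, 0.5, 2)
  V <- matrix(rnorm(n_ch * n_t), n_ch, n_t)
  d <- spectral_dataset(seq_len(n_ch), times, V)
  Fv <- objective_F(d, rates, A, off, w)
  # independent brute-force two-nested-loop summation
  Fb <- 0
  for (n in seq_len(n_ch)) for (m in seq_len(n_t)) {
    model <- off[n] + sum(A[, n] * exp(-rates * times[m]))
    Fb <- Fb + w[n]^2 * (V[n, m] - model)^2
  }
  expect_equal(Fv, Fb, tolerance = 1e-10 * Fb)
  # perfect model gives zero
  Vp <- t(cbind(exp(-outer(times, rates)), 1) %*% rbind(A, off))
  dp <- spectral_dataset(seq_len(n_ch), times, Vp)
  expect_equal(objective_F(dp, rates, A, off, w), 0, tolerance = 1e-12)
  # doubling all weights quadruples F
  expect_equal(objective_F(d, rates, A, off, 2 * w), 4 * Fv, tolerance = 1e-10)
})

test_that("a noiseless single exponential is recovered to high precision", {
  times <- 10^seq(-4, 0, length.out = 25)
  d <- exp_dataset(matrix(c(1, -0.5), 2, 1), 37, times, offset = 0.05)
  fit <- fit_global(d, 1, n_starts = 4, seed = 1)
  expect_equal(fit$rates, 37, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_lt(fit$F, 1e-12)
  # F must equal the objective recomputed from the stored components
  expect_equal(fit$F,
               objective_F(d, fit$rates, fit$amplitude_spectra, fit$offset,
                           fit$weights),
               tolerance = 1e-10 + 1e-10 * max(fit$F, 1))
})

test_that("axis storage order does not change the fitted rates", {
  times <- 10^seq(-4, 1, length.out = 30)
  amps <- matrix(c(1, -0.4, 0.2, 0.9, -0.3, 0.5), 3, 2)
  rates <- c(200, 2)
  d_asc <- exp_dataset(amps, rates, times, axis = c(1000, 1010, 1020))
  V <- d_asc$values
  d_desc <- spectral_dataset(c(1020, 1010, 1000), times, V[3:1, ])
  f1 <- fit_global(d_asc, 2, n_starts = 4, seed = 2)
  f2 <- fit_global(d_desc, 2, n_starts = 4, seed = 2)
  expect_equal(f1$rates, f2$rates, tolerance = 1e-10)
})

test_that("zero weight on a channel reproduces the fit with the channel deleted", {
  set.seed(55)
  times <- 10^seq(-4, 1, length.out = 30)
  amps <- matrix(rnorm(8), 4, 2)
  d <- exp_dataset(amps, c(150, 1.5), times)
  d$values <- d$values + 0.002 * matrix(rnorm(length(d$values)), nrow(d$values))
  w <- c(0, 1, 1, 1)
  f_w <- fit_global(d, 2, weights = w, n_starts = 4, seed = 3)
  d_del <- spectral_dataset(d$axis[-1], times, d$values[-1, ])
  f_d <- fit_global(d_del, 2, n_starts = 4, seed = 3)
  expect_equal(f_w$rates, f_d$rates, tolerance = 1e-7)
})

test_that("close rate pairs are flagged in the result notes, not as errors", {
  times <- 10^seq(-3, 1, length.out = 40)
  d <- exp_dataset(matrix(c(1, 0.8, -0.5, 0.6), 2, 2), c(20, 10), times)
  fit <- fit_global(d, 2, n_starts = 6, seed = 4)
  expect_true(length(fit$notes) >= 1)
  expect_match(fit$notes[1], "factor 3")
})

test_that("an over-sized model on too few time points errors", {
  d <- exp_dataset(matrix(1, 1, 1), 5, 10^seq(-2, 0, length.out = 6))
  expect_error(fit_global(d, 3), "time points")
})

test_that("predict/fitted/residuals/coef/simulate methods are coherent", {
  times <- 10^seq(-4, 0, length.out = 25)
  d <- exp_dataset(matrix(c(1, -0.5), 2, 1), 37, times, offset = 0.05)
  fit <- fit_global(d, 1, n_starts = 3, seed = 1)
  expect_equal(fitted(fit) + residuals(fit), d$values, tolerance = 1e-12)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(dim(predict(fit, times = c(0.01, 0.1))), c(2L, 2L))
  expect_named(coef(fit), "k1")
  expect_equal(unname(coef(fit, "halflives")), log(2) / unname(coef(fit)),
               tolerance = 1e-12)
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "spectral_dataset")
  expect_output(print(summary(fit)), "Global multi-exponential fit")
  grDevices::pdf(NULL)
  expect_no_error(plot(fit))
  grDevices::dev.off()
})

test_that("select_order picks the generating order and F is non-increasing in N", {
  set.seed(66)
  times <- 10^seq(-4, 1, length.out = 40)
  amps <- matrix(c(1, -0.7, 0.5, 0.8, 0.6, -0.9), 3, 2)
  d <- exp_dataset(amps, c(500, 2), times)
  d$values <- d$values + 0.005 * matrix(rnorm(length(d$values)), nrow(d$values))
  sel <- select_order(d, 4, n_starts = 4, seed = 5)
  expect_equal(sel$chosen, 2)
  expect_true(all(diff(sel$table$F) <= 1e-9 * sel$table$F[-nrow(sel$table)] +
                    1e-12))
  # pure noise: the most parsimonious order wins
  dn <- spectral_dataset(d$axis, times,
                         0.01 * matrix(rnorm(3 * length(times)), 3))
  seln <- select_order(dn, 3, n_starts = 4, seed = 6)
  expect_equal(seln$chosen, 1)
})
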
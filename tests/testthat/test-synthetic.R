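test_that("band profiles have the declared shape", {
  g <- band(1529, 8, -1)
  expect_equal(band_profile(g, 1529), -1)
  expect_equal(band_profile(g, c(1525, 1533)), c(-0.5, -0.5), tolerance = 1e-12)
  l <- band(1650, 10, 0.4, shape = "lorentzian")
  expect_equal(band_profile(l, 1650), 0.4)
  expect_equal(band_profile(l, c(1645, 1655)), c(0.2, 0.2), tolerance = 1e-12)
  # gaussian area by quadrature
  q <- integrate(function(x) band_profile(band(0, 8, 0.7), x), -200, 200,
                 rel.tol = 1e-10)$value
  expect_equal(q, 0.7 * 8 * sqrt(pi / (4 * log(2))), tolerance = 1e-8)
})

test_that("species spectra superpose bands linearly", {
  axis <- seq(1100, 1800, 2)
  expect_equal(species_difference_spectrum(list(), axis)$values,
               rep(0, length(axis)))
  b1 <- band(1200, 10, 1); b2 <- band(1700, 10, -0.5)
  s <- species_difference_spectrum(list(b1, b2), axis)
  expect_equal(s$values, band_profile(b1, axis) + band_profile(b2, axis))
})

test_that("an overlapping +/- carbonyl pair gives a dispersive feature with an interior zero crossing", {
  pair <- list(band(1708, 8, -0.25), band(1716, 8, 0.25))
  f <- function(x) {
    v <- 0
    for (b in pair) v <- v + band_profile(b, x)
    v
  }
  root <- uniroot(f, c(1708, 1716), tol = 1e-12)$root
  expect_gt(root, 1708); expect_lt(root, 1716)
  expect_lt(f(1708), 0); expect_gt(f(1716), 0)
})

test_that("the default model reproduces the transition table by construction", {
  m <- default_gtacr1_model()
  expect_s3_class(m, "photocycle_model")
  hl <- sort(log(2) / as.numeric(apparent_rates(m$scheme)), decreasing = FALSE)
  expect_equal(sort(hl), sort(gtacr1_reference_transitions("FTIR")$halflife),
               tolerance = 1e-9)
  # the irreversible variant has the same apparent rates
  mi <- default_gtacr1_model(reversible = FALSE)
  expect_equal(sort(as.numeric(apparent_rates(mi$scheme))),
               sort(as.numeric(apparent_rates(m$scheme))), tolerance = 1e-9)
})

test_that("marker-band structure of the default species spectra matches the assignments", {
  m <- default_gtacr1_model()
  axis <- default_ftir_axis()
  sp <- lapply(m$species_spectra, species_difference_spectrum, axis = axis)
  at <- function(s, x) s$values[which.min(abs(s$axis - x))]
  expect_gt(at(sp$L2, 1691), 0.2)            # conducting-state marker in L2
  expect_lt(abs(at(sp$M, 1691)), 0.05)       # and not in M
  expect_gt(at(sp$L2, 1184), 0.3)            # protonated 13-cis marker
  expect_lt(abs(at(sp$M, 1184)), 0.05)       # decays upon M formation
  expect_lt(at(sp$L2, 1708), -0.1)           # carbonyl pair in L2
  expect_gt(at(sp$L2, 1716), 0.1)
  expect_lt(abs(at(sp$L1, 1716)), 0.05)      # +1716 absent before L2
  # no syn-cycle marker band anywhere
  for (s in sp) expect_lt(abs(at(s, 1154)), 0.02)
  # N/O is spectrally weak
  expect_lt(max(abs(sp$NO$values)), 0.15)
  # K and L1 differ (the 450 ns transition is spectrally visible)
  expect_gt(max(abs(sp$K$values - sp$L1$values)), 0.2)
})

test_that("simulation is deterministic under a seed and exact when noiseless", {
  m <- tiny_model()
  axis <- seq(1450, 1700, 5)
  times <- 10^seq(-4, 1, length.out = 30)
  d1 <- simulate_dataset(m, axis, times, noise_sigma = 0.01, seed = 42)
  d2 <- simulate_dataset(m, axis, times, noise_sigma = 0.01, seed = 42)
  expect_identical(d1$values, d2$values)
  d3 <- simulate_dataset(m, axis, times, noise_sigma = 0.01, seed = 43)
  expect_false(identical(d3$values, d1$values))
  expect_error(simulate_dataset(m, axis, times, noise_sigma = 0.01), "seed")
  # noiseless single time point equals the explicit per-state superposition
  t0 <- 0.05
  d0 <- simulate_dataset(m, axis, t0)
  P <- populations(m$scheme, t0)
  manual <- numeric(length(axis))
  for (s in names(m$species_spectra))
    manual <- manual +
      P[s, 1] * species_difference_spectrum(m$species_spectra[[s]], axis)$values
  expect_equal(d0$values[, 1], manual, tolerance = 1e-12)
  # closed cycle: signal vanishes at long times (slowest rate 10/s, t = 50/k)
  dl <- simulate_dataset(m, axis, 5)
  expect_lt(max(abs(dl$values)), 1e-9)
})

test_that("the forward model is linear in the species spectra", {
  sch <- chain_scheme(c(100, 5), states = c("A", "B"))
  axis <- seq(1500, 1600, 10)
  times <- c(1e-3, 1e-2, 1e-1, 1)
  mA <- photocycle_model(sch, list(A = list(band(1520, 15, 1)), B = list()))
  mB <- photocycle_model(sch, list(A = list(), B = list(band(1580, 15, -0.5))))
  mAB <- photocycle_model(sch, list(A = list(band(1520, 15, 1)),
                                    B = list(band(1580, 15, -0.5))))
  expect_equal(simulate_dataset(mAB, axis, times)$values,
               simulate_dataset(mA, axis, times)$values +
                 simulate_dataset(mB, axis, times)$values,
               tolerance = 1e-12)
})

test_that("noise statistics follow the requested sigma, including per-channel vectors", {
  m <- tiny_model()
  axis <- seq(1480, 1680, 10)
  times <- 10^seq(-4, 1, length.out = 20)
  base <- simulate_dataset(m, axis, times)
  sig_vec <- seq(0.01, 0.05, length.out = length(axis))
  d <- simulate_dataset(m, axis, times, noise_sigma = sig_vec, seed = 8)
  resid <- d$values - base$values
  # pool draws across repeated seeds for a tight check
  for (s in 9:28) {
    dd <- simulate_dataset(m, axis, times, noise_sigma = sig_vec, seed = s)
    resid <- cbind(resid, dd$values - base$values)
  }
  est <- apply(resid, 1, sd)                 # 420 draws per channel
  expect_equal(est, sig_vec, tolerance = 0.12)
  expect_lt(max(abs(est - sig_vec) / sig_vec), 0.20)
})

test_that("every noiseless channel lies inside the multi-exponential model class", {
  m <- default_gtacr1_model()
  times <- default_times(60)
  axis <- seq(1150, 1750, 25)
  d <- simulate_dataset(m, axis, times)
  k <- as.numeric(apparent_rates(m$scheme))
  fitted <- solve_amplitudes(d, k, with_offset = TRUE)
  E <- cbind(exp(-outer(times, k)), 1)
  R <- d$values - t(E %*% rbind(fitted$amplitude_spectra, fitted$offset))
  expect_lt(max(abs(R)), 1e-10)
})

test_that("UV/VIS simulation mirrors the FTIR generator on an nm axis", {
  mu <- default_gtacr1_uvvis_model()
  expect_equal(sort(log(2) / as.numeric(apparent_rates(mu$scheme))),
               sort(gtacr1_reference_transitions("UVVIS")$halflife),
               tolerance = 1e-9)
  d1 <- simulate_uvvis(mu, noise_sigma = 0.005, seed = 3,
                       times = default_times(40))
  d2 <- simulate_uvvis(mu, noise_sigma = 0.005, seed = 3,
                       times = default_times(40))
  expect_identical(d1$values, d2$values)
  expect_identical(d1$modality, "UVVIS")
  expect_error(simulate_uvvis(default_gtacr1_model()), "nm")
  # a noiseless trace is a sum of <= 6 exponentials
  d0 <- simulate_uvvis(mu, times = default_times(50))
  k <- as.numeric(apparent_rates(mu$scheme))
  fitted <- solve_amplitudes(d0, k, with_offset = FALSE)
  E <- exp(-outer(d0$times, k))
  R <- d0$values - t(E %*% fitted$amplitude_spectra)
  expect_lt(max(abs(R)), 1e-10)
})

test_that("band shifting moves only the targeted centres", {
  m <- default_gtacr1_model()
  m2 <- shift_bands(m, centers = 1184, delta = -14)
  cents <- function(mod) sort(unique(unlist(
    lapply(mod$species_spectra, function(b) vapply(b, `[[`, 0, "center")))))
  expect_true(1170 %in% cents(m2))
  expect_false(1184 %in% cents(m2))
  expect_true(all(setdiff(cents(m), 1184) %in% cents(m2)))
})

test_that("photocycle models roundtrip through JSON", {
  m <- default_gtacr1_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_photocycle_model(m, path)
  m2 <- read_photocycle_model(path)
  expect_equal(m2$scheme$rates$k, m$scheme$rates$k, tolerance = 1e-12)
  expect_equal(names(m2$species_spectra), names(m$species_spectra))
  axis <- default_ftir_axis()
  for (s in names(m$species_spectra))
    expect_equal(species_difference_spectrum(m2$species_spectra[[s]], axis)$values,
                 species_difference_spectrum(m$species_spectra[[s]], axis)$values,
                 tolerance = 1e-12)
})
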
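#' Spectral band
#'
#' A single positive (photoproduct) or negative (educt bleach) band of a
#' difference spectrum.
#'
#' @param center band centre (cm\eqn{^{-1}} or nm).
#' @param fwhm full width at half maximum, same unit as the axis, > 0.
#' @param amplitude signed peak height in absorbance-difference units.
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @return An object of class `band`.
#' @export
band <- function(center, fwhm, amplitude, shape = c("gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  if (fwhm <= 0) stop("fwhm must be > 0")
  structure(list(center = center, fwhm = fwhm, amplitude = amplitude,
                 shape = shape), class = "band")
}

#' Evaluate a band profile on an axis
#'
#' Gaussian: \eqn{A \exp(-4 \ln 2 (x - c)^2 / w^2)}; Lorentzian:
#' \eqn{A (w/2)^2 / ((x - c)^2 + (w/2)^2)}. Either way the peak value at
#' the centre equals the amplitude.
#'
#' @param band a [band()].
#' @param axis numeric channel positions.
#' @return Numeric vector of the same length as `axis`.
#' @export
band_profile <- function(band, axis) {
  stopifnot(inherits(band, "band"))
  dx <- axis - band$center
  switch(band$shape,
    gaussian   = band$amplitude * exp(-4 * log(2) * dx^2 / band$fwhm^2),
    lorentzian = band$amplitude * (band$fwhm / 2)^2 / (dx^2 + (band$fwhm / 2)^2))
}

#' Compose a species difference spectrum from bands
#'
#' Point-wise sum of the band profiles; linear in the band list. An
#' empty list gives the zero spectrum (a spectrally silent state).
#'
#' @param bands list of [band()] objects (possibly empty).
#' @param axis numeric channel positions.
#' @param label spectrum label.
#' @return A [spectrum()].
#' @export
species_difference_spectrum <- function(bands, axis, label = "") {
  v <- numeric(length(axis))
  for (b in bands) v <- v + band_profile(b, axis)
  spectrum(axis, v, label = label)
}

#' Photocycle model: scheme plus per-state difference spectra
#'
#' The forward-generator ground truth: a [kinetic_scheme()] together
#' with a band-composed intermediate-minus-ground difference spectrum
#' for every non-ground state (an empty band list marks a spectrally
#' silent state).
#'
#' @param scheme a [kinetic_scheme()].
#' @param species_spectra named list, one entry per non-ground state,
#'   each a list of [band()] objects.
#' @param axis_unit `"cm-1"` or `"nm"`.
#' @return An object of class `photocycle_model`.
#' @export
photocycle_model <- function(scheme, species_spectra,
                             axis_unit = c("cm-1", "nm")) {
  axis_unit <- match.arg(axis_unit)
  stopifnot(inherits(scheme, "kinetic_scheme"))
  non_ground <- setdiff(scheme$states, "ground")
  missing <- setdiff(non_ground, names(species_spectra))
  if (length(missing))
    stop("missing species spectra for state(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(species_spectra), non_ground)
  if (length(extra))
    stop("species spectra for unknown state(s): ", paste(extra, collapse = ", "))
  for (s in names(species_spectra))
    for (b in species_spectra[[s]])
      if (!inherits(b, "band")) stop("species_spectra must contain band objects")
  structure(list(scheme = scheme, species_spectra = species_spectra,
                 axis_unit = axis_unit),
            class = "photocycle_model")
}

#' @export
print.photocycle_model <- function(x, ...) {
  cat(sprintf("<photocycle_model> %d states, axis unit %s\n",
              length(x$scheme$states), x$axis_unit))
  for (s in names(x$species_spectra)) {
    bb <- x$species_spectra[[s]]
    desc <- if (length(bb) == 0) "silent" else
      paste(vapply(bb, function(b)
        sprintf("%+.2g@%g", b$amplitude, b$center), character(1)),
        collapse = " ")
    cat(sprintf("  %-4s %s\n", s, desc))
  }
  invisible(x)
}

# solve the L2 <-> M -> N/O block so that the two block eigenvalues equal
# the target observable rates l4 > l5 at a fixed back/forward ratio r:
#   kf (1+r) + km = l4 + l5,  kf km = l4 l5
.calibrate_closing <- function(l4, l5, r) {
  S <- l4 + l5; P <- l4 * l5
  disc <- S^2 - 4 * (1 + r) * P
  if (disc < 0)
    stop("closing rates not calibratable: eigenvalue targets too close for r = ", r)
  kf <- (S + sqrt(disc)) / (2 * (1 + r))
  list(k_L2M = kf, k_M = P / kf)
}

#' Default anion-channelrhodopsin (GtACR1-like) FTIR photocycle model
#'
#' A branched-topology scheme whose six apparent rates are, by
#' construction, \eqn{\ln 2 / t_{1/2}} for the half-lives 450 ns, 18 us,
#' 1.9 ms, 35 ms, 107 ms and 4.4 s, combined with band-composed species
#' spectra on a 1100-1798 cm\eqn{^{-1}} axis implementing the marker-band
#' assignments: the protonated 13-cis retinal band at +1184 in all
#' protonated-Schiff-base states (K, L1, L1', L2) and absent in M; the
#' ground-state retinal C=C bleach at -1529 in every intermediate; the
#' amide-I channel-opening band at -1644 and the conducting-state marker
#' at +1691 in L2 only; the protonated-glutamate carbonyl bleach at
#' -1708 from L1 onward (the residue deprotonates with the
#' sub-microsecond K decay) with the +1716 counterpart appearing from L2
#' (reprotonation in a changed hydrogen-bond environment); a red-shifted
#' ethylenic photoproduct at +1515 distinguishing K; and a spectrally
#' weak N/O state (amplitudes scaled by 0.1). No state carries a band at
#' 1154 cm\eqn{^{-1}} (the 13-cis,C=N-syn marker): the syn photocycle is
#' deliberately absent.
#'
#' @param reversible include the M -> L2 reverse edge (ratio `r_rev` of
#'   the forward rate; the closing block is then calibrated so the
#'   apparent rates still equal the target values). `FALSE` yields the
#'   irreversible variant whose step rates equal the target rates
#'   directly, as needed for species-spectrum reconstruction.
#' @param phi branching fraction toward the fast-opening branch.
#' @param r_rev back/forward ratio of the reversible L2/M reaction.
#' @param halflives the six target half-lives in seconds, fastest first.
#' @return A [photocycle_model()].
#' @export
default_gtacr1_model <- function(reversible = TRUE, phi = 0.7, r_rev = 0.3,
                                 halflives = c(450e-9, 18e-6, 1.9e-3,
                                               35e-3, 107e-3, 4.4)) {
  stopifnot(length(halflives) == 6, all(halflives > 0), phi > 0, phi <= 1)
  k <- log(2) / halflives
  cal <- if (reversible) .calibrate_closing(k[4], k[5], r_rev)
         else list(k_L2M = k[4], k_M = k[5])
  cat_r <- if (reversible) r_rev else 0
  tmpl <- l_topology_catalogue(r_rev = cat_r)$branched
  scheme <- build_topology(tmpl, c(k_K = k[1], phi = phi, k_L1 = k[2],
                                   k_L1p = k[3], k_L2M = cal$k_L2M,
                                   k_M = cal$k_M, k_NO = k[6]))
  g <- function(center, amplitude, fwhm = 8) band(center, fwhm, amplitude)
  retinal_1184 <- g(1184, 0.6)
  bleach_1529  <- g(1529, -1.0)
  glu_1708     <- g(1708, -0.25)
  glu_1716     <- g(1716, 0.25)
  amide_1644   <- g(1644, -0.5, fwhm = 12)
  open_1691    <- g(1691, 0.35, fwhm = 12)
  k_ethylenic  <- g(1515, 0.5)
  L1_bands <- list(retinal_1184, bleach_1529, glu_1708)
  spectra <- list(
    K   = list(retinal_1184, bleach_1529, k_ethylenic),
    L1  = L1_bands,
    L1p = L1_bands,
    L2  = list(retinal_1184, bleach_1529, amide_1644, open_1691,
               glu_1708, glu_1716),
    M   = list(bleach_1529, glu_1708, glu_1716),
    NO  = list(g(1529, -0.10), g(1708, -0.025))
  )
  if (identical(phi, 1)) spectra$L1p <- NULL  # branch pruned away
  spectra <- spectra[intersect(names(spectra), scheme$states)]
  photocycle_model(scheme, spectra, axis_unit = "cm-1")
}

#' Default UV/VIS variant of the photocycle model
#'
#' Same branched topology, calibrated to the UV/VIS half-lives 3 us,
#' 23 us, 2.3 ms, 23 ms, 200 ms and 3.5 s, with generic visible
#' difference bands (ground-state bleach near 515 nm, red-shifted K,
#' blue-shifted M-like product near 390 nm). The band positions are
#' declared placeholders: no measured absorption maxima are reproduced.
#'
#' @inheritParams default_gtacr1_model
#' @return A [photocycle_model()] with `axis_unit = "nm"`.
#' @export
default_gtacr1_uvvis_model <- function(reversible = TRUE, phi = 0.7,
                                       r_rev = 0.3,
                                       halflives = c(3e-6, 23e-6, 2.3e-3,
                                                     23e-3, 200e-3, 3.5)) {
  m <- default_gtacr1_model(reversible = reversible, phi = phi,
                            r_rev = r_rev, halflives = halflives)
  bleach <- band(515, 55, -1.0)
  spectra <- list(
    K   = list(bleach, band(545, 50, 0.7)),
    L1  = list(bleach, band(480, 50, 0.6)),
    L1p = list(bleach, band(480, 50, 0.6)),
    L2  = list(bleach, band(470, 50, 0.7)),
    M   = list(bleach, band(390, 45, 0.8)),
    NO  = list(band(515, 55, -0.15), band(535, 50, 0.1))
  )
  spectra <- spectra[intersect(names(spectra), m$scheme$states)]
  photocycle_model(m$scheme, spectra, axis_unit = "nm")
}

#' Default acquisition grids
#'
#' The FTIR emulation uses 350 channels from 1100 to 1798 cm\eqn{^{-1}}
#' at 2 cm\eqn{^{-1}} spacing and 120 log-spaced times from 100 ns to
#' 20 s (a merged step-scan/rapid-scan span).
#'
#' @param n_times number of log-spaced time points.
#' @return Numeric vector.
#' @export
default_ftir_axis <- function() seq(1100, 1798, by = 2)

#' @rdname default_ftir_axis
#' @export
default_times <- function(n_times = 120)
  10^seq(log10(1e-7), log10(20), length.out = n_times)

# run code with a private, fully seeded RNG stream; the global RNG state
# is untouched (no global random state leaks from the generator).
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Simulate a time-resolved difference-spectral dataset
#'
#' Forward model: \eqn{\Delta E(\nu, t) = \sum_s P_s(t)\, S_s(\nu)} plus
#' optional i.i.d. Gaussian noise. Because the populations of a
#' first-order network are sums of exponentials in the scheme's apparent
#' rates, every noiseless channel lies exactly inside the
#' multi-exponential global-fit model class.
#'
#' @param model a [photocycle_model()].
#' @param axis channel positions; default [default_ftir_axis()].
#' @param times positive times in seconds; default [default_times()].
#' @param noise_sigma Gaussian noise standard deviation in
#'   absorbance-difference units; either a scalar (homoscedastic) or a
#'   per-channel vector (heteroscedastic). `0` gives the exact noiseless
#'   forward model.
#' @param seed integer seed; required whenever `noise_sigma > 0`. The
#'   generator draws from a private RNG stream fully determined by it.
#' @param modality dataset modality tag.
#' @return A [spectral_dataset()].
#' @export
simulate_dataset <- function(model, axis = default_ftir_axis(),
                             times = default_times(), noise_sigma = 0,
                             seed = NULL, modality = "FTIR") {
  stopifnot(inherits(model, "photocycle_model"))
  if (any(noise_sigma < 0)) stop("noise_sigma must be >= 0")
  if (any(noise_sigma > 0) && is.null(seed))
    stop("seed is required when noise_sigma > 0")
  if (!(length(noise_sigma) %in% c(1L, length(axis))))
    stop("noise_sigma must be scalar or one value per channel")
  P <- populations(model$scheme, times)
  states <- names(model$species_spectra)
  S <- vapply(states, function(s)
    species_difference_spectrum(model$species_spectra[[s]], axis)$values,
    numeric(length(axis)))
  V <- S %*% P[states, , drop = FALSE]
  if (any(noise_sigma > 0)) {
    noise <- .with_seed(seed,
      matrix(stats::rnorm(length(V)), nrow(V), ncol(V)) * noise_sigma)
    V <- V + noise
  }
  spectral_dataset(axis, times, V, modality = modality,
                   segment = "simulated",
                   axis_unit = model$axis_unit)
}

#' @rdname simulate_dataset
#' @param wavelengths channel axis in nm for the UV/VIS variant.
#' @export
simulate_uvvis <- function(model, wavelengths = seq(330, 650, by = 2),
                           times = default_times(), noise_sigma = 0,
                           seed = NULL) {
  if (!identical(model$axis_unit, "nm"))
    stop("simulate_uvvis expects a model with nm-axis spectra")
  simulate_dataset(model, axis = wavelengths, times = times,
                   noise_sigma = noise_sigma, seed = seed,
                   modality = "UVVIS")
}

#' Shift selected bands of a photocycle model
#'
#' Applies a centre shift to every band of the model whose centre lies
#' within `window/2` of one of `centers` — a generic way to emulate
#' isotope-induced band shifts (e.g. a 14 cm\eqn{^{-1}} downshift of a
#' retinal skeletal stretching mode) without any isotope chemistry.
#'
#' @param model a [photocycle_model()].
#' @param centers band centres to shift.
#' @param delta signed shift to apply to matching band centres.
#' @param window matching tolerance around each centre.
#' @return A new [photocycle_model()].
#' @export
shift_bands <- function(model, centers, delta, window = 1) {
  stopifnot(inherits(model, "photocycle_model"))
  spectra <- lapply(model$species_spectra, function(bands)
    lapply(bands, function(b) {
      if (any(abs(b$center - centers) <= window / 2)) b$center <- b$center + delta
      b
    }))
  photocycle_model(model$scheme, spectra, axis_unit = model$axis_unit)
}

# -- model (de)serialisation --------------------------------------------------

#' Read / write a photocycle model as JSON
#'
#' The JSON carries a `scheme` section (states, rates, initial,
#' conducting) plus `species_spectra`: state -> array of
#' `[center, fwhm, amplitude, shape]`.
#'
#' @param model a [photocycle_model()].
#' @param path file path.
#' @return `read_photocycle_model` returns a [photocycle_model()];
#'   `write_photocycle_model` invisibly returns `path`.
#' @export
write_photocycle_model <- function(model, path) {
  stopifnot(inherits(model, "photocycle_model"))
  sc <- model$scheme
  j <- list(
    axis_unit = model$axis_unit,
    scheme = list(
      states = sc$states,
      rates = lapply(seq_len(nrow(sc$rates)), function(i)
        list(sc$rates$from[i], sc$rates$to[i], sc$rates$k[i])),
      initial = as.list(sc$initial[sc$initial > 0]),
      conducting = as.list(sc$conducting)),
    species_spectra = lapply(model$species_spectra, function(bands)
      lapply(bands, function(b) list(b$center, b$fwhm, b$amplitude, b$shape))))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_photocycle_model
#' @export
read_photocycle_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rates <- do.call(rbind, lapply(j$scheme$rates, function(r)
    data.frame(from = r[[1]], to = r[[2]], k = as.numeric(r[[3]]),
               stringsAsFactors = FALSE)))
  scheme <- kinetic_scheme(unlist(j$scheme$states), rates,
                           initial = unlist(j$scheme$initial),
                           conducting = unlist(j$scheme$conducting))
  spectra <- lapply(j$species_spectra, function(bands)
    lapply(bands, function(b)
      band(as.numeric(b[[1]]), as.numeric(b[[2]]), as.numeric(b[[3]]),
           shape = b[[4]])))
  photocycle_model(scheme, spectra, axis_unit = j$axis_unit)
}
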
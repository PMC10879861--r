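#' Gaussian band model for one component spectrum
#'
#' A component spectrum is a sum of Gaussian bands, each given by a centre
#' (cm^-1), a width (Gaussian sigma, cm^-1) and a nonnegative amplitude.
#' Band models stand in for measured pure-component spectra: they reproduce
#' the overlap structure of the C-H stretch window without digitising any
#' published curve.
#'
#' @param centers,widths,amplitudes Numeric vectors of equal length (>= 1).
#' @return An object of class `band_model` (a data.frame of bands).
#' @export
band_model <- function(centers, widths, amplitudes) {
  if (length(centers) < 1L || length(widths) != length(centers) ||
      length(amplitudes) != length(centers))
    stop("band_model: need equal-length centers, widths, amplitudes (>= 1 band)",
         call. = FALSE)
  if (any(widths <= 0)) stop("band_model: widths must be > 0", call. = FALSE)
  if (any(amplitudes < 0)) stop("band_model: amplitudes must be >= 0", call. = FALSE)
  structure(data.frame(center = centers, width = widths, amplitude = amplitudes),
            class = c("band_model", "data.frame"))
}

#' Evaluate a band model on a wavenumber axis
#'
#' @param model A [band_model()].
#' @param axis A [wn_axis()] or numeric vector of shifts.
#' @return Numeric intensity vector, one value per shift.
#' @export
eval_band_model <- function(model, axis) {
  x <- as.numeric(axis)
  y <- numeric(length(x))
  for (i in seq_len(nrow(model)))
    y <- y + model$amplitude[i] *
      exp(-(x - model$center[i])^2 / (2 * model$width[i]^2))
  y
}

#' Default C-H window band models for the five tissue components
#'
#' Band centres sit near canonical C-H stretch features: ~2850 cm^-1 CH2
#' symmetric, ~2880 cm^-1 CH2 asymmetric, ~2930 cm^-1 CH3 (protein), the
#' ~3009 cm^-1 =C-H band specific to unsaturated lipid, and a broad water
#' O-H shoulder rising past 3050 cm^-1. ECM is the cellular-protein model
#' with every centre blue-shifted by a small uniform amount, emulating the
#' collagen/fibril spectral blue shift that distinguishes the two in tissue.
#'
#' @param ecm_shift Uniform blue shift (cm^-1) applied to the protein bands
#'   to obtain the ECM model (default 8).
#' @return Named list of five [band_model()]s: `unsaturated_lipid`,
#'   `cellular_protein`, `ecm`, `saturated_lipid`, `water`.
#' @export
default_band_models <- function(ecm_shift = 8) {
  protein_centers <- c(2880, 2930, 2960)
  protein_widths <- c(18, 22, 16)
  protein_amps <- c(0.45, 1.0, 0.35)
  list(
    unsaturated_lipid = band_model(c(2850, 2885, 2930, 3009),
                                   c(14, 16, 20, 12),
                                   c(0.9, 0.5, 0.45, 0.55)),
    cellular_protein = band_model(protein_centers, protein_widths, protein_amps),
    ecm = band_model(protein_centers + ecm_shift, protein_widths, protein_amps),
    saturated_lipid = band_model(c(2850, 2880, 2930),
                                 c(13, 14, 18),
                                 c(1.0, 0.75, 0.25)),
    water = band_model(c(3120, 2950), c(80, 70), c(1.0, 0.12))
  )
}

#' Build the default five-component reference library
#'
#' Evaluates [default_band_models()] on the given axis and packs the result
#' into a unit-norm [ref_library()]. The five spectra overlap heavily (as in
#' the C-H window) but remain identifiable: pairwise cosine similarities lie
#' strictly inside (0, 0.99).
#'
#' @param axis A [wn_axis()] within 2800-3100 cm^-1 (e.g. 45 channels over
#'   2820-3030 cm^-1).
#' @return A [ref_library()] with K = 5 components.
#' @export
make_default_library <- function(axis) {
  if (!inherits(axis, "wn_axis")) axis <- wn_axis(axis)
  x <- as.numeric(axis)
  if (min(x) < 2800 || max(x) > 3100)
    stop("make_default_library: axis must lie within 2800-3100 cm^-1",
         call. = FALSE)
  models <- default_band_models()
  spectra <- t(vapply(models, eval_band_model, numeric(length(x)), axis = x))
  ref_library(spectra, axis, names = names(models))
}

#' Default wavenumber axis: 45 channels over 2820-3030 cm^-1
#' @return A [wn_axis()] of length 45.
#' @export
default_axis <- function() wn_axis(seq(2820, 3030, length.out = 45))

scene_primitive <- function(shape, component, level, ...) {
  shape <- match.arg(shape, c("background", "disk", "annulus", "fiber"))
  if (level < 0) stop("scene primitive: level must be >= 0", call. = FALSE)
  c(list(shape = shape, component = component, level = level), list(...))
}

#' Default tissue-phantom scene
#'
#' Spatial primitives in relative (0-1) coordinates, emulating breast-tissue
#' morphology: a duct (cellular-protein annulus) with a necrotic core
#' (saturated-lipid disk), adipocyte rings (unsaturated-lipid annuli), ECM
#' fibers (polylines), and a water background covering the whole field of
#' view (water coexists with everything, so truth maps need not sum to 1).
#' Every component dominates at least one region, as the balanced RFE
#' sampler requires.
#'
#' @return A list of scene primitives understood by [generate_phantom()].
#' @export
default_scene <- function() {
  list(
    scene_primitive("background", "water", 0.6),
    scene_primitive("disk", "saturated_lipid", 1.0,
                    center = c(0.33, 0.33), radius = 0.205),
    scene_primitive("annulus", "cellular_protein", 1.0,
                    center = c(0.33, 0.33), r_inner = 0.22, r_outer = 0.30),
    scene_primitive("annulus", "unsaturated_lipid", 1.0,
                    center = c(0.78, 0.20), r_inner = 0.09, r_outer = 0.17),
    scene_primitive("annulus", "unsaturated_lipid", 1.0,
                    center = c(0.80, 0.52), r_inner = 0.09, r_outer = 0.17),
    scene_primitive("fiber", "ecm", 1.0,
                    points = rbind(c(0.06, 0.72), c(0.95, 0.86)),
                    thickness = 0.04),
    scene_primitive("fiber", "ecm", 1.0,
                    points = rbind(c(0.06, 0.92), c(0.95, 0.60)),
                    thickness = 0.04)
  )
}

#' Phantom specification
#'
#' Everything needed to generate a synthetic hyperspectral cube with known
#' ground truth. Defaults describe the reference study conditions: a
#' 64 x 64 pixel scene on the 45-channel 2820-3030 cm^-1 axis, five
#' components, additive white Gaussian noise at 2% of the peak signal.
#'
#' @param height,width Image size in pixels (default 64 x 64).
#' @param axis A [wn_axis()] (default [default_axis()]).
#' @param components Named list of [band_model()]s (default
#'   [default_band_models()]).
#' @param scene List of spatial primitives (default [default_scene()]); each
#'   must reference a declared component.
#' @param noise_sd Additive Gaussian sigma relative to the peak (maximum)
#'   noise-free signal (default 0.02).
#' @param seed Integer RNG seed; the same spec and seed give bit-identical
#'   cubes (default 1).
#' @param pixel_size_um Pixel edge in micrometres (default 0.5).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 64, width = 64, axis = default_axis(),
                         components = default_band_models(),
                         scene = default_scene(), noise_sd = 0.02,
                         seed = 1L, pixel_size_um = 0.5) {
  if (height < 1 || width < 1)
    stop("phantom_spec: height and width must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("phantom_spec: noise_sd must be >= 0", call. = FALSE)
  if (is.null(names(components)) || anyDuplicated(names(components)))
    stop("phantom_spec: components must be uniquely named", call. = FALSE)
  for (p in scene)
    if (!p$component %in% names(components))
      stop(sprintf("phantom_spec: scene references undeclared component '%s'",
                   p$component), call. = FALSE)
  structure(list(height = as.integer(height), width = as.integer(width),
                 axis = if (inherits(axis, "wn_axis")) axis else wn_axis(axis),
                 components = components, scene = scene,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 pixel_size_um = pixel_size_um),
            class = "phantom_spec")
}

rasterize_primitive <- function(p, H, W) {
  sc <- min(H, W)
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  mask <- switch(p$shape,
    background = matrix(TRUE, H, W),
    disk = {
      r0 <- p$center[1] * H; c0 <- p$center[2] * W
      (rr - r0)^2 + (cc - c0)^2 <= (p$radius * sc)^2
    },
    annulus = {
      r0 <- p$center[1] * H; c0 <- p$center[2] * W
      d2 <- (rr - r0)^2 + (cc - c0)^2
      d2 >= (p$r_inner * sc)^2 & d2 <= (p$r_outer * sc)^2
    },
    fiber = {
      pts <- cbind(p$points[, 1] * H, p$points[, 2] * W)
      thick <- p$thickness * sc
      m <- matrix(FALSE, H, W)
      for (s in seq_len(nrow(pts) - 1L)) {
        a <- pts[s, ]; b <- pts[s + 1L, ]
        ab <- b - a
        len2 <- sum(ab^2)
        t <- if (len2 > 0) ((rr - a[1]) * ab[1] + (cc - a[2]) * ab[2]) / len2
             else rr * 0
        t <- pmin(pmax(t, 0), 1)
        d2 <- (rr - (a[1] + t * ab[1]))^2 + (cc - (a[2] + t * ab[2]))^2
        m <- m | (d2 <= thick^2)
      }
      m
    })
  mask
}

#' Generate a synthetic tissue phantom
#'
#' Rasterizes the scene into ground-truth concentration maps, mixes them
#' linearly with the component spectra (cube = sum_k truth_k (x) spectrum_k),
#' adds white Gaussian noise scaled to the peak noise-free signal, and clips
#' at zero. With `noise_sd = 0` the cube reproduces the linear mixing model
#' exactly. The same spec and seed give bit-identical output; the caller's
#' RNG state is left untouched.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `cube` (a [hyper_cube()]), `truth` (the
#'   noise-free [conc_maps()] ground truth) and `library` (the unit-norm
#'   [ref_library()] built from the spec's band models).
#' @examples
#' ph <- generate_phantom(phantom_spec(height = 16, width = 16, noise_sd = 0))
#' dim(ph$cube$data)
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  H <- spec$height; W <- spec$width
  x <- as.numeric(spec$axis)
  comp_names <- names(spec$components)
  K <- length(comp_names)
  spectra <- t(vapply(spec$components, eval_band_model, numeric(length(x)),
                      axis = x))
  lib <- ref_library(spectra, spec$axis, names = comp_names)
  truth <- array(0, dim = c(H, W, K))
  for (p in spec$scene) {
    k <- match(p$component, comp_names)
    mask <- rasterize_primitive(p, H, W)
    plane <- truth[, , k]
    plane[mask] <- plane[mask] + p$level
    truth[, , k] <- plane
  }
  # linear mixing against the *normalized* library, so unmixing targets truth
  N <- H * W
  clean <- matrix(truth, nrow = N) %*% lib$spectra  # N x M
  cube_data <- array(clean, dim = c(H, W, length(x)))
  if (spec$noise_sd > 0) {
    peak <- max(cube_data)
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(spec$seed)
    cube_data <- cube_data +
      array(rnorm(length(cube_data), sd = spec$noise_sd * peak),
            dim = dim(cube_data))
  }
  cube_data[cube_data < 0] <- 0
  cube <- hyper_cube(cube_data, spec$axis, pixel_size_um = spec$pixel_size_um,
                     provenance = list(source = "phantom", seed = spec$seed,
                                       noise_sd = spec$noise_sd))
  list(cube = cube,
       truth = conc_maps(truth, comp_names,
                         provenance = list(source = "phantom_truth",
                                           seed = spec$seed)),
       library = lib)
}
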
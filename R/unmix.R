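#' Unmixing parameters
#'
#' Settings for sparsity-penalized (LASSO) spectral unmixing. The objective
#' solved per pixel is
#' \deqn{\min_c \; \|y - A^\top c\|_2^2 + \lambda \|c\|_1, \quad c \ge 0,}
#' where rows of A are the (unit-norm) reference spectra and y is the pixel
#' spectrum, *not* normalized. Note the absence of a 1/(2M) factor: lambda is
#' interpretable directly on this scale, with 0.01 the working default.
#' Non-negativity is on by default because the outputs are concentrations;
#' set `nonneg = FALSE` to solve the unconstrained LASSO.
#'
#' @param lam Sparsity penalty lambda >= 0 (default 0.01).
#' @param nonneg Constrain abundances to be nonnegative (default `TRUE`).
#' @param max_iters Maximum coordinate-descent sweeps (default 20000).
#' @param tol Convergence tolerance on the largest coordinate change per
#'   sweep, relative to the largest coefficient (default 1e-10).
#' @return An object of class `unmix_params`.
#' @export
unmix_params <- function(lam = 0.01, nonneg = TRUE, max_iters = 20000,
                         tol = 1e-10) {
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam < 0)
    stop("unmix_params: lam must be a single number >= 0", call. = FALSE)
  if (max_iters < 1L) stop("unmix_params: max_iters must be >= 1", call. = FALSE)
  if (tol <= 0) stop("unmix_params: tol must be > 0", call. = FALSE)
  structure(list(lam = lam, nonneg = isTRUE(nonneg),
                 max_iters = as.integer(max_iters), tol = tol),
            class = "unmix_params")
}

#' Unmix a single pixel spectrum
#'
#' Solves the per-pixel non-negative LASSO against a reference library by
#' cyclic coordinate descent started from zero (deterministic). See
#' [unmix_params()] for the exact objective and lambda convention.
#'
#' @param y Numeric length-M pixel spectrum on the library's axis (possibly
#'   channel-restricted).
#' @param library A [ref_library()].
#' @param params An [unmix_params()].
#' @return Numeric length-K abundance vector named by component.
#' @examples
#' ax <- wn_axis(seq(2820, 3030, length.out = 45))
#' lib <- make_default_library(ax)
#' y <- 2 * lib$spectra["water", ]
#' lasso_unmix_pixel(y, lib, unmix_params(lam = 0))
#' @export
lasso_unmix_pixel <- function(y, library, params = unmix_params()) {
  y <- as.numeric(y)
  if (length(y) != ncol(library$spectra))
    stop(sprintf("lasso_unmix_pixel: spectrum has %d channels, library has %d",
                 length(y), ncol(library$spectra)), call. = FALSE)
  if (!all(is.finite(y)))
    stop("lasso_unmix_pixel: non-finite values in spectrum", call. = FALSE)
  C <- lasso_cd_cpp(library$spectra, matrix(y, ncol = 1), params$lam,
                    params$nonneg, params$max_iters, params$tol)
  stats::setNames(as.numeric(C[, 1]), library$names)
}

#' Unmix a hyperspectral cube into concentration maps
#'
#' Applies [lasso_unmix_pixel()] independently to every pixel (vectorised in
#' compiled code). The cube and library must share the same wavenumber axis;
#' both may be channel-restricted with [restrict_to_channels()] first, in
#' which case the library keeps its full-spectrum normalization so abundances
#' remain on the full-spectrum concentration scale.
#'
#' @param cube A [hyper_cube()].
#' @param library A [ref_library()] on the same axis.
#' @param params An [unmix_params()].
#' @return A [conc_maps()] with one plane per library component, in library
#'   order; lambda, normalization tag and channel subset are recorded in the
#'   provenance field.
#' @export
unmix_cube <- function(cube, library, params = unmix_params()) {
  v <- validate_cube(cube)
  if (length(v)) stop(paste("unmix_cube: invalid cube:", v[1]), call. = FALSE)
  if (length(cube$axis) != ncol(library$spectra) ||
      max(abs(as.numeric(cube$axis) - as.numeric(library$axis))) > 1e-6)
    stop("unmix_cube: cube and library are on different axes", call. = FALSE)
  d <- dim(cube$data)
  Y <- matrix(aperm(cube$data, c(3, 1, 2)), nrow = d[3])  # M x (H*W)
  C <- lasso_cd_cpp(library$spectra, Y, params$lam, params$nonneg,
                    params$max_iters, params$tol)
  K <- nrow(library$spectra)
  maps <- aperm(array(C, dim = c(K, d[1], d[2])), c(2, 3, 1))
  if (!params$nonneg) maps[maps < 0] <- 0  # conc_maps are concentrations
  conc_maps(maps, library$names,
            provenance = list(lam = params$lam,
                              nonneg = params$nonneg,
                              normalization = library$normalization,
                              axis_used = as.numeric(cube$axis)))
}

#' Derive a cellular-protein reference spectrum by lipid subtraction
#'
#' Pure cellular protein cannot be measured directly: a cultured-cell
#' spectrum always contains intracellular lipid. This routine removes the
#' lipid contribution by fitting a nonnegative scale alpha on a lipid-marker
#' spectral window (default: within `halfwidth` cm^-1 of the ~3009 cm^-1
#' =C-H band, which is specific to unsaturated lipid) and subtracting
#' `alpha * lipid` from the cell spectrum, clipping at zero and
#' renormalizing to unit Euclidean norm.
#'
#' @param cell_spectrum,lipid_spectrum Nonnegative length-M spectra on `axis`.
#' @param axis The shared [wn_axis()].
#' @param marker_shift Centre of the lipid-marker window in cm^-1
#'   (default 3009).
#' @param halfwidth Half-width of the marker window in cm^-1 (default 10).
#' @return Unit-norm nonnegative protein spectrum (numeric length M).
#' @export
derive_protein_reference <- function(cell_spectrum, lipid_spectrum, axis,
                                     marker_shift = 3009, halfwidth = 10) {
  if (!inherits(axis, "wn_axis")) axis <- wn_axis(axis)
  cell <- as.numeric(cell_spectrum); lip <- as.numeric(lipid_spectrum)
  if (length(cell) != length(axis) || length(lip) != length(axis))
    stop("derive_protein_reference: spectra must match the axis length",
         call. = FALSE)
  if (any(cell < 0) || any(lip < 0))
    stop("derive_protein_reference: spectra must be nonnegative", call. = FALSE)
  win <- abs(as.numeric(axis) - marker_shift) <= halfwidth
  if (!any(win)) win <- rep(TRUE, length(axis))  # no marker channel: fit globally
  denom <- sum(lip[win]^2)
  alpha <- if (denom > 0) max(0, sum(cell[win] * lip[win]) / denom) else 0
  res <- pmax(cell - alpha * lip, 0)
  nrm <- sqrt(sum(res^2))
  if (nrm <= 1e-12 * max(1, sqrt(sum(cell^2))))
    stop("derive_protein_reference: residual spectrum is all zero (degenerate input)",
         call. = FALSE)
  res / nrm
}
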
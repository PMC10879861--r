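#' @useDynLib srhmap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile rnorm runif sd
NULL

#' Wavenumber axis
#'
#' An ordered grid of Raman shifts (cm^-1) shared by hyperspectral cubes and
#' reference spectra. Shifts must be finite, positive and strictly increasing.
#'
#' @param shifts Numeric vector of Raman shifts in cm^-1.
#' @return An object of class `wn_axis`: the numeric vector with class attached.
#' @examples
#' ax <- wn_axis(seq(2820, 3030, length.out = 45))
#' length(ax)
#' @export
wn_axis <- function(shifts) {
  shifts <- as.numeric(shifts)
  if (length(shifts) < 1L)
    stop("wn_axis: need at least one shift", call. = FALSE)
  if (!all(is.finite(shifts)) || any(shifts <= 0))
    stop("wn_axis: shifts must be finite and positive", call. = FALSE)
  if (is.unsorted(shifts, strictly = TRUE))
    stop("wn_axis: shifts must be strictly increasing", call. = FALSE)
  structure(shifts, class = "wn_axis")
}

#' @export
print.wn_axis <- function(x, ...) {
  cat(sprintf("<wn_axis> %d shifts, %.1f to %.1f cm^-1\n",
              length(x), x[1], x[length(x)]))
  invisible(x)
}

#' Hyperspectral SRS image cube
#'
#' An H x W x M volume of nonnegative stimulated Raman scattering intensities,
#' one image plane per Raman shift, stored in (row, column, channel) order with
#' image origin top-left. The third dimension must match the wavenumber axis.
#'
#' @param data Numeric H x W x M array of intensities (arbitrary SRS units).
#' @param axis A [wn_axis()] of length M.
#' @param pixel_size_um Physical pixel edge in micrometres (default 0.5,
#'   i.e. 500 nm).
#' @param provenance Optional named list of free-text metadata (instrument,
#'   dwell time, seed, pipeline-stage history).
#' @return An object of class `hyper_cube` with fields `data`, `axis`,
#'   `pixel_size_um`, `provenance`.
#' @seealso [validate_cube()], [read_cube()], [generate_phantom()]
#' @export
hyper_cube <- function(data, axis, pixel_size_um = 0.5, provenance = list()) {
  if (!inherits(axis, "wn_axis")) axis <- wn_axis(axis)
  data <- as.array(data)
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3L)
    stop("hyper_cube: data must be an H x W x M array", call. = FALSE)
  if (dim(data)[3] != length(axis))
    stop(sprintf("hyper_cube: data has %d channels but axis has %d shifts",
                 dim(data)[3], length(axis)), call. = FALSE)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("hyper_cube: pixel_size_um must be a single positive number",
         call. = FALSE)
  structure(list(data = data, axis = axis,
                 pixel_size_um = as.numeric(pixel_size_um),
                 provenance = provenance),
            class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hyper_cube> %d x %d px, %d channels (%.1f-%.1f cm^-1), pixel %.3g um\n",
              d[1], d[2], d[3], x$axis[1], x$axis[length(x$axis)],
              x$pixel_size_um))
  invisible(x)
}

#' @export
dim.hyper_cube <- function(x) dim(x$data)

#' Validate a hyperspectral cube
#'
#' Report-only structural check; returns a character vector of violations
#' (empty when the cube is well formed). Never mutates or errors on its input.
#'
#' @param cube A [hyper_cube()] (or a malformed list resembling one).
#' @return Character vector of human-readable violations; `character(0)` if
#'   the cube is valid.
#' @export
validate_cube <- function(cube) {
  v <- character(0)
  if (!is.list(cube) || is.null(cube$data) || is.null(cube$axis)) {
    return("not a hyper_cube: missing data or axis")
  }
  d <- dim(cube$data)
  if (length(d) != 3L) {
    v <- c(v, "data is not a 3-d array")
    return(v)
  }
  if (d[1] < 1L || d[2] < 1L)
    v <- c(v, "spatial dimensions must be >= 1")
  if (d[3] != length(cube$axis))
    v <- c(v, sprintf("axis length mismatch: %d channels vs %d shifts",
                      d[3], length(cube$axis)))
  if (!all(is.finite(cube$data)))
    v <- c(v, "non-finite intensity values present")
  if (is.unsorted(as.numeric(cube$axis), strictly = TRUE) ||
      any(!is.finite(cube$axis)) || any(cube$axis <= 0))
    v <- c(v, "axis is not a strictly increasing positive grid")
  if (!is.null(cube$pixel_size_um) &&
      (!is.finite(cube$pixel_size_um) || cube$pixel_size_um <= 0))
    v <- c(v, "pixel_size_um must be positive")
  v
}

#' Reference spectra library
#'
#' K named pure-component (endmember) spectra on a shared wavenumber axis:
#' the matrix A of the linear mixing model y = A^T c. At construction each
#' spectrum is scaled to unit Euclidean norm (recorded in the `normalization`
#' tag) so that the sparsity penalty lambda is transferable across libraries.
#'
#' @param spectra Numeric K x M matrix, one spectrum per row. Row names are
#'   used as component names if `names` is not given.
#' @param axis A [wn_axis()] of length M.
#' @param names Character vector of K unique component identifiers.
#' @param normalize Scale each row to unit Euclidean norm (default `TRUE`).
#' @return An object of class `ref_library` with fields `spectra`, `names`,
#'   `axis`, `normalization`.
#' @export
ref_library <- function(spectra, axis, names = rownames(spectra),
                        normalize = TRUE) {
  if (!inherits(axis, "wn_axis")) axis <- wn_axis(axis)
  spectra <- as.matrix(spectra)
  if (is.null(names)) names <- paste0("component_", seq_len(nrow(spectra)))
  names <- as.character(names)
  if (nrow(spectra) < 1L)
    stop("ref_library: need at least one spectrum", call. = FALSE)
  if (ncol(spectra) != length(axis))
    stop("ref_library: spectra have wrong number of channels", call. = FALSE)
  if (length(names) != nrow(spectra) || anyDuplicated(names))
    stop("ref_library: names must be unique, one per spectrum", call. = FALSE)
  if (!all(is.finite(spectra)) || any(spectra < 0))
    stop("ref_library: spectra must be finite and nonnegative", call. = FALSE)
  tag <- "none"
  if (normalize) {
    nrm <- sqrt(rowSums(spectra^2))
    if (any(nrm == 0))
      stop("ref_library: cannot normalize an all-zero spectrum", call. = FALSE)
    spectra <- spectra / nrm
    tag <- "unit_l2"
  }
  rownames(spectra) <- names
  structure(list(spectra = spectra, names = names, axis = axis,
                 normalization = tag),
            class = "ref_library")
}

#' @export
print.ref_library <- function(x, ...) {
  cat(sprintf("<ref_library> %d components x %d channels [%s]: %s\n",
              nrow(x$spectra), ncol(x$spectra), x$normalization,
              paste(x$names, collapse = ", ")))
  invisible(x)
}

#' Concentration (abundance) maps
#'
#' H x W x K nonnegative abundance volume produced by spectral unmixing,
#' one plane per library component, in library order.
#'
#' @param data Numeric H x W x K array of abundances (arbitrary units).
#' @param names Character vector of K component identifiers matching the
#'   library used for unmixing.
#' @param axis_used Optional [channel_subset()] recording which channels
#'   produced the maps (`NULL` means the full axis).
#' @param provenance Optional named list (lambda, normalization tag, ...).
#' @return An object of class `conc_maps`.
#' @export
conc_maps <- function(data, names, axis_used = NULL, provenance = list()) {
  data <- as.array(data)
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3L)
    stop("conc_maps: data must be an H x W x K array", call. = FALSE)
  names <- as.character(names)
  if (dim(data)[3] != length(names) || anyDuplicated(names))
    stop("conc_maps: need one unique name per component plane", call. = FALSE)
  if (!all(is.finite(data)) || any(data < 0))
    stop("conc_maps: abundances must be finite and nonnegative", call. = FALSE)
  dimnames(data) <- list(NULL, NULL, names)
  structure(list(data = data, names = names, axis_used = axis_used,
                 provenance = provenance),
            class = "conc_maps")
}

#' @export
print.conc_maps <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<conc_maps> %d x %d px, %d components: %s\n",
              d[1], d[2], d[3], paste(x$names, collapse = ", ")))
  invisible(x)
}

#' Selected channel subset
#'
#' The output of recursive feature elimination: which channels of a parent
#' wavenumber axis survive, plus the elimination trace (per-step MSE).
#'
#' @param indices Integer positions (1-based) into the parent axis; unique,
#'   stored sorted ascending.
#' @param parent_axis The [wn_axis()] the indices refer to.
#' @param trace Optional data.frame with one row per eliminated channel, in
#'   elimination order, columns `eliminated_index`, `eliminated_shift`, `mse`.
#'   Its length must equal `length(parent_axis) - length(indices)`.
#' @return An object of class `channel_subset` with fields `indices`,
#'   `shifts`, `trace`.
#' @seealso [rfe_select()], [restrict_to_channels()]
#' @export
channel_subset <- function(indices, parent_axis, trace = NULL) {
  if (!inherits(parent_axis, "wn_axis")) parent_axis <- wn_axis(parent_axis)
  indices <- as.integer(indices)
  if (length(indices) < 1L || anyDuplicated(indices))
    stop("channel_subset: indices must be unique, at least one", call. = FALSE)
  if (any(indices < 1L) || any(indices > length(parent_axis)))
    stop("channel_subset: index out of range of parent axis", call. = FALSE)
  indices <- sort(indices)
  if (is.null(trace)) {
    trace <- data.frame(eliminated_index = integer(0),
                        eliminated_shift = numeric(0), mse = numeric(0))
  }
  if (nrow(trace) != length(parent_axis) - length(indices))
    stop("channel_subset: trace length must equal number of eliminated channels",
         call. = FALSE)
  structure(list(indices = indices,
                 shifts = as.numeric(parent_axis)[indices],
                 trace = trace),
            class = "channel_subset")
}

#' @export
print.channel_subset <- function(x, ...) {
  cat(sprintf("<channel_subset> %d channels: %s cm^-1 (%d eliminated)\n",
              length(x$indices),
              paste(round(x$shifts, 1), collapse = ", "), nrow(x$trace)))
  invisible(x)
}

#' Restrict a cube or reference library to a channel subset
#'
#' Slices the spectral dimension down to the selected channels. The returned
#' object's axis equals the subset shifts. Library spectra are sliced, not
#' renormalized: they keep their full-spectrum unit-norm scaling so that
#' reduced-channel abundances stay on the same concentration scale as
#' full-spectrum abundances (required for SSIM/PSNR comparison against the
#' full-channel result).
#'
#' @param x A [hyper_cube()] or [ref_library()].
#' @param subset A [channel_subset()] on `x`'s axis, or an integer vector of
#'   channel indices.
#' @return An object of the same class as `x`, restricted to the subset.
#' @export
restrict_to_channels <- function(x, subset) UseMethod("restrict_to_channels")

subset_indices <- function(subset, m) {
  idx <- if (inherits(subset, "channel_subset")) subset$indices
         else sort(unique(as.integer(subset)))
  if (length(idx) < 1L) stop("empty channel subset", call. = FALSE)
  if (any(idx < 1L) || any(idx > m))
    stop(sprintf("channel index out of range 1..%d", m), call. = FALSE)
  idx
}

#' @export
restrict_to_channels.hyper_cube <- function(x, subset) {
  idx <- subset_indices(subset, dim(x$data)[3])
  hyper_cube(x$data[, , idx, drop = FALSE],
             wn_axis(as.numeric(x$axis)[idx]),
             pixel_size_um = x$pixel_size_um,
             provenance = c(x$provenance,
                            list(channel_subset = as.numeric(x$axis)[idx])))
}

#' @export
restrict_to_channels.ref_library <- function(x, subset) {
  idx <- subset_indices(subset, ncol(x$spectra))
  out <- x
  out$spectra <- x$spectra[, idx, drop = FALSE]
  out$axis <- wn_axis(as.numeric(x$axis)[idx])
  # normalization tag is kept: rows still carry full-spectrum unit-norm scale
  out
}
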
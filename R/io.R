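#' Write a hyperspectral cube as multi-page TIFF + JSON sidecar
#'
#' One grayscale 32-bit TIFF page per channel, in axis order, plus a JSON
#' sidecar carrying the wavenumber axis, pixel size, an intensity scale
#' factor, and free-text provenance. Intensities are stored divided by the
#' recorded `intensity_scale` (the cube maximum) so that arbitrary SRS
#' signal levels survive the TIFF's unit-range samples; the round trip is
#' lossless well beyond 32-bit float precision.
#'
#' @param cube A [hyper_cube()].
#' @param stack_path Output TIFF path.
#' @param sidecar_path Output JSON path (default: `stack_path` with a
#'   `.json` extension).
#' @return Invisibly, the sidecar list that was written.
#' @export
write_cube <- function(cube, stack_path,
                       sidecar_path = sub("\\.tiff?$", ".json", stack_path)) {
  v <- validate_cube(cube)
  if (length(v)) stop(paste("write_cube: invalid cube:", v[1]), call. = FALSE)
  d <- dim(cube$data)
  scale <- max(cube$data)
  if (scale <= 0) scale <- 1
  pages <- lapply(seq_len(d[3]), function(m) cube$data[, , m] / scale)
  tiff::writeTIFF(pages, stack_path, bits.per.sample = 32L,
                  compression = "none")
  sidecar <- list(shifts_cm1 = as.numeric(cube$axis),
                  pixel_size_um = cube$pixel_size_um,
                  intensity_scale = scale,
                  provenance = cube$provenance)
  jsonlite::write_json(sidecar, sidecar_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(sidecar)
}

#' Read a hyperspectral cube from multi-page TIFF + JSON sidecar
#'
#' Pages map to channels in sidecar order; data are floating point after
#' multiplication by the sidecar's `intensity_scale` (1 if absent).
#'
#' @param stack_path Multi-page grayscale TIFF.
#' @param sidecar_path JSON sidecar with `shifts_cm1` (length must equal the
#'   page count) and `pixel_size_um`.
#' @return A [hyper_cube()].
#' @export
read_cube <- function(stack_path,
                      sidecar_path = sub("\\.tiff?$", ".json", stack_path)) {
  if (!file.exists(stack_path))
    stop(sprintf("read_cube: no such file: %s", stack_path), call. = FALSE)
  if (!file.exists(sidecar_path))
    stop(sprintf("read_cube: no such sidecar: %s", sidecar_path), call. = FALSE)
  pages <- tiff::readTIFF(stack_path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- jsonlite::fromJSON(sidecar_path, simplifyVector = TRUE)
  shifts <- as.numeric(sidecar$shifts_cm1)
  if (length(shifts) != length(pages))
    stop(sprintf("read_cube: sidecar has %d shifts but stack has %d pages",
                 length(shifts), length(pages)), call. = FALSE)
  scale <- if (!is.null(sidecar$intensity_scale))
    as.numeric(sidecar$intensity_scale) else 1
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # tolerate greyscale-as-RGB
    p * scale
  })
  data <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  prov <- sidecar$provenance
  if (is.null(prov)) prov <- list()
  psz <- if (!is.null(sidecar$pixel_size_um))
    as.numeric(sidecar$pixel_size_um) else 0.5
  hyper_cube(data, wn_axis(shifts), pixel_size_um = psz,
             provenance = as.list(prov))
}

#' Read a reference-spectra library from CSV
#'
#' Expected layout: a header row, first column `wavenumber_cm1` (strictly
#' increasing), then one nonnegative intensity column per component.
#' Spectra are unit-norm normalized at construction; column order is
#' preserved as component order.
#'
#' @param csv_path CSV file path.
#' @return A [ref_library()].
#' @export
read_library <- function(csv_path) {
  df <- utils::read.csv(csv_path, check.names = FALSE)
  if (ncol(df) < 2L || names(df)[1] != "wavenumber_cm1")
    stop("read_library: first column must be 'wavenumber_cm1' followed by one column per component",
         call. = FALSE)
  wn <- as.numeric(df[[1]])
  if (any(!is.finite(wn)) || is.unsorted(wn, strictly = TRUE))
    stop("read_library: wavenumber column must be finite and strictly increasing",
         call. = FALSE)
  spectra <- t(as.matrix(df[-1]))
  if (any(!is.finite(spectra)) || any(spectra < 0))
    stop("read_library: spectra must be finite and nonnegative", call. = FALSE)
  ref_library(spectra, wn_axis(wn), names = names(df)[-1])
}

#' Write a reference-spectra library to CSV
#'
#' Inverse of [read_library()] (the stored spectra are the normalized ones,
#' so reading the file back reproduces the library exactly).
#'
#' @param library A [ref_library()].
#' @param csv_path Output path.
#' @export
write_library <- function(library, csv_path) {
  df <- data.frame(wavenumber_cm1 = as.numeric(library$axis),
                   t(library$spectra), check.names = FALSE)
  names(df)[-1] <- library$names
  utils::write.csv(df, csv_path, row.names = FALSE)
  invisible(csv_path)
}

#' Write concentration maps: one TIFF per component plus a JSON manifest
#'
#' The manifest records the component names and file names, the channel
#' subset used, lambda, the library normalization tag, and per-component
#' intensity scales, so any map can be traced back to its inputs. Refuses
#' maps containing negative values.
#'
#' @param maps A [conc_maps()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
write_maps <- function(maps, out_dir) {
  if (!inherits(maps, "conc_maps"))
    stop("write_maps: need a conc_maps object", call. = FALSE)
  if (any(maps$data < 0))
    stop("write_maps: negative abundances violate the concentration-map invariant",
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  K <- length(maps$names)
  files <- character(K); scales <- numeric(K)
  for (k in seq_len(K)) {
    plane <- maps$data[, , k]
    scales[k] <- max(plane)
    if (scales[k] <= 0) scales[k] <- 1
    files[k] <- paste0(gsub("[^A-Za-z0-9_.-]", "_", maps$names[k]), ".tif")
    tiff::writeTIFF(plane / scales[k], file.path(out_dir, files[k]),
                    bits.per.sample = 32L, compression = "none")
  }
  manifest <- list(names = maps$names, files = files,
                   intensity_scale = scales,
                   axis_used = if (inherits(maps$axis_used, "channel_subset"))
                     maps$axis_used$shifts else maps$axis_used,
                   provenance = maps$provenance)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read concentration maps written by [write_maps()]
#'
#' @param dir Directory containing `manifest.json` and the component TIFFs.
#' @return A [conc_maps()].
#' @export
read_maps <- function(dir) {
  mf <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                           simplifyVector = TRUE)
  K <- length(mf$names)
  planes <- vector("list", K)
  for (k in seq_len(K)) {
    p <- tiff::readTIFF(file.path(dir, mf$files[k]))
    planes[[k]] <- p * mf$intensity_scale[k]
  }
  data <- array(unlist(planes), dim = c(dim(planes[[1]]), K))
  conc_maps(data, mf$names, provenance = as.list(mf$provenance))
}

#' Write an RGB rendering to PNG
#'
#' @param img H x W x 3 array in [0, 1] (from [render_merged()]).
#' @param path Output PNG path.
#' @export
write_render_png <- function(img, path) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("write_render_png: need an H x W x 3 array", call. = FALSE)
  png::writePNG(img, path)
  invisible(path)
}
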
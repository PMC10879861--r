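#' Default pseudo-color scheme for the five-component histology rendering
#'
#' Yellow for unsaturated lipids, red for cellular protein, blue for ECM,
#' cyan for saturated lipids, grey for water.
#'
#' @return Named list of RGB triples in [0, 1].
#' @export
default_color_scheme <- function() {
  list(unsaturated_lipid = c(1, 1, 0),
       cellular_protein = c(1, 0, 0),
       ecm = c(0, 0, 1),
       saturated_lipid = c(0, 1, 1),
       water = c(0.6, 0.6, 0.6))
}

#' Percentile-stretch contrast enhancement
#'
#' Linearly maps the [p_lo, p_hi] percentile interval of a nonnegative
#' image plane to [0, 1], clipping outside. Used e.g. to bring up detail in
#' the low-contrast water channel before display. A constant plane has no
#' stretch interval and maps to all zeros.
#'
#' @param plane Nonnegative numeric matrix.
#' @param percentiles Length-2 vector `c(p_lo, p_hi)` in percent,
#'   `p_lo < p_hi` (default `c(1, 99)`).
#' @return Matrix with values in [0, 1].
#' @export
enhance_contrast <- function(plane, percentiles = c(1, 99)) {
  plane <- as.matrix(plane)
  if (length(percentiles) != 2L || percentiles[1] >= percentiles[2])
    stop("enhance_contrast: need percentiles p_lo < p_hi", call. = FALSE)
  if (any(plane < 0))
    stop("enhance_contrast: plane must be nonnegative", call. = FALSE)
  qq <- quantile(plane, percentiles / 100, names = FALSE)
  if (qq[2] <= qq[1]) return(plane * 0)
  out <- (plane - qq[1]) / (qq[2] - qq[1])
  pmin(pmax(out, 0), 1)
}

#' Merged pseudo-color histology rendering
#'
#' Each component plane is normalized to its own maximum, multiplied by its
#' RGB color and an optional per-component weight, and the colored planes
#' are summed and clipped to [0, 1]. Additive blending means overlapping
#' components mix (red + blue = magenta) and the image is scale-invariant
#' per component. The water channel is drawn at reduced weight by default so
#' its grey background does not wash out tissue structure.
#'
#' @param maps A [conc_maps()].
#' @param scheme Named list of RGB triples covering every component
#'   (default [default_color_scheme()]).
#' @param water_weight Blend weight applied to the component named `"water"`
#'   if present (default 0.5; set to 1 to disable).
#' @return H x W x 3 RGB array with values in [0, 1].
#' @export
render_merged <- function(maps, scheme = default_color_scheme(),
                          water_weight = 0.5) {
  d <- dim(maps$data)
  img <- array(0, dim = c(d[1], d[2], 3L))
  for (k in seq_along(maps$names)) {
    nm <- maps$names[k]
    col <- scheme[[nm]]
    if (is.null(col))
      stop(sprintf("render_merged: no color for component '%s'", nm),
           call. = FALSE)
    if (length(col) != 3L || any(col < 0) || any(col > 1))
      stop("render_merged: colors must be RGB triples in [0, 1]", call. = FALSE)
    plane <- maps$data[, , k]
    mx <- max(plane)
    if (mx > 0) plane <- plane / mx
    wgt <- if (identical(nm, "water")) water_weight else 1
    for (ch in 1:3)
      img[, , ch] <- img[, , ch] + wgt * col[ch] * plane
  }
  img[img > 1] <- 1
  img[img < 0] <- 0
  img
}
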
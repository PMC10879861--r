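#' Rectangular grid of overlapping hyperspectral tiles
#'
#' @param tiles List of [hyper_cube()]s in row-major order (length
#'   `rows * cols`). All tiles must share size, axis and pixel size.
#' @param rows,cols Grid shape.
#' @param overlap Nominal overlap between neighboring tiles in pixels
#'   (>= 0, less than the tile size).
#' @return An object of class `tile_grid`.
#' @export
tile_grid <- function(tiles, rows, cols, overlap) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  overlap <- as.integer(overlap)
  if (length(tiles) != rows * cols)
    stop("tile_grid: need rows * cols tiles in row-major order", call. = FALSE)
  d1 <- dim(tiles[[1]]$data)
  ax1 <- as.numeric(tiles[[1]]$axis)
  for (t in tiles) {
    if (!inherits(t, "hyper_cube"))
      stop("tile_grid: tiles must be hyper_cube objects", call. = FALSE)
    if (!all(dim(t$data) == d1))
      stop("tile_grid: all tiles must have the same dimensions", call. = FALSE)
    if (length(t$axis) != length(ax1) || max(abs(as.numeric(t$axis) - ax1)) > 1e-6)
      stop("tile_grid: all tiles must share the wavenumber axis", call. = FALSE)
    if (abs(t$pixel_size_um - tiles[[1]]$pixel_size_um) > 1e-9)
      stop("tile_grid: all tiles must share the pixel size", call. = FALSE)
  }
  if (overlap < 0 || overlap >= min(d1[1], d1[2]))
    stop("tile_grid: overlap must be >= 0 and smaller than the tile size",
         call. = FALSE)
  structure(list(tiles = tiles, rows = rows, cols = cols, overlap = overlap),
            class = "tile_grid")
}

#' Cut a cube into an overlapping tile grid
#'
#' Test/benchmark helper: splits a cube into a `rows` x `cols` grid of tiles
#' with the given nominal overlap, optionally jittering each tile's source
#' origin by known integer offsets (to exercise registration refinement).
#' The full size must tile exactly:
#' `H = rows * tile_h - (rows - 1) * overlap` for an integer `tile_h` (and
#' likewise for width).
#'
#' @param cube A [hyper_cube()].
#' @param rows,cols Grid shape.
#' @param overlap Overlap in pixels.
#' @param jitter Optional `(rows*cols)` x 2 integer matrix of (row, col)
#'   origin offsets per tile, row-major; clamped to keep tiles inside the
#'   cube. Default: no jitter.
#' @return List with `grid` (a [tile_grid()]) and `jitter` (the applied,
#'   possibly clamped, offsets).
#' @export
split_into_tiles <- function(cube, rows, cols, overlap, jitter = NULL) {
  d <- dim(cube$data)
  rows <- as.integer(rows); cols <- as.integer(cols)
  overlap <- as.integer(overlap)
  th_num <- d[1] + (rows - 1L) * overlap
  tw_num <- d[2] + (cols - 1L) * overlap
  if (th_num %% rows != 0L || tw_num %% cols != 0L)
    stop("split_into_tiles: size does not tile exactly with this overlap",
         call. = FALSE)
  th <- th_num %/% rows; tw <- tw_num %/% cols
  n <- rows * cols
  if (is.null(jitter)) jitter <- matrix(0L, n, 2L)
  jitter <- matrix(as.integer(jitter), n, 2L)
  tiles <- vector("list", n)
  applied <- matrix(0L, n, 2L)
  for (i in seq_len(rows)) for (j in seq_len(cols)) {
    t_idx <- (i - 1L) * cols + j
    r0 <- (i - 1L) * (th - overlap) + 1L
    c0 <- (j - 1L) * (tw - overlap) + 1L
    r0j <- min(max(r0 + jitter[t_idx, 1], 1L), d[1] - th + 1L)
    c0j <- min(max(c0 + jitter[t_idx, 2], 1L), d[2] - tw + 1L)
    applied[t_idx, ] <- c(r0j - r0, c0j - c0)
    tiles[[t_idx]] <- hyper_cube(
      cube$data[r0j:(r0j + th - 1L), c0j:(c0j + tw - 1L), , drop = FALSE],
      cube$axis, pixel_size_um = cube$pixel_size_um)
  }
  list(grid = tile_grid(tiles, rows, cols, overlap), jitter = applied)
}

# integer shift s maximizing correlation, restricted to candidate shifts;
# returns s such that b(x) ~= a(x - s)
phase_corr_shift <- function(a, b, candidates) {
  fa <- stats::fft(a); fb <- stats::fft(b)
  cp <- fb * Conj(fa)
  mag <- Mod(cp)
  cp <- cp / pmax(mag, 1e-12)
  surf <- Re(stats::fft(cp, inverse = TRUE))
  H <- nrow(a); W <- ncol(a)
  best <- candidates[1, ]; best_val <- -Inf
  for (r in seq_len(nrow(candidates))) {
    s <- candidates[r, ]
    ir <- ((s[1]) %% H) + 1L
    ic <- ((s[2]) %% W) + 1L
    if (surf[ir, ic] > best_val) { best_val <- surf[ir, ic]; best <- s }
  }
  as.integer(best)
}

#' Fuse a tile grid into one large field-of-view cube
#'
#' Places the tiles at their nominal grid positions and averages overlaps
#' with linear feather weights (weight ramps from 1/(overlap+1) at a tile
#' edge to 1 in the interior), which removes visible seams without ghosting.
#' Where overlapping tiles agree the fusion is exact (the weights cancel).
#'
#' With `refine = TRUE`, each tile's translation relative to its already
#' placed left (or top) neighbor is estimated by phase correlation on the
#' mean-over-channels image, searching integer shifts within +/- 25% of the
#' nominal overlap; registration never moves a tile further than that.
#'
#' @param grid A [tile_grid()].
#' @param refine Estimate per-tile translations by phase correlation
#'   (default `FALSE`: trust the nominal grid positions).
#' @return A [hyper_cube()] spanning the full grid extent. Provenance
#'   records `tile_origins` (placed origins, row-major n x 2) and
#'   `tile_offsets` (origins minus nominal positions).
#' @export
stitch_grid <- function(grid, refine = FALSE) {
  tiles <- grid$tiles
  rows <- grid$rows; cols <- grid$cols; v <- grid$overlap
  d <- dim(tiles[[1]]$data)
  th <- d[1]; tw <- d[2]; M <- d[3]
  H <- rows * th - (rows - 1L) * v
  W <- cols * tw - (cols - 1L) * v
  n <- rows * cols
  nominal <- matrix(0L, n, 2L)
  for (i in seq_len(rows)) for (j in seq_len(cols)) {
    t_idx <- (i - 1L) * cols + j
    nominal[t_idx, ] <- c((i - 1L) * (th - v) + 1L, (j - 1L) * (tw - v) + 1L)
  }
  origins <- nominal
  if (refine && n > 1L) {
    wmax <- as.integer(floor(0.25 * v))
    means <- lapply(tiles, function(t) rowMeans(t$data, dims = 2))
    for (i in seq_len(rows)) for (j in seq_len(cols)) {
      t_idx <- (i - 1L) * cols + j
      if (t_idx == 1L) next
      ref_idx <- if (j > 1L) t_idx - 1L else t_idx - cols
      # b(x) = a(x - s) with s = origin_ref - origin_tile
      s_nom <- origins[ref_idx, ] - nominal[t_idx, ]
      if (wmax > 0L) {
        cand <- as.matrix(expand.grid(s_nom[1] + (-wmax:wmax),
                                      s_nom[2] + (-wmax:wmax)))
        s_est <- phase_corr_shift(means[[ref_idx]], means[[t_idx]], cand)
      } else s_est <- s_nom
      origins[t_idx, ] <- origins[ref_idx, ] - s_est
    }
    origins[, 1] <- pmin(pmax(origins[, 1], 1L), H - th + 1L)
    origins[, 2] <- pmin(pmax(origins[, 2], 1L), W - tw + 1L)
  }
  ramp <- function(len) pmin(pmin(seq_len(len), rev(seq_len(len))), v + 1L) / (v + 1L)
  wt <- outer(ramp(th), ramp(tw))
  acc <- array(0, dim = c(H, W, M))
  wacc <- matrix(0, H, W)
  for (t_idx in seq_len(n)) {
    r0 <- origins[t_idx, 1]; c0 <- origins[t_idx, 2]
    rr <- r0:(r0 + th - 1L); cc <- c0:(c0 + tw - 1L)
    acc[rr, cc, ] <- acc[rr, cc, , drop = FALSE] +
      tiles[[t_idx]]$data * as.vector(wt)
    wacc[rr, cc] <- wacc[rr, cc] + wt
  }
  out <- acc / as.vector(pmax(wacc, 1e-12))
  hyper_cube(out, tiles[[1]]$axis, pixel_size_um = tiles[[1]]$pixel_size_um,
             provenance = list(stitched = TRUE, refined = isTRUE(refine),
                               tile_origins = origins,
                               tile_offsets = origins - nominal))
}
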
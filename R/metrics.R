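# valid-region windowed sums via an integral image
win_sum <- function(m, w) {
  H <- nrow(m); W <- ncol(m)
  cs <- apply(m, 2, cumsum)
  if (H == 1L) cs <- matrix(cs, 1L, W)
  cs <- t(apply(cs, 1, cumsum))
  if (W == 1L) cs <- matrix(cs, H, 1L)
  P <- matrix(0, H + 1L, W + 1L)
  P[2:(H + 1L), 2:(W + 1L)] <- cs
  ih <- seq_len(H - w + 1L); iw <- seq_len(W - w + 1L)
  P[ih + w, iw + w, drop = FALSE] - P[ih, iw + w, drop = FALSE] -
    P[ih + w, iw, drop = FALSE] + P[ih, iw, drop = FALSE]
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM over a sliding uniform window (default 7 x 7, valid
#' region only), with stabilizers C1 = (0.01 R)^2 and C2 = (0.03 R)^2 where
#' R is the data range, and unbiased (n-1) variance normalization.
#' Symmetric in its two arguments.
#'
#' @param a,b Numeric matrices of identical shape.
#' @param data_range Dynamic range R > 0 of the data.
#' @param win Odd window edge length (default 7; reduced automatically for
#'   images smaller than the window).
#' @return A single SSIM value in [-1, 1].
#' @export
ssim <- function(a, b, data_range, win = 7L) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)))
    stop("ssim: images must have the same shape", call. = FALSE)
  if (data_range <= 0) stop("ssim: data_range must be > 0", call. = FALSE)
  w <- min(win, dim(a))
  n <- w * w
  if (n < 2L) stop("ssim: window must contain at least 2 pixels", call. = FALSE)
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  mx <- win_sum(a, w) / n
  my <- win_sum(b, w) / n
  # unbiased second moments
  vx <- (win_sum(a * a, w) - n * mx^2) / (n - 1)
  vy <- (win_sum(b * b, w) - n * my^2) / (n - 1)
  cxy <- (win_sum(a * b, w) - n * mx * my) / (n - 1)
  s <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
       ((mx^2 + my^2 + c1) * (vx + vy + c2))
  mean(s)
}

#' Peak signal-to-noise ratio (PSNR)
#'
#' `10 * log10(R^2 / MSE)` in decibels; identical inputs give `Inf`.
#'
#' @inheritParams ssim
#' @return PSNR in dB (`Inf` for identical inputs).
#' @export
psnr <- function(a, b, data_range) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)))
    stop("psnr: images must have the same shape", call. = FALSE)
  if (data_range <= 0) stop("psnr: data_range must be > 0", call. = FALSE)
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

#' Quality report: per-component SSIM/PSNR against a reference
#'
#' Quantifies how well a set of concentration maps (e.g. from a reduced
#' channel subset) reproduces a reference set (e.g. the full-spectrum
#' result). The data range for each component is the maximum of the
#' *reference* map for that component, so PSNR stays comparable across
#' different channel subsets. Aggregates are unweighted means over
#' components.
#'
#' @param maps A [conc_maps()] to evaluate.
#' @param ref_maps The reference [conc_maps()] (same components, same size).
#' @return An object of class `quality_report`: list with `per_component`
#'   (data.frame: name, ssim, psnr_db, data_range), `mean_ssim`,
#'   `mean_psnr_db`.
#' @export
quality_report <- function(maps, ref_maps) {
  if (!identical(maps$names, ref_maps$names))
    stop("quality_report: component names differ", call. = FALSE)
  if (!all(dim(maps$data)[1:2] == dim(ref_maps$data)[1:2]))
    stop("quality_report: image sizes differ", call. = FALSE)
  K <- length(maps$names)
  res <- data.frame(name = maps$names, ssim = NA_real_, psnr_db = NA_real_,
                    data_range = NA_real_)
  for (k in seq_len(K)) {
    ref <- ref_maps$data[, , k]
    r <- max(ref)
    if (r <= 0) r <- 1  # empty reference component: fall back to unit range
    res$ssim[k] <- ssim(maps$data[, , k], ref, data_range = r)
    res$psnr_db[k] <- psnr(maps$data[, , k], ref, data_range = r)
    res$data_range[k] <- r
  }
  structure(list(per_component = res,
                 mean_ssim = mean(res$ssim),
                 mean_psnr_db = mean(res$psnr_db)),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report>\n")
  print(x$per_component, row.names = FALSE)
  cat(sprintf("mean SSIM %.4f, mean PSNR %.2f dB\n",
              x$mean_ssim, x$mean_psnr_db))
  invisible(x)
}
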
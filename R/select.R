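#' Balanced pixel-sampler parameters
#'
#' Recursive feature elimination is expensive, so channel selection runs on
#' a small pixel subset: `n_total` pixels split into `n_subsets` groups of
#' equal size, one group per dominant chemical component, each drawn
#' uniformly at random without replacement. Defaults follow the working
#' recipe of 2100 pixels in 5 component-balanced subsets of 420.
#'
#' @param n_total Total pixel budget (default 2100); must be divisible by
#'   `n_subsets`.
#' @param n_subsets Number of component-balanced subsets (default 5).
#' @param seed Integer RNG seed for the random draw (default 1).
#' @return An object of class `sampler_params`.
#' @export
sampler_params <- function(n_total = 2100, n_subsets = 5, seed = 1L) {
  n_total <- as.integer(n_total); n_subsets <- as.integer(n_subsets)
  if (n_total < 1L || n_subsets < 1L)
    stop("sampler_params: n_total and n_subsets must be positive", call. = FALSE)
  if (n_total %% n_subsets != 0L)
    stop("sampler_params: n_total must be divisible by n_subsets", call. = FALSE)
  structure(list(n_total = n_total, n_subsets = n_subsets,
                 seed = as.integer(seed)),
            class = "sampler_params")
}

#' Sample component-balanced pixels for channel selection
#'
#' Labels every pixel with its dominant component (the argmax of the
#' full-spectrum abundances; ties go to the first component in library
#' order) and draws `n_total / n_subsets` pixels per component uniformly
#' without replacement. The draw is reproducible from the seed and leaves
#' the caller's RNG state untouched.
#'
#' @param cube The [hyper_cube()] the maps came from (full channel set).
#' @param full_maps [conc_maps()] produced from `cube` with the full
#'   spectrum; `n_subsets` must equal its component count.
#' @param params A [sampler_params()].
#' @param roi Optional `c(r0, r1, c0, c1)` rectangle restricting the
#'   "representative field of view" sampled from (default: whole cube).
#' @return An object of class `pixel_sample`: list with `coordinates`
#'   (n x 2 matrix of row, col), `dominant_labels` (component index per
#'   pixel), `spectra` (M x n matrix), `full_abundances` (K x n matrix).
#' @export
sample_balanced_pixels <- function(cube, full_maps, params = sampler_params(),
                                   roi = NULL) {
  d <- dim(cube$data)
  K <- length(full_maps$names)
  if (params$n_subsets != K)
    stop(sprintf("sample_balanced_pixels: n_subsets (%d) must equal the number of components (%d)",
                 params$n_subsets, K), call. = FALSE)
  if (!all(dim(full_maps$data)[1:2] == d[1:2]))
    stop("sample_balanced_pixels: maps and cube sizes differ", call. = FALSE)
  A <- matrix(full_maps$data, nrow = d[1] * d[2])  # N x K
  labels <- max.col(A, ties.method = "first")
  in_roi <- rep(TRUE, d[1] * d[2])
  if (!is.null(roi)) {
    rr <- rep(seq_len(d[1]), times = d[2])
    cc <- rep(seq_len(d[2]), each = d[1])
    in_roi <- rr >= roi[1] & rr <= roi[2] & cc >= roi[3] & cc <= roi[4]
  }
  n_per <- params$n_total %/% params$n_subsets
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(params$seed)
  chosen <- integer(0)
  for (k in seq_len(K)) {
    pool <- which(labels == k & in_roi)
    if (length(pool) < n_per)
      stop(sprintf("sample_balanced_pixels: component '%s' dominates only %d pixels (need %d)",
                   full_maps$names[k], length(pool), n_per), call. = FALSE)
    chosen <- c(chosen, sort(sample(pool, n_per)))
  }
  rows <- ((chosen - 1L) %% d[1]) + 1L
  cols <- ((chosen - 1L) %/% d[1]) + 1L
  Y <- t(matrix(cube$data, nrow = d[1] * d[2])[chosen, , drop = FALSE])  # M x n
  structure(list(coordinates = cbind(row = rows, col = cols),
                 dominant_labels = labels[chosen],
                 spectra = Y,
                 full_abundances = t(A[chosen, , drop = FALSE])),
            class = "pixel_sample")
}

#' Recursive feature elimination over spectral channels
#'
#' Greedy backward selection: while more than `target_k` channels survive,
#' each surviving channel is tentatively removed, the sampled pixels are
#' re-unmixed on the remaining channels, and the mean squared error between
#' the resulting abundances and the full-spectrum abundances (unweighted
#' mean over pixels and components) is computed. The channel whose removal
#' yields the minimum MSE contributes least to the unmixing result and is
#' permanently discarded; ties break toward the lowest wavenumber. The
#' elimination trace records each step.
#'
#' @param sample A [pixel_sample()] from [sample_balanced_pixels()], with
#'   full-spectrum abundances.
#' @param library The full-spectrum [ref_library()].
#' @param params The [unmix_params()] used throughout (same lambda as the
#'   full-spectrum unmixing).
#' @param target_k Number of channels to keep (1 <= target_k <= M).
#' @return A [channel_subset()] with the surviving indices, their shifts and
#'   the per-step elimination trace.
#' @export
rfe_select <- function(sample, library, params = unmix_params(), target_k) {
  M <- ncol(library$spectra)
  target_k <- as.integer(target_k)
  if (target_k < 1L || target_k > M)
    stop("rfe_select: target_k must be between 1 and the channel count",
         call. = FALSE)
  if (nrow(sample$spectra) != M)
    stop("rfe_select: sample spectra do not match the library channels",
         call. = FALSE)
  current <- seq_len(M)
  trace <- data.frame(eliminated_index = integer(0),
                      eliminated_shift = numeric(0), mse = numeric(0))
  Cfull <- sample$full_abundances
  while (length(current) > target_k) {
    best_j <- NA_integer_; best_mse <- Inf
    for (j in current) {  # ascending = lowest wavenumber wins ties
      keep <- setdiff(current, j)
      C <- lasso_cd_cpp(library$spectra[, keep, drop = FALSE],
                        sample$spectra[keep, , drop = FALSE],
                        params$lam, params$nonneg, params$max_iters,
                        params$tol, warm = Cfull)
      mse <- mean((C - Cfull)^2)
      if (mse < best_mse) { best_mse <- mse; best_j <- j }
    }
    current <- setdiff(current, best_j)
    trace <- rbind(trace,
                   data.frame(eliminated_index = best_j,
                              eliminated_shift = as.numeric(library$axis)[best_j],
                              mse = best_mse))
  }
  channel_subset(current, library$axis, trace = trace)
}

#' Reconstruct the surviving subset at an intermediate RFE stage
#'
#' The elimination trace orders the discarded channels, so the subset that
#' was current when `k` channels survived is the parent axis minus the first
#' `M - k` eliminations. Useful for degradation ladders (e.g. scoring the
#' 45-, 20-, 10- and 5-channel results of one RFE run).
#'
#' @param subset A [channel_subset()] produced by [rfe_select()].
#' @param parent_axis The full [wn_axis()] the RFE ran on.
#' @param k Stage to reconstruct (`length(subset$indices) <= k <= M`).
#' @return A [channel_subset()] with `k` channels and the truncated trace.
#' @export
subset_at_k <- function(subset, parent_axis, k) {
  M <- length(parent_axis)
  k <- as.integer(k)
  if (k < length(subset$indices) || k > M)
    stop("subset_at_k: k must be between the final subset size and M",
         call. = FALSE)
  n_elim <- M - k
  elim <- subset$trace$eliminated_index[seq_len(n_elim)]
  channel_subset(setdiff(seq_len(M), elim), parent_axis,
                 trace = subset$trace[seq_len(n_elim), , drop = FALSE])
}

#' Unmix on a channel subset and score against the full-spectrum result
#'
#' Restricts the cube and library to the subset (library spectra are sliced,
#' not renormalized, so abundances stay on the full-spectrum scale), unmixes,
#' and returns per-component SSIM/PSNR against the full-spectrum maps.
#'
#' @param cube Full [hyper_cube()].
#' @param library Full-spectrum [ref_library()].
#' @param params [unmix_params()].
#' @param subset A [channel_subset()] (or integer indices).
#' @param full_maps Full-spectrum [conc_maps()] reference.
#' @return A [quality_report()].
#' @export
evaluate_subset <- function(cube, library, params, subset, full_maps) {
  rcube <- restrict_to_channels(cube, subset)
  rlib <- restrict_to_channels(library, subset)
  maps <- unmix_cube(rcube, rlib, params)
  quality_report(maps, full_maps)
}

#' Acquisition cost model and channel-reduction speed factor
#'
#' Acquisition cost is channels x pixels x dwell time; pixels and dwell
#' cancel in the ratio, so reducing the channel count from 45 to 5 speeds
#' acquisition by exactly 9x.
#'
#' @param n_channels Number of spectral channels acquired.
#' @param n_pixels Number of pixels per channel (default 1).
#' @param dwell_s Pixel dwell time in seconds (default 10e-6).
#' @return `acquisition_cost()`: total dwell-time cost in seconds;
#'   `acquisition_speedup()`: the dimensionless speed factor
#'   `full / reduced`.
#' @export
acquisition_cost <- function(n_channels, n_pixels = 1, dwell_s = 10e-6) {
  if (n_channels < 1 || n_pixels < 1 || dwell_s <= 0)
    stop("acquisition_cost: arguments must be positive", call. = FALSE)
  n_channels * n_pixels * dwell_s
}

#' @rdname acquisition_cost
#' @param full_channels,reduced_channels Channel counts being compared.
#' @export
acquisition_speedup <- function(full_channels, reduced_channels,
                                n_pixels = 1, dwell_s = 10e-6) {
  acquisition_cost(full_channels, n_pixels, dwell_s) /
    acquisition_cost(reduced_channels, n_pixels, dwell_s)
}
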
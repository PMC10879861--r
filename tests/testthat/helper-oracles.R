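# Independent oracles used to verify the package's solvers. These share no
# code with the implementation: the LASSO oracles work from first-order
# conditions (projected gradient, exhaustive support enumeration), the TV
# oracle does exact coordinate minimization on the dual, and the SSIM oracle
# evaluates the definition window by window.

# --- non-negative / signed LASSO oracles ------------------------------------

# projected (proximal) gradient on f(c) = ||y - t(A) %*% c||^2 + lam * sum|c|
pg_lasso_oracle <- function(A, y, lam, nonneg = TRUE, iters = 200000,
                            tol = 1e-14) {
  K <- nrow(A)
  G <- A %*% t(A)
  L <- 2 * max(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  eta <- 1 / L
  c0 <- rep(0, K)
  b <- as.numeric(A %*% y)
  for (i in seq_len(iters)) {
    grad <- 2 * (G %*% c0 - b)
    z <- c0 - eta * as.numeric(grad)
    if (nonneg) {
      cn <- pmax(z - eta * lam, 0)
    } else {
      cn <- sign(z) * pmax(abs(z) - eta * lam, 0)
    }
    if (max(abs(cn - c0)) < tol) { c0 <- cn; break }
    c0 <- cn
  }
  c0
}

# exhaustive support enumeration solving each KKT system (exact for small K)
active_set_lasso_oracle <- function(A, y, lam, nonneg = TRUE) {
  K <- nrow(A)
  G <- A %*% t(A)
  b <- as.numeric(A %*% y)
  obj <- function(c0) sum((y - as.numeric(t(A) %*% c0))^2) + lam * sum(abs(c0))
  best <- rep(0, K); best_obj <- obj(best)
  if (nonneg) {
    for (mask in 1:(2^K - 1)) {
      S <- which(bitwAnd(mask, 2^(0:(K - 1))) > 0)
      cS <- try(solve(G[S, S, drop = FALSE], b[S] - lam / 2), silent = TRUE)
      if (inherits(cS, "try-error")) next
      if (any(cS < 0)) next
      c0 <- rep(0, K); c0[S] <- cS
      o <- obj(c0)
      if (o < best_obj - 1e-15) { best_obj <- o; best <- c0 }
    }
  } else {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), K)))
    for (r in seq_len(nrow(signs))) {
      s <- signs[r, ]
      S <- which(s != 0)
      if (length(S) == 0) next
      cS <- try(solve(G[S, S, drop = FALSE], b[S] - (lam / 2) * s[S]),
                silent = TRUE)
      if (inherits(cS, "try-error")) next
      if (any(sign(cS) != s[S])) next
      c0 <- rep(0, K); c0[S] <- cS
      o <- obj(c0)
      if (o < best_obj - 1e-15) { best_obj <- o; best <- c0 }
    }
  }
  best
}

lasso_objective <- function(A, y, c0, lam)
  sum((y - as.numeric(t(A) %*% c0))^2) + lam * sum(abs(c0))

# --- 1-D total variation oracle ---------------------------------------------

# exact coordinate minimization on the dual of
#   min_u 0.5 * ||u - y||^2 + lam * sum |u[i+1] - u[i]|
# dual: min_p 0.5 * ||y - Dt(p)||^2, |p_i| <= lam, u = y - Dt(p)
tv1d_oracle <- function(y, lam, cycles = 200000, tol = 1e-15) {
  n <- length(y)
  if (n < 2 || lam == 0) return(y)
  p <- rep(0, n - 1)
  # Dt(p)[i] = p[i-1] - p[i] (p[0] = p[n] = 0)
  dtp <- function(p) c(0, p) - c(p, 0)
  for (cyc in seq_len(cycles)) {
    delta <- 0
    u <- y - dtp(p)
    for (i in seq_len(n - 1)) {
      # minimize over p_i alone: quadratic with curvature 2, gradient u[i+1]-u[i]
      pn <- p[i] + (u[i + 1] - u[i]) / 2
      pn <- min(max(pn, -lam), lam)
      d <- pn - p[i]
      if (d != 0) {
        u[i] <- u[i] + d
        u[i + 1] <- u[i + 1] - d
        p[i] <- pn
      }
      delta <- max(delta, abs(d))
    }
    if (delta < tol) break
  }
  y - dtp(p)
}

tv1d_objective <- function(u, y, lam) 0.5 * sum((u - y)^2) + lam * sum(abs(diff(u)))

# --- SSIM oracle -------------------------------------------------------------

# direct window-by-window evaluation of the SSIM definition
ssim_direct_oracle <- function(a, b, data_range, win = 7L) {
  c1 <- (0.01 * data_range)^2; c2 <- (0.03 * data_range)^2
  H <- nrow(a); W <- ncol(a)
  vals <- c()
  for (i in seq_len(H - win + 1L)) for (j in seq_len(W - win + 1L)) {
    x <- a[i:(i + win - 1L), j:(j + win - 1L)]
    y <- b[i:(i + win - 1L), j:(j + win - 1L)]
    mx <- mean(x); my <- mean(y)
    vx <- stats::var(as.numeric(x)); vy <- stats::var(as.numeric(y))
    cxy <- stats::cov(as.numeric(x), as.numeric(y))
    vals <- c(vals, ((2 * mx * my + c1) * (2 * cxy + c2)) /
                ((mx^2 + my^2 + c1) * (vx + vy + c2)))
  }
  mean(vals)
}

# --- planted RFE instance ----------------------------------------------------

# 3 components on 8 channels: channels 2, 5, 7 carry all inter-component
# contrast (values are permutations of one set, so row norms are equal and
# unit-norm normalization preserves the structure); the other 5 channels are
# identical across components.
planted_rfe_instance <- function(n_pixels = 60, noise_sd = 0.05, seed = 42) {
  ax <- srhmap::wn_axis(seq(2840, 3020, length.out = 8))
  S <- matrix(0.5, 3, 8)
  S[1, c(2, 5, 7)] <- c(0.9, 0.1, 0.1)
  S[2, c(2, 5, 7)] <- c(0.1, 0.9, 0.1)
  S[3, c(2, 5, 7)] <- c(0.1, 0.1, 0.9)
  lib <- srhmap::ref_library(S, ax, names = c("c1", "c2", "c3"))
  set.seed(seed)
  C_true <- matrix(runif(3 * n_pixels, 0, 1), 3, n_pixels)
  Y <- t(lib$spectra) %*% C_true +
    matrix(rnorm(8 * n_pixels, sd = noise_sd), 8, n_pixels)
  Y[Y < 0] <- 0
  list(lib = lib, Y = Y, contrast_channels = c(2L, 5L, 7L))
}

# exhaustive search over all size-k channel subsets by the RFE criterion:
# abundance MSE against the full-spectrum LASSO result
exhaustive_subset_oracle <- function(Y, lib, params, k) {
  M <- ncol(lib$spectra)
  Cfull <- srhmap:::lasso_cd_cpp(lib$spectra, Y, params$lam, params$nonneg,
                                 params$max_iters, params$tol)
  combs <- utils::combn(M, k)
  best <- NULL; best_mse <- Inf
  for (i in seq_len(ncol(combs))) {
    keep <- combs[, i]
    C <- srhmap:::lasso_cd_cpp(lib$spectra[, keep, drop = FALSE],
                               Y[keep, , drop = FALSE],
                               params$lam, params$nonneg,
                               params$max_iters, params$tol)
    mse <- mean((C - Cfull)^2)
    if (mse < best_mse - 1e-15) { best_mse <- mse; best <- keep }
  }
  list(subset = best, mse = best_mse)
}
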
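# Shared numeric helpers. Nothing here is specific to one pipeline stage.

#' Truncated geometric sequencing depths
#'
#' Draws per-site total read depths from a geometric distribution on
#' \{1, 2, ...\} with success probability `p` (mean `1/p`). Zero depths carry
#' no information, so the support starts at 1; this equals redrawing zeros
#' from the usual geometric on \{0, 1, ...\}.
#'
#' @param n Number of draws.
#' @param p Geometric success probability (default 0.01, mean depth 100).
#' @return Integer vector of depths, all `>= 1`.
#' @export
rdepth_geom <- function(n, p = 0.01) {
  stopifnot(p > 0, p <= 1)
  stats::rgeom(n, p) + 1L
}

#' Weighted kernel-density peaks
#'
#' Locates local maxima of a weighted kernel density estimate (Silverman
#' bandwidth) and discards maxima below `min_frac` of the global maximum.
#'
#' @param x Numeric values.
#' @param w Non-negative weights (recycled to `length(x)`).
#' @param min_frac Minimum peak height, as a fraction of the tallest peak.
#' @param min_sep Peaks closer than this are merged, keeping the taller one
#'   (0 disables).
#' @param bw Bandwidth passed to [stats::density()]; default Silverman.
#' @return data.frame with columns `x` (peak location, ascending) and `height`.
#' @export
density_peaks <- function(x, w = NULL, min_frac = 0.05, min_sep = 0,
                          bw = "nrd0") {
  keep <- is.finite(x)
  x <- x[keep]
  if (is.null(w)) w <- rep(1, length(x)) else w <- rep_len(w, length(keep))[keep]
  if (length(x) < 2L || sum(w) <= 0) {
    return(data.frame(x = numeric(0), height = numeric(0)))
  }
  d <- suppressWarnings(stats::density(x, weights = w / sum(w), bw = bw))
  y <- d$y
  n <- length(y)
  is_max <- y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf)
  is_max <- is_max & y >= min_frac * max(y)
  pk <- data.frame(x = d$x[is_max], height = y[is_max])
  if (min_sep > 0 && nrow(pk) > 1L) {
    repeat {
      gaps <- diff(pk$x)
      close <- which(gaps < min_sep)
      if (!length(close)) break
      i <- close[1L]
      drop <- if (pk$height[i] >= pk$height[i + 1L]) i + 1L else i
      pk <- pk[-drop, , drop = FALSE]
    }
  }
  pk
}

# Highest peak of a weighted density; NA when no peak is found.
density_mode <- function(x, w = NULL, bw = "nrd0") {
  pk <- density_peaks(x, w, min_frac = 0, bw = bw)
  if (nrow(pk) == 0L) return(NA_real_)
  pk$x[which.max(pk$height)]
}

#' Non-negative least squares
#'
#' Lawson-Hanson active-set solver for `min ||A x - b||` subject to `x >= 0`.
#' Used for mutational-signature fitting; small problems only.
#'
#' @param A Numeric matrix (m x n).
#' @param b Numeric vector of length m.
#' @param tol Convergence tolerance on the dual feasibility check.
#' @return List with `x` (coefficients) and `residual` (Euclidean norm).
#' @export
nnls_fit <- function(A, b, tol = 1e-10) {
  A <- as.matrix(A)
  stopifnot(length(b) == nrow(A))
  n <- ncol(A)
  x <- numeric(n)
  passive <- rep(FALSE, n)
  w <- crossprod(A, b - A %*% x)
  iter <- 0L
  while (any(!passive & w > tol) && iter < 30L * n) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      z[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      z[is.na(z)] <- 0
      if (all(z[passive] > tol)) {
        x <- z
        break
      }
      neg <- passive & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive <- passive & x > tol
      x[!passive] <- 0
    }
    w <- crossprod(A, b - A %*% x)
  }
  list(x = as.numeric(x), residual = sqrt(sum((b - A %*% x)^2)))
}

# Polynomial rolling hash of a character scalar (31-bit, hex string). Used
# to stamp output headers with a configuration fingerprint without pulling
# in a hashing dependency; not cryptographic.
fnv1a_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# Weighted median (type-agnostic, interpolation-free).
weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]
  w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1L]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
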
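# Internal numeric helpers shared across modules.

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards so simulations are reproducible without side
# effects on the session RNG.
withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up in magnitude (the convention used
#' when comparing derived quantities against values printed at fixed
#' precision), unlike \code{round()}'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (may be negative).
#' @return rounded numeric vector.
#' @examples
#' roundHalfUp(0.0745, 3)  # 0.075
#' roundHalfUp(8.5, 0)     # 9
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  # tiny cushion absorbs representation error of values that are exact
  # halves in decimal but not in binary
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# 0-based pixel-centre coordinate grids, in px.
pixelGrid <- function(shape) {
  list(x = matrix(rep(0:(shape[2] - 1L), each = shape[1]), shape[1]),
       y = matrix(rep(0:(shape[1] - 1L), times = shape[2]), shape[1]))
}

# Add an isotropic 2D Gaussian spot of integrated intensity `photons`
# centred at 0-based pixel coordinates (xPx, yPx). Only a window of
# +-6 sigma is touched.
renderSpot <- function(mat, xPx, yPx, sigmaPx, photons) {
  h <- nrow(mat); w <- ncol(mat)
  r <- ceiling(6 * sigmaPx)
  cx <- max(0L, floor(xPx - r)):min(w - 1L, ceiling(xPx + r))
  cy <- max(0L, floor(yPx - r)):min(h - 1L, ceiling(yPx + r))
  if (!length(cx) || !length(cy)) return(mat)
  gx <- exp(-(cx - xPx)^2 / (2 * sigmaPx^2))
  gy <- exp(-(cy - yPx)^2 / (2 * sigmaPx^2))
  amp <- photons / (2 * pi * sigmaPx^2)
  mat[cy + 1L, cx + 1L] <- mat[cy + 1L, cx + 1L] + amp * outer(gy, gx)
  mat
}

# Anisotropic Gaussian spot with principal axes rotated by thetaRad
# (counter-clockwise from +x); sigmaXPx is the width along the rotated x
# axis, sigmaYPx along the rotated y axis.
renderAnisoSpot <- function(mat, xPx, yPx, sigmaXPx, sigmaYPx, thetaRad,
                            photons) {
  h <- nrow(mat); w <- ncol(mat)
  r <- ceiling(6 * max(sigmaXPx, sigmaYPx))
  cx <- max(0L, floor(xPx - r)):min(w - 1L, ceiling(xPx + r))
  cy <- max(0L, floor(yPx - r)):min(h - 1L, ceiling(yPx + r))
  if (!length(cx) || !length(cy)) return(mat)
  dx <- outer(rep(1, length(cy)), cx - xPx)
  dy <- outer(cy - yPx, rep(1, length(cx)))
  u <- cos(thetaRad) * dx + sin(thetaRad) * dy
  v <- -sin(thetaRad) * dx + cos(thetaRad) * dy
  amp <- photons / (2 * pi * sigmaXPx * sigmaYPx)
  mat[cy + 1L, cx + 1L] <- mat[cy + 1L, cx + 1L] +
    amp * exp(-u^2 / (2 * sigmaXPx^2) - v^2 / (2 * sigmaYPx^2))
  mat
}

# Apply the camera noise model: Poisson photon noise on signal plus
# background, then additive Gaussian read noise.
applyCameraNoise <- function(expected, readNoiseSd) {
  n <- length(expected)
  out <- matrix(rpois(n, pmax(expected, 0)), nrow(expected))
  if (readNoiseSd > 0) out <- out + matrix(rnorm(n, 0, readNoiseSd),
                                           nrow(expected))
  out
}

# Inverse-mapped bilinear resampling implementing a rigid rotation plus
# isotropic scaling about a given input centre. Output pixel (u, v)
# relative to the output-image centre samples the input at
#   centerIn + R(angleRad) %*% c(u, v) / scale.
# Pixels mapping outside the input are 0.
warpRigidScale <- function(img, centerIn, angleRad, scale, outDim = dim(img)) {
  h <- outDim[1]; w <- outDim[2]
  ocx <- (w - 1) / 2; ocy <- (h - 1) / 2
  u <- matrix(rep(0:(w - 1L) - ocx, each = h), h) / scale
  v <- matrix(rep(0:(h - 1L) - ocy, times = w), h) / scale
  xs <- centerIn[1] + cos(angleRad) * u - sin(angleRad) * v
  ys <- centerIn[2] + sin(angleRad) * u + cos(angleRad) * v
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  ih <- nrow(img); iw <- ncol(img)
  sample0 <- function(xi, yi) {
    ok <- xi >= 0 & xi <= iw - 1L & yi >= 0 & yi <= ih - 1L
    val <- numeric(length(xi))
    val[ok] <- img[cbind(yi[ok] + 1L, xi[ok] + 1L)]
    val
  }
  out <- (1 - fx) * (1 - fy) * sample0(x0, y0) +
    fx * (1 - fy) * sample0(x0 + 1L, y0) +
    (1 - fx) * fy * sample0(x0, y0 + 1L) +
    fx * fy * sample0(x0 + 1L, y0 + 1L)
  matrix(out, h, w)
}

# adjusted R-squared: 1 - (1 - R2) (n - 1) / (n - p - 1)
adjustedR2 <- function(observed, fitted, nParams, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(observed))
  rss <- sum(weights * (observed - fitted)^2)
  mu <- sum(weights * observed) / sum(weights)
  tss <- sum(weights * (observed - mu)^2)
  n <- length(observed)
  r2 <- 1 - rss / tss
  1 - (1 - r2) * (n - 1) / (n - nParams - 1)
}

# Multi-start nlsLM wrapper: tries each start list, keeps the converged fit
# with the lowest deviance; NULL when nothing converges.
bestNlsFit <- function(formula, data, starts, weights = NULL, lower = NULL) {
  best <- NULL
  if (!is.null(weights)) data$.fitWeights <- weights
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200)
  for (st in starts) {
    fit <- suppressWarnings(tryCatch(
      if (is.null(weights))
        minpack.lm::nlsLM(formula, data = data, start = st, lower = lower,
                          control = ctrl)
      else
        minpack.lm::nlsLM(formula, data = data, start = st,
                          weights = .fitWeights, lower = lower,
                          control = ctrl),
      error = function(e) NULL))
    if (!is.null(fit) &&
        (is.null(best) || deviance(fit) < deviance(best))) best <- fit
  }
  best
}
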
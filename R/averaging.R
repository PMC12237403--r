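# Axial (row) centre of mass restricted to signal support: pixels below
# median + 3 MAD -- the background plus its noise floor -- are zeroed, so a
# faint uniform background cannot drag the centre of mass towards the image
# centre. The truncation is symmetric about the band and leaves its centre
# unbiased.
.supportCom <- function(m) {
  m <- pmax(m - (stats::median(m) + 3 * stats::mad(m)), 0)
  s <- sum(m)
  if (s <= 0) return(NA_real_)
  sum(rowSums(m) * (0:(nrow(m) - 1))) / s
}

#' Side-average a stack of annotated ministack images
#'
#' Registers and averages ministacks seen edge-on. Each image is, in one
#' bilinear resampling pass: rotated so its double-punctum axis is
#' horizontal (the cis-to-trans axis then runs down the image), rescaled so
#' the punctum separation matches the reference separation (the median
#' across the stack unless given), and aligned on the punctum midpoint.
#' After warping, images whose cis-marker centre of mass falls below the
#' trans marker's are flipped vertically (the cis side points up by
#' convention), each channel is normalized to a maximum of 1, and the
#' pixelwise mean is taken. Images with coincident puncta are skipped and
#' counted.
#'
#' @param stack a \linkS4class{SideViewStack}.
#' @param referenceSepPx reference punctum separation in px; default the
#'   median separation across the stack.
#' @param outDim output (height, width); default the first image's size.
#' @param orientChannels length-2 character: the channels whose centres of
#'   mass define the up-down orientation, cis-side first; set \code{NULL}
#'   to disable flipping.
#' @return a \linkS4class{SideAverageImage}; attribute \code{"nSkipped"}
#'   counts degenerate images.
#' @examples
#' sim <- simulateSideViewStack(nImages = 6, noise = FALSE, seed = 5)
#' avg <- sideAverage(sim$stack)
#' axialPositions(avg)
#' @export
sideAverage <- function(stack, referenceSepPx = NULL, outDim = NULL,
                        orientChannels = c("cis", "trans")) {
  stopifnot(is(stack, "SideViewStack"))
  ann <- stack@annotations
  sep <- sqrt((ann$x2 - ann$x1)^2 + (ann$y2 - ann$y1)^2)
  usable <- sep > 0
  if (!any(usable)) stop("no image with a non-degenerate punctum axis")
  if (is.null(referenceSepPx)) referenceSepPx <- stats::median(sep[usable])
  if (is.null(outDim)) outDim <- dim(stack@images[[1]])[1:2]
  channels <- stack@channels
  doFlip <- !is.null(orientChannels) && all(orientChannels %in% channels)
  acc <- array(0, c(outDim, length(channels)))
  n <- 0L
  for (i in seq_along(stack@images)) {
    if (!usable[i]) next
    mid <- c((ann$x1[i] + ann$x2[i]) / 2, (ann$y1[i] + ann$y2[i]) / 2)
    angle <- atan2(ann$y2[i] - ann$y1[i], ann$x2[i] - ann$x1[i])
    scale <- referenceSepPx / sep[i]
    warped <- array(0, c(outDim, length(channels)))
    for (k in seq_along(channels))
      warped[, , k] <- warpRigidScale(stack@images[[i]][, , k], mid, angle,
                                      scale, outDim)
    if (doFlip) {
      yCom <- function(ch) .supportCom(warped[, , match(ch, channels)])
      y1 <- yCom(orientChannels[1]); y2 <- yCom(orientChannels[2])
      if (is.finite(y1) && is.finite(y2) && y1 > y2)
        warped <- warped[rev(seq_len(outDim[1])), , , drop = FALSE]
    }
    for (k in seq_along(channels)) {
      mx <- max(warped[, , k])
      if (mx > 0) warped[, , k] <- warped[, , k] / mx
    }
    acc <- acc + warped
    n <- n + 1L
  }
  avg <- acc / n
  axial <- vapply(seq_along(channels), function(k)
    .supportCom(avg[, , k]) * stack@pixelSizeNm, numeric(1))
  names(axial) <- channels
  out <- new("SideAverageImage", data = avg, channels = channels,
             pixelSizeNm = stack@pixelSizeNm, nAveraged = n,
             axialYNm = axial)
  attr(out, "nSkipped") <- sum(!usable)
  out
}

#' Side-view localization quotient
#'
#' The approximate LQ read from axial centre-of-mass positions in a side
#' average: \eqn{LQ^{side} = (y_{cargo} - y_{GM130}) /
#' (y_{GalT} - y_{GM130})}.
#'
#' @param yCargo,yGm130,yGalt axial positions in nm (any common origin).
#' @return dimensionless LQ.
#' @examples
#' lqSide(250, 100, 400)  # 0.5
#' @export
lqSide <- function(yCargo, yGm130, yGalt) {
  if (any(yGalt == yGm130))
    stop("degenerate axis: trans and cis axial positions coincide")
  (yCargo - yGm130) / (yGalt - yGm130)
}

#' Axial line intensity profile of a side average
#'
#' Sums each channel across the lateral (column) dimension, giving summed
#' intensity versus axial position in nm (from the top row).
#'
#' @param avg a \linkS4class{SideAverageImage}.
#' @param channel channel role.
#' @return data.frame \code{axial_nm, intensity}.
#' @export
axialProfile <- function(avg, channel) {
  m <- channelMatrix(avg, channel)
  data.frame(axial_nm = (0:(nrow(m) - 1)) * avg@pixelSizeNm,
             intensity = rowSums(m))
}

#' Fit a Gaussian peak to an axial profile
#'
#' Single Gaussian plus constant baseline by least squares; the fitted
#' centre Xc is the axial position of the profiled marker.
#'
#' @param profile data.frame \code{axial_nm, intensity} with at least 5
#'   points.
#' @return a \linkS4class{GaussianPeakFit}.
#' @examples
#' x <- seq(0, 900, by = 45)
#' prof <- data.frame(axial_nm = x,
#'                    intensity = 2 + exp(-(x - 300)^2 / (2 * 120^2)))
#' fitAxialGaussian(prof)@centerNm
#' @export
fitAxialGaussian <- function(profile) {
  if (nrow(profile) < 5) stop("at least 5 profile points are required")
  d <- data.frame(x = profile$axial_nm, y = profile$intensity)
  amp0 <- max(d$y) - min(d$y)
  if (amp0 <= 0 || !is.finite(amp0))
    stop("profile has no peak to fit")
  wt <- pmax(d$y - min(d$y), 0)
  xc0 <- sum(wt * d$x) / sum(wt)
  w0 <- sqrt(sum(wt * (d$x - xc0)^2) / sum(wt))
  if (!is.finite(w0) || w0 <= 0) w0 <- diff(range(d$x)) / 6
  starts <- lapply(c(0.5, 1, 2), function(f)
    list(amp = amp0, xc = xc0, w = w0 * f, base = min(d$y)))
  fit <- bestNlsFit(y ~ base + amp * exp(-(x - xc)^2 / (2 * w^2)), d,
                    starts, lower = c(0, -Inf, 1e-9, -Inf))
  if (is.null(fit)) stop("axial Gaussian fit did not converge")
  cf <- coef(fit)
  new("GaussianPeakFit", centerNm = unname(cf["xc"]),
      widthNm = abs(unname(cf["w"])), amplitude = unname(cf["amp"]),
      baseline = unname(cf["base"]),
      adjR2 = adjustedR2(d$y, fitted(fit), 4))
}

#' Axial distance between two fitted markers
#'
#' Signed difference of Gaussian peak centres,
#' \eqn{d = Xc_b - Xc_a}; e.g. \code{markerDistance(gm130Fit, galtFit)}
#' gives the GM130-to-GalT stack axis length.
#'
#' @param fitA,fitB \linkS4class{GaussianPeakFit} objects.
#' @return distance in nm (antisymmetric in its arguments).
#' @export
markerDistance <- function(fitA, fitB) {
  fitB@centerNm - fitA@centerNm
}

#' En-face average of ring-annotated ministack images
#'
#' Each image is translated so its giantin ring centre sits at the image
#' centre and rescaled so the ring radius matches the reference radius
#' (median across images unless given), then per-channel max-normalized
#' and averaged pixelwise. Images with non-positive radius are skipped
#' and counted.
#'
#' @param images list of h x w x channel arrays (or matrices).
#' @param annotations data.frame \code{image_id, cx, cy, r} in 0-based px.
#' @param referenceRadiusPx reference ring radius; default median.
#' @param outDim output size; default the first image's.
#' @return list \code{image} (averaged array), \code{nAveraged},
#'   \code{nSkipped}, \code{referenceRadiusPx}.
#' @export
enFaceAverage <- function(images, annotations, referenceRadiusPx = NULL,
                          outDim = NULL) {
  if (length(images) != nrow(annotations))
    stop("one annotation row per image is required")
  images <- lapply(images, function(m)
    if (is.matrix(m)) array(m, c(dim(m), 1L)) else m)
  usable <- annotations$r > 0
  if (!any(usable)) stop("no image with a positive ring radius")
  if (is.null(referenceRadiusPx))
    referenceRadiusPx <- stats::median(annotations$r[usable])
  if (is.null(outDim)) outDim <- dim(images[[1]])[1:2]
  nCh <- dim(images[[1]])[3]
  acc <- array(0, c(outDim, nCh))
  n <- 0L
  for (i in seq_along(images)) {
    if (!usable[i]) next
    scale <- referenceRadiusPx / annotations$r[i]
    for (k in seq_len(nCh)) {
      w <- warpRigidScale(images[[i]][, , k],
                          c(annotations$cx[i], annotations$cy[i]), 0,
                          scale, outDim)
      mx <- max(w)
      if (mx > 0) w <- w / mx
      acc[, , k] <- acc[, , k] + w
    }
    n <- n + 1L
  }
  list(image = acc / n, nAveraged = n, nSkipped = sum(!usable),
       referenceRadiusPx = referenceRadiusPx)
}

#' Radial mean intensity profile
#'
#' Mean intensity in concentric one-pixel annuli about a centre, with the
#' radius normalized to the ring marker's radius and the intensity to a
#' maximum of 1.
#'
#' @param img numeric matrix (one channel, e.g. of an en-face average).
#' @param center 0-based (cx, cy) in px; default the image centre.
#' @param ringRadiusPx normalizing radius in px.
#' @param maxRadiusPx outermost annulus; default the largest full circle.
#' @return data.frame \code{radius_norm, intensity} with the radius grid
#'   starting at 0.
#' @export
radialMeanProfile <- function(img, center = NULL, ringRadiusPx,
                              maxRadiusPx = NULL) {
  if (ringRadiusPx <= 0) stop("ringRadiusPx must be positive")
  h <- nrow(img); w <- ncol(img)
  if (is.null(center)) center <- c((w - 1) / 2, (h - 1) / 2)
  if (is.null(maxRadiusPx))
    maxRadiusPx <- floor(min(center[1], w - 1 - center[1],
                             center[2], h - 1 - center[2]))
  g <- pixelGrid(c(h, w))
  r <- sqrt((g$x - center[1])^2 + (g$y - center[2])^2)
  bin <- round(r)
  keep <- bin <= maxRadiusPx
  means <- tapply(img[keep], bin[keep], mean)
  rad <- as.numeric(names(means))
  data.frame(radius_norm = rad / ringRadiusPx,
             intensity = as.numeric(means) / max(means))
}
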
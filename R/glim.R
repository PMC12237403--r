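#' Detect ministack ROIs in a multi-channel image
#'
#' Candidate ministacks are local maxima of a Gaussian-smoothed
#' sum-of-channels image above a robust threshold
#' (median + \code{thresholdK} * MAD). Each candidate receives a fixed
#' square box of half-width \code{boxRadiusPx}; boxes clipping the image
#' border are dropped, and both members of any overlapping pair are
#' discarded (conservative tie-break), with counts reported as attributes.
#'
#' @param image a \linkS4class{MinistackImage} with channels
#'   \code{cis, trans, cargo} (bead fields are accepted too).
#' @param smoothSigmaPx smoothing sigma in px.
#' @param boxRadiusPx ROI half-width in px.
#' @param thresholdK MAD multiplier of the detection threshold.
#' @return data.frame of ROIs with 0-based half-open pixel bounds
#'   \code{stack_id, x0, x1, y0, y1}; attributes \code{nBorderDropped} and
#'   \code{nOverlapDropped} count discarded candidates.
#' @examples
#' sim <- simulateMinistackField(simulationConfig(nStacks = 5, seed = 1))
#' nrow(detectROIs(sim$image))
#' @export
detectROIs <- function(image, smoothSigmaPx = 2, boxRadiusPx = 11,
                       thresholdK = 8) {
  stopifnot(is(image, "MinistackImage"))
  s <- Reduce(`+`, lapply(channelRoles(image),
                          function(ch) channelMatrix(image, ch)))
  s <- EBImage::gblur(s, sigma = smoothSigmaPx)
  thr <- stats::median(s) + thresholdK * stats::mad(s)
  h <- nrow(s); w <- ncol(s)
  # strict 3x3 local maxima above threshold (border excluded)
  core <- s[2:(h - 1), 2:(w - 1)]
  isMax <- core > thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0) next
    isMax <- isMax & core > s[2:(h - 1) + dy, 2:(w - 1) + dx]
  }
  idx <- which(isMax, arr.ind = TRUE)
  if (!nrow(idx)) {
    out <- data.frame(stack_id = integer(0), x0 = integer(0),
                      x1 = integer(0), y0 = integer(0), y1 = integer(0))
    attr(out, "nBorderDropped") <- 0L
    attr(out, "nOverlapDropped") <- 0L
    return(out)
  }
  cy <- idx[, 1]  # 0-based peak coordinates
  cx <- idx[, 2]
  r <- as.integer(boxRadiusPx)
  box <- data.frame(x0 = cx - r, x1 = cx + r + 1L,
                    y0 = cy - r, y1 = cy + r + 1L)
  inside <- box$x0 >= 0 & box$y0 >= 0 & box$x1 <= w & box$y1 <= h
  nBorder <- sum(!inside)
  box <- box[inside, , drop = FALSE]
  n <- nrow(box)
  keep <- rep(TRUE, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (box$x0[i] < box$x1[j] && box$x0[j] < box$x1[i] &&
          box$y0[i] < box$y1[j] && box$y0[j] < box$y1[i]) {
        keep[i] <- FALSE; keep[j] <- FALSE
      }
    }
  }
  out <- box[keep, , drop = FALSE]
  out <- cbind(stack_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "nBorderDropped") <- nBorder
  attr(out, "nOverlapDropped") <- sum(!keep)
  out
}

#' Subtract the local background of an ROI
#'
#' The background is estimated per channel as the median of the one-pixel-
#' wide border ring of the ROI and subtracted; negative results are clamped
#' to zero.
#'
#' @param pixels numeric matrix or h x w x channel array of ROI pixels.
#' @return object of the same shape, background-subtracted.
#' @examples
#' subtractBackground(matrix(5, 7, 7))  # all zeros
#' @export
subtractBackground <- function(pixels) {
  one <- function(m) {
    ring <- c(m[1, ], m[nrow(m), ], m[2:(nrow(m) - 1), 1],
              m[2:(nrow(m) - 1), ncol(m)])
    pmax(m - stats::median(ring), 0)
  }
  if (is.matrix(pixels)) return(one(pixels))
  for (k in seq_len(dim(pixels)[3])) pixels[, , k] <- one(pixels[, , k])
  pixels
}

#' Intensity-weighted centre of mass of an ROI
#'
#' The centre of mass of background-subtracted pixels, as the intensity-
#' weighted mean of 0-based pixel-centre coordinates scaled to nm.
#'
#' @param pixels numeric matrix (one channel of an ROI).
#' @param pixelSizeNm pixel size in nm.
#' @param originPx optional 0-based (x, y) pixel offset of the ROI within
#'   its parent image, added before scaling.
#' @return list \code{x_nm, y_nm, intensity, valid}; \code{valid} is
#'   \code{FALSE} (a QC failure, not an error) when total intensity is
#'   not positive.
#' @examples
#' centerOfMass(matrix(1, 5, 5), 65)  # geometric centre (130, 130) nm
#' @export
centerOfMass <- function(pixels, pixelSizeNm, originPx = c(0, 0)) {
  tot <- sum(pixels)
  if (!is.finite(tot) || tot <= 0)
    return(list(x_nm = NA_real_, y_nm = NA_real_, intensity = 0,
                valid = FALSE))
  xs <- 0:(ncol(pixels) - 1L)
  ys <- 0:(nrow(pixels) - 1L)
  list(x_nm = (sum(colSums(pixels) * xs) / tot + originPx[1]) * pixelSizeNm,
       y_nm = (sum(rowSums(pixels) * ys) / tot + originPx[2]) * pixelSizeNm,
       intensity = tot, valid = TRUE)
}

# Iteratively re-centred sub-pixel centroid: the measurement window is
# re-placed on the previous centroid estimate so that a spot displaced from
# the initial box centre (e.g. by chromatic shift) is not truncated
# asymmetrically.
.refinedCentroid <- function(m, cxPx, cyPx, rPx, iters = 3L) {
  h <- nrow(m); w <- ncol(m)
  for (it in seq_len(iters)) {
    x0 <- min(max(round(cxPx) - rPx, 0L), w - 2L * rPx - 1L)
    y0 <- min(max(round(cyPx) - rPx, 0L), h - 2L * rPx - 1L)
    crop <- m[(y0 + 1):(y0 + 2 * rPx + 1), (x0 + 1):(x0 + 2 * rPx + 1)]
    cm <- centerOfMass(subtractBackground(crop), 1, c(x0, y0))
    if (!cm$valid) return(cm)
    cxPx <- cm$x_nm; cyPx <- cm$y_nm
  }
  cm
}

.beadCentroids <- function(image, rois, r) {
  channels <- channelRoles(image)
  res <- lapply(channels, function(ch) {
    m <- channelMatrix(image, ch)
    t(vapply(seq_len(nrow(rois)), function(i) {
      cm <- .refinedCentroid(m, (rois$x0[i] + rois$x1[i] - 1) / 2,
                             (rois$y0[i] + rois$y1[i] - 1) / 2, r)
      c(cm$x_nm, cm$y_nm, cm$intensity)
    }, numeric(3)))
  })
  names(res) <- channels
  res
}

#' Fit a chromatic aberration model from a bead field
#'
#' Beads are detected on the reference channel; each bead's sub-pixel
#' centroid is measured in every channel inside the same box (nearest-
#' neighbour matching by construction). The default model is a per-channel
#' least-squares translation; \code{model = "affine"} additionally fits
#' linear terms.
#'
#' @param beadImage a multi-channel \linkS4class{MinistackImage} of beads.
#' @param reference reference channel role.
#' @param model \code{"translation"} or \code{"affine"}.
#' @param windowRadiusPx half-width of the per-bead centroid window; kept
#'   tight (~2.5 spot sigma) so background noise contributes little
#'   centroid variance.
#' @param ... passed to \code{\link{detectROIs}}.
#' @return a \linkS4class{ChromaticModel}.
#' @export
fitChromaticModel <- function(beadImage, reference = "cis",
                              model = c("translation", "affine"),
                              windowRadiusPx = 6L, ...) {
  model <- match.arg(model)
  rois <- detectROIs(beadImage, ...)
  if (nrow(rois) < 3)
    stop("chromatic calibration needs >= 3 matched beads, found ",
         nrow(rois))
  cents <- .beadCentroids(beadImage, rois, as.integer(windowRadiusPx))
  channels <- channelRoles(beadImage)
  if (!reference %in% channels) stop("reference channel not present")
  ref <- cents[[reference]][, 1:2, drop = FALSE]
  shifts <- matrix(0, length(channels), 2,
                   dimnames = list(channels, c("dx", "dy")))
  affine <- list()
  rms <- setNames(numeric(length(channels)), channels)
  for (ch in channels) {
    pts <- cents[[ch]][, 1:2, drop = FALSE]
    if (ch == reference) { rms[ch] <- 0; next }
    if (model == "translation") {
      shifts[ch, ] <- colMeans(pts - ref)
      resid <- sweep(pts, 2, shifts[ch, ]) - ref
    } else {
      X <- cbind(1, pts)
      coef <- qr.solve(X, ref)  # maps channel coords into reference frame
      affine[[ch]] <- coef
      shifts[ch, ] <- -(colMeans(X %*% coef) - colMeans(pts))
      resid <- X %*% coef - ref
    }
    rms[ch] <- sqrt(mean(rowSums(resid^2) / 2))
  }
  new("ChromaticModel", reference = reference, model = model,
      shiftsPx = shifts, affineCoef = affine, residualRmsPx = rms,
      nBeads = nrow(rois))
}

#' Map coordinates into the reference channel frame
#'
#' @param chromModel a \linkS4class{ChromaticModel}.
#' @param coordsPx n x 2 matrix (or length-2 vector) of 0-based pixel
#'   coordinates measured in \code{channel}.
#' @param channel the channel the coordinates were measured in.
#' @return corrected coordinates, same shape as the input.
#' @export
correctCoordinates <- function(chromModel, coordsPx, channel) {
  vec <- is.null(dim(coordsPx))
  if (vec) coordsPx <- matrix(coordsPx, 1)
  if (!channel %in% rownames(chromModel@shiftsPx))
    stop("channel '", channel, "' not in the chromatic model")
  out <- if (chromModel@model == "affine" &&
             !is.null(chromModel@affineCoef[[channel]])) {
    cbind(1, coordsPx) %*% chromModel@affineCoef[[channel]]
  } else {
    sweep(coordsPx, 2, chromModel@shiftsPx[channel, ])
  }
  if (vec) out[1, ] else out
}

#' Localization quotient of a centroid triplet
#'
#' With displacement vectors \eqn{a = cargo - cis} and
#' \eqn{b = trans - cis}, the LQ is the signed projection
#' \eqn{(a \cdot b) / (b \cdot b)}: the cargo's position along the
#' cis-to-trans axis in units of the axis length. The cis marker (GM130)
#' is 0 and the trans marker (GalT-mCherry) is 1 by construction; values
#' below 0 or above 1 place the cargo before or beyond the stack.
#'
#' @param cargo,cis,trans length-2 (x, y) coordinates in nm, chromatic
#'   correction already applied.
#' @return list \code{lq}, \code{d_axis_nm} (axis length |b|) and
#'   \code{valid} (\code{FALSE} when the axis is degenerate).
#' @examples
#' computeLQ(c(80, -20), c(0, 0), c(60, 80))$lq  # 0.32
#' @export
computeLQ <- function(cargo, cis, trans) {
  b <- trans - cis
  bb <- sum(b * b)
  if (!is.finite(bb) || bb == 0)
    return(list(lq = NA_real_, d_axis_nm = 0, valid = FALSE))
  list(lq = sum((cargo - cis) * b) / bb, d_axis_nm = sqrt(bb), valid = TRUE)
}

#' Flag analyzable LQ records
#'
#' A ministack passes QC when its cis-to-trans axis length lies within
#' \code{[minAxisNm, maxAxisNm]} and all three channel intensities reach
#' \code{minIntensity}. The defaults (70-1000 nm) demand an axis clearly
#' above the localization error yet below plausible inter-stack spacing.
#'
#' @param records data.frame with columns \code{d_axis_nm} and
#'   \code{intensity_cis, intensity_trans, intensity_cargo} (intensity
#'   columns optional).
#' @param minAxisNm,maxAxisNm axis length gates in nm.
#' @param minIntensity minimum integrated intensity per channel.
#' @return \code{records} with a logical \code{pass_qc} column.
#' @export
filterAnalyzable <- function(records, minAxisNm = 70, maxAxisNm = 1000,
                             minIntensity = 0) {
  ok <- is.finite(records$d_axis_nm) & records$d_axis_nm >= minAxisNm &
    records$d_axis_nm <= maxAxisNm
  for (col in c("intensity_cis", "intensity_trans", "intensity_cargo"))
    if (col %in% names(records))
      ok <- ok & is.finite(records[[col]]) & records[[col]] > 0 &
        records[[col]] >= minIntensity
  records$pass_qc <- ok
  records
}

#' Classify an LQ into a Golgi region
#'
#' Lower-inclusive half-open zones along the cis-to-trans axis:
#' ERES/ERGIC (LQ < -0.25), cis (-0.25 <= LQ < 0.25), medial
#' (0.25 <= LQ < 0.75), trans-Golgi (0.75 <= LQ < 1.25) and TGN
#' (LQ >= 1.25).
#'
#' @param lq numeric vector of finite LQs.
#' @return factor with levels \code{ERES_ERGIC, CIS, MEDIAL, TRANS, TGN}.
#' @examples
#' classifyRegion(c(-0.3, 0.4, 1.25))
#' @export
classifyRegion <- function(lq) {
  if (any(!is.finite(lq))) stop("LQ values must be finite")
  cut(lq, c(-Inf, -0.25, 0.25, 0.75, 1.25, Inf), right = FALSE,
      labels = c("ERES_ERGIC", "CIS", "MEDIAL", "TRANS", "TGN"))
}

#' Measure LQs for every ministack in an image
#'
#' End-to-end GLIM measurement: ROI detection (unless ROIs are supplied),
#' per-ROI border-ring background subtraction, per-channel sub-pixel
#' centres of mass, optional chromatic correction, LQ computation and
#' analyzability filtering.
#'
#' @param image a three-channel \linkS4class{MinistackImage}
#'   (\code{cis, trans, cargo}).
#' @param rois optional ROI data.frame from \code{\link{detectROIs}}.
#' @param chromModel optional \linkS4class{ChromaticModel}.
#' @param cargoId,chaseTimeMin labels copied into the output.
#' @param minAxisNm,maxAxisNm,minIntensity QC gates, see
#'   \code{\link{filterAnalyzable}}.
#' @param ... passed to \code{\link{detectROIs}}.
#' @return data.frame with one row per ministack: \code{stack_id, cargo_id,
#'   chase_time_min, lq, d_axis_nm}, per-channel coordinates and
#'   intensities, and \code{pass_qc}.
#' @examples
#' sim <- simulateMinistackField(simulationConfig(nStacks = 6, seed = 4))
#' lqs <- measureMinistacks(sim$image)
#' mean(lqs$lq[lqs$pass_qc])
#' @export
measureMinistacks <- function(image, rois = NULL, chromModel = NULL,
                              cargoId = "cargo", chaseTimeMin = NA_real_,
                              minAxisNm = 70, maxAxisNm = 1000,
                              minIntensity = 0, ...) {
  need <- c("cis", "trans", "cargo")
  if (!all(need %in% channelRoles(image)))
    stop("image must have channel roles cis, trans and cargo")
  if (is.null(rois)) rois <- detectROIs(image, ...)
  px <- pixelSizeNm(image)
  rows <- lapply(seq_len(nrow(rois)), function(i) {
    coords <- list(); inten <- list(); ok <- TRUE
    for (ch in need) {
      m <- channelMatrix(image, ch)
      crop <- m[(rois$y0[i] + 1):rois$y1[i], (rois$x0[i] + 1):rois$x1[i]]
      cm <- centerOfMass(subtractBackground(crop), 1,
                        c(rois$x0[i], rois$y0[i]))
      if (!cm$valid) ok <- FALSE
      pt <- c(cm$x_nm, cm$y_nm)  # still in px here
      if (ok && !is.null(chromModel))
        pt <- correctCoordinates(chromModel, pt, ch)
      coords[[ch]] <- pt * px
      inten[[ch]] <- cm$intensity
    }
    lqr <- if (ok) computeLQ(coords$cargo, coords$cis, coords$trans)
      else list(lq = NA_real_, d_axis_nm = 0, valid = FALSE)
    data.frame(stack_id = rois$stack_id[i], cargo_id = cargoId,
               chase_time_min = chaseTimeMin, lq = lqr$lq,
               d_axis_nm = lqr$d_axis_nm,
               x_cis_nm = coords$cis[1], y_cis_nm = coords$cis[2],
               x_trans_nm = coords$trans[1], y_trans_nm = coords$trans[2],
               x_cargo_nm = coords$cargo[1], y_cargo_nm = coords$cargo[2],
               intensity_cis = inten$cis, intensity_trans = inten$trans,
               intensity_cargo = inten$cargo,
               pass_qc = ok && lqr$valid)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(stack_id = integer(0), cargo_id = character(0),
               chase_time_min = numeric(0), lq = numeric(0),
               d_axis_nm = numeric(0), pass_qc = logical(0))
  filterAnalyzable(out, minAxisNm, maxAxisNm, minIntensity)
}
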
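#' Build a synthetic imaging configuration
#'
#' Defaults emulate wide-field GLIM imaging: 65 nm pixels, a 300 nm
#' GM130-to-GalT axis, diffraction-limited spots (sigma 150 nm), bright
#' puncta of ~5000 photons over a 20 photon/px background with 2-count
#' read noise.
#'
#' @param imageShape (height, width) in px.
#' @param pixelSizeNm pixel size in nm.
#' @param axisLengthNm GM130-to-GalT distance in nm.
#' @param cargoLqTrue ground-truth LQ of the cargo spot.
#' @param lateralOffsetNm cargo offset perpendicular to the axis, nm.
#' @param stackAngleDeg axis orientation (counter-clockwise from +x);
#'   \code{NA} draws a random angle per stack.
#' @param psfSigmaNm spot sigma in nm; scalar or one value per channel
#'   (cis, trans, cargo).
#' @param chromaticShiftPx 3 x 2 matrix of per-channel (dx, dy) shifts in
#'   px; rows named cis, trans, cargo. The cis channel is the reference.
#' @param photonScale expected photons per spot.
#' @param backgroundLevel background photons per pixel.
#' @param readNoiseSd read noise SD in counts.
#' @param noise \code{FALSE} for noiseless expected-intensity images.
#' @param nStacks stacks (or beads) per field.
#' @param seed RNG seed.
#' @return A \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(nStacks = 5, seed = 7)
#' @export
simulationConfig <- function(imageShape = c(256L, 256L), pixelSizeNm = 65,
                             axisLengthNm = 300, cargoLqTrue = 0.4,
                             lateralOffsetNm = 0, stackAngleDeg = NA_real_,
                             psfSigmaNm = 150,
                             chromaticShiftPx = matrix(0, 3, 2,
                               dimnames = list(c("cis", "trans", "cargo"),
                                               c("dx", "dy"))),
                             photonScale = 5000, backgroundLevel = 20,
                             readNoiseSd = 2, noise = TRUE, nStacks = 25L,
                             seed = 1L) {
  new("SimulationConfig", imageShape = as.integer(imageShape),
      pixelSizeNm = pixelSizeNm, axisLengthNm = axisLengthNm,
      cargoLqTrue = cargoLqTrue, lateralOffsetNm = lateralOffsetNm,
      stackAngleDeg = stackAngleDeg, psfSigmaNm = psfSigmaNm,
      chromaticShiftPx = chromaticShiftPx, photonScale = photonScale,
      backgroundLevel = backgroundLevel, readNoiseSd = readNoiseSd,
      noise = noise, nStacks = as.integer(nStacks), seed = as.integer(seed))
}

.simChannels <- c("cis", "trans", "cargo")

.psfSigmaPerChannel <- function(config) {
  s <- config@psfSigmaNm
  if (length(s) == 1L) s <- rep(s, 3L)
  names(s) <- .simChannels
  s
}

# Rejection-sample nStacks anchor positions (nm) with pairwise separation
# >= minSepNm and a clear margin to the border. Errors with the density
# limit when placement fails.
.placeStacks <- function(config, minSepNm, marginNm) {
  hNm <- (config@imageShape[1] - 1) * config@pixelSizeNm
  wNm <- (config@imageShape[2] - 1) * config@pixelSizeNm
  if (wNm - 2 * marginNm <= 0 || hNm - 2 * marginNm <= 0)
    stop("image too small for the requested stack geometry")
  xs <- ys <- numeric(0)
  tries <- 0L; maxTries <- 4000L * config@nStacks
  while (length(xs) < config@nStacks) {
    if (tries >= maxTries)
      stop("could not place ", config@nStacks, " stacks with >= ",
           round(minSepNm), " nm separation in a ", round(wNm), " x ",
           round(hNm), " nm field; reduce nStacks below ~",
           floor((wNm - 2 * marginNm) * (hNm - 2 * marginNm) / minSepNm^2),
           " or enlarge the image")
    tries <- tries + 1L
    x <- runif(1, marginNm, wNm - marginNm)
    y <- runif(1, marginNm, hNm - marginNm)
    if (!length(xs) || all((xs - x)^2 + (ys - y)^2 >= minSepNm^2)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  cbind(x = xs, y = ys)
}

.finishChannels <- function(expected, config) {
  planes <- lapply(expected, function(m) {
    m <- m + config@backgroundLevel
    if (config@noise) applyCameraNoise(m, config@readNoiseSd) else m
  })
  array(unlist(planes, use.names = FALSE),
        c(config@imageShape, length(planes)))
}

#' Simulate a field of Golgi ministacks with known ground truth
#'
#' Renders three-channel images in which every ministack consists of three
#' Gaussian spots: the cis marker (GM130) at the stack origin, the trans
#' marker (GalT) at \code{axisLengthNm} along the stack axis, and the cargo
#' at \code{cargoLqTrue * axisLengthNm} along the axis (plus an optional
#' perpendicular offset). Per-channel chromatic shifts are applied to the
#' non-reference channels, then Poisson photon noise, Gaussian read noise
#' and a constant background.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with elements \code{image} (\linkS4class{MinistackImage})
#'   and \code{truth} (data.frame \code{stack_id, channel, x_nm, y_nm,
#'   lq_true}; chromatic shifts are \emph{not} included in the truth
#'   coordinates, which live in the reference frame).
#' @examples
#' sim <- simulateMinistackField(simulationConfig(nStacks = 4, seed = 2))
#' sim$image
#' @export
simulateMinistackField <- function(config) {
  validObject(config)
  sig <- .psfSigmaPerChannel(config)
  minSep <- 6 * max(sig) + config@axisLengthNm
  margin <- 3 * max(sig) + config@axisLengthNm +
    abs(config@lateralOffsetNm)
  withSeed(config@seed, {
    anchors <- .placeStacks(config, minSep, margin)
    n <- config@nStacks
    ang <- if (is.na(config@stackAngleDeg)) runif(n, 0, 360) else
      rep(config@stackAngleDeg, n)
    th <- ang * pi / 180
    dir <- cbind(cos(th), sin(th))
    perp <- cbind(-sin(th), cos(th))
    pos <- list(
      cis = anchors,
      trans = anchors + config@axisLengthNm * dir,
      cargo = anchors + config@cargoLqTrue * config@axisLengthNm * dir +
        config@lateralOffsetNm * perp)
    px <- config@pixelSizeNm
    expected <- lapply(.simChannels, function(ch) {
      m <- matrix(0, config@imageShape[1], config@imageShape[2])
      sh <- config@chromaticShiftPx[ch, ]
      for (i in seq_len(n))
        m <- renderSpot(m, pos[[ch]][i, 1] / px + sh[1],
                        pos[[ch]][i, 2] / px + sh[2],
                        sig[ch] / px, config@photonScale)
      m
    })
    names(expected) <- .simChannels
    truth <- do.call(rbind, lapply(.simChannels, function(ch)
      data.frame(stack_id = seq_len(n), channel = ch,
                 x_nm = pos[[ch]][, 1], y_nm = pos[[ch]][, 2],
                 lq_true = config@cargoLqTrue)))
    truth <- truth[order(truth$stack_id), ]
    rownames(truth) <- NULL
    list(image = MinistackImage(.finishChannels(expected, config),
                                .simChannels, px),
         truth = truth)
  })
}

#' Simulate a multi-colour bead field
#'
#' All channels render the same bead positions, displaced only by the
#' configured per-channel chromatic shift; used to calibrate and test
#' chromatic aberration correction.
#'
#' @param config a \linkS4class{SimulationConfig}; \code{nStacks} is the
#'   number of beads.
#' @return list with \code{image} and \code{truth} (bead positions in nm in
#'   the reference frame, plus the true shifts as attribute
#'   \code{"shifts_px"}).
#' @export
simulateBeadField <- function(config) {
  validObject(config)
  sig <- .psfSigmaPerChannel(config)
  shiftMarginPx <- max(abs(config@chromaticShiftPx))
  minSep <- 8 * max(sig)
  margin <- 4 * max(sig) + shiftMarginPx * config@pixelSizeNm
  withSeed(config@seed, {
    anchors <- .placeStacks(config, minSep, margin)
    px <- config@pixelSizeNm
    expected <- lapply(.simChannels, function(ch) {
      m <- matrix(0, config@imageShape[1], config@imageShape[2])
      sh <- config@chromaticShiftPx[ch, ]
      for (i in seq_len(config@nStacks))
        m <- renderSpot(m, anchors[i, 1] / px + sh[1],
                        anchors[i, 2] / px + sh[2], sig[ch] / px,
                        config@photonScale)
      m
    })
    truth <- data.frame(stack_id = seq_len(config@nStacks),
                        x_nm = anchors[, 1], y_nm = anchors[, 2])
    attr(truth, "shifts_px") <- config@chromaticShiftPx
    list(image = MinistackImage(.finishChannels(expected, config),
                                .simChannels, px),
         truth = truth)
  })
}

#' Simulate an LQ-versus-chase-time series
#'
#' Draws per-ministack LQs around the first-order exponential
#' \code{lqKinetic(t, y0, A, tIntraMin)} and reports the per-timepoint mean
#' with SEM = \code{noiseSd / sqrt(nStacksPerT)}.
#'
#' @param y0,A,tIntraMin kinetic parameters (see \code{\link{lqKinetic}}).
#' @param timepoints chase times in minutes, non-negative and increasing.
#' @param noiseSd SD of single-ministack LQs around the model.
#' @param nStacksPerT ministacks per timepoint.
#' @param seed RNG seed.
#' @param cargoId reporter label.
#' @return data.frame \code{cargo_id, t_min, mean_lq, sem_lq, n}.
#' @examples
#' simulateLQSeries(1.0, 1.2, 8, timepoints = seq(5, 60, by = 5))
#' @export
simulateLQSeries <- function(y0, A, tIntraMin, timepoints, noiseSd = 0.05,
                             nStacksPerT = 30L, seed = 1L,
                             cargoId = "simulated") {
  if (!length(timepoints)) stop("timepoints must be non-empty")
  if (any(timepoints < 0) || is.unsorted(timepoints, strictly = TRUE))
    stop("timepoints must be non-negative and strictly increasing")
  if (tIntraMin <= 0) stop("tIntraMin must be positive")
  withSeed(seed, {
    mu <- lqKinetic(timepoints, y0, A, tIntraMin)
    meanLq <- vapply(mu, function(m)
      mean(m + rnorm(nStacksPerT, 0, noiseSd)), numeric(1))
    data.frame(cargo_id = cargoId, t_min = timepoints, mean_lq = meanLq,
               sem_lq = noiseSd / sqrt(nStacksPerT), n = nStacksPerT)
  })
}

#' Simulate a Golgi-intensity decay trace
#'
#' Intensity follows \code{y0 + A1 * exp(-t / t1Min)} plus Gaussian noise.
#'
#' @param y0 baseline offset.
#' @param A1 decay amplitude.
#' @param t1Min exponential time constant (min).
#' @param durationMin trace length (min).
#' @param dtMin frame interval (min).
#' @param noiseSd additive noise SD (intensity units).
#' @param seed RNG seed.
#' @param cellId cell label.
#' @return data.frame \code{cell_id, t_min, intensity}.
#' @export
simulateDecayTrace <- function(y0, A1, t1Min, durationMin, dtMin = 1,
                               noiseSd = 0, seed = 1L, cellId = "simulated") {
  if (dtMin <= 0) stop("dtMin must be positive")
  if (t1Min <= 0) stop("t1Min must be positive")
  if (durationMin <= 0) stop("durationMin must be positive")
  t <- seq(0, durationMin, by = dtMin)
  withSeed(seed, {
    data.frame(cell_id = cellId, t_min = t,
               intensity = y0 + A1 * exp(-t / t1Min) +
                 rnorm(length(t), 0, noiseSd))
  })
}

#' Simulate annotated side-view ministack images
#'
#' Renders a canonical side-view template -- the axis-defining marker
#' (giantin) as a double punctum flanking the stack, every other channel
#' as a laterally elongated cisternal band at its axial position -- then
#' produces \code{nImages} randomly rotated, slightly rescaled and
#' sub-pixel-shifted noisy copies with exact punctum annotations.
#'
#' Axial positions are measured along the cis-to-trans axis with the
#' puncta plane at the axis-defining marker's own position.
#'
#' @param axialPositionsNm named numeric of per-channel axial positions in
#'   nm; the first element is the axis-defining double-punctum marker.
#' @param punctaSeparationNm lateral separation of the double punctum.
#' @param nImages number of images.
#' @param imageShape,pixelSizeNm image geometry (Airyscan default 45 nm).
#' @param psfSigmaNm axial band thickness / punctum sigma, nm.
#' @param lateralSigmaNm lateral band sigma, nm.
#' @param photonScale,backgroundLevel,readNoiseSd,noise camera model.
#' @param rotate randomly rotate each image (\code{FALSE} keeps all copies
#'   in the canonical orientation).
#' @param scaleJitter SD of the per-image relative scale factor.
#' @param seed RNG seed.
#' @return list with \code{stack} (a \linkS4class{SideViewStack}) and
#'   \code{truth} (per-image angle, scale, and per-channel axial
#'   positions in nm).
#' @examples
#' sim <- simulateSideViewStack(
#'   c(giantin = 150, cis = 0, trans = 300), nImages = 5, seed = 3)
#' @export
simulateSideViewStack <- function(axialPositionsNm =
                                    c(giantin = 150, cis = 0, trans = 300),
                                  punctaSeparationNm = 600, nImages = 20L,
                                  imageShape = c(96L, 96L), pixelSizeNm = 45,
                                  psfSigmaNm = 110, lateralSigmaNm = 220,
                                  photonScale = 5000, backgroundLevel = 5,
                                  readNoiseSd = 1, noise = TRUE,
                                  rotate = TRUE, scaleJitter = 0.03,
                                  seed = 1L) {
  if (is.null(names(axialPositionsNm)) || anyDuplicated(names(axialPositionsNm)))
    stop("axialPositionsNm must have unique channel names")
  channels <- names(axialPositionsNm)
  marker <- channels[1]
  px <- pixelSizeNm
  h <- imageShape[1]; w <- imageShape[2]
  centre <- c((w - 1) / 2, (h - 1) / 2)
  # canonical coordinates (nm) relative to the puncta midpoint; axial axis
  # points down (+y = trans direction)
  mid <- axialPositionsNm[marker]
  canonical <- lapply(channels, function(ch) {
    if (ch == marker)
      rbind(c(-punctaSeparationNm / 2, 0), c(punctaSeparationNm / 2, 0))
    else
      rbind(c(0, axialPositionsNm[ch] - mid))
  })
  names(canonical) <- channels
  withSeed(seed, {
    angles <- if (rotate) runif(nImages, 0, 2 * pi) else numeric(nImages)
    scales <- 1 + rnorm(nImages, 0, scaleJitter)
    offs <- matrix(runif(2 * nImages, -0.5, 0.5), ncol = 2)
    images <- vector("list", nImages)
    ann <- data.frame(image_id = seq_len(nImages), x1 = NA_real_,
                      y1 = NA_real_, x2 = NA_real_, y2 = NA_real_)
    for (i in seq_len(nImages)) {
      rot <- matrix(c(cos(angles[i]), sin(angles[i]),
                      -sin(angles[i]), cos(angles[i])), 2)
      place <- function(p) {
        q <- rot %*% (scales[i] * p / px)  # nm -> px, then rotate
        c(centre[1] + offs[i, 1] + q[1], centre[2] + offs[i, 2] + q[2])
      }
      planes <- lapply(channels, function(ch) {
        m <- matrix(0, h, w)
        pts <- canonical[[ch]]
        for (k in seq_len(nrow(pts))) {
          p <- place(pts[k, ])
          if (ch == marker) {
            m <- renderSpot(m, p[1], p[2], scales[i] * psfSigmaNm / px,
                            photonScale)
          } else {
            m <- renderAnisoSpot(m, p[1], p[2],
                                 scales[i] * lateralSigmaNm / px,
                                 scales[i] * psfSigmaNm / px,
                                 angles[i], photonScale)
          }
        }
        m <- m + backgroundLevel
        if (noise) applyCameraNoise(m, readNoiseSd) else m
      })
      images[[i]] <- array(unlist(planes, use.names = FALSE),
                           c(h, w, length(channels)))
      p1 <- place(canonical[[marker]][1, ])
      p2 <- place(canonical[[marker]][2, ])
      ann[i, c("x1", "y1", "x2", "y2")] <- c(p1[1], p1[2], p2[1], p2[2])
    }
    truth <- data.frame(image_id = seq_len(nImages), angle_rad = angles,
                        scale = scales)
    for (ch in channels)
      truth[[paste0("axial_", ch, "_nm")]] <- axialPositionsNm[ch]
    list(stack = new("SideViewStack", images = images, annotations = ann,
                     channels = channels, pixelSizeNm = px),
         truth = truth)
  })
}

#' Simulate annotated en-face ministack images
#'
#' Each image contains a ring marker (giantin seen face-on) rendered as a
#' Gaussian tube of radius \code{ringRadiusNm} plus a central cargo spot,
#' at a random sub-image offset with slight radius jitter.
#'
#' @param ringRadiusNm ring radius in nm.
#' @param nImages number of images.
#' @param imageShape,pixelSizeNm image geometry.
#' @param ringSigmaNm radial thickness of the ring.
#' @param cargoSigmaNm sigma of the central cargo spot.
#' @param offsetMaxPx maximum |offset| of the ring centre from the image
#'   centre, px.
#' @param radiusJitter SD of the relative radius jitter.
#' @param photonScale,backgroundLevel,readNoiseSd,noise camera model.
#' @param seed RNG seed.
#' @return list with \code{images} (list of h x w x 2 arrays, channels
#'   \code{ring, cargo}), \code{annotations} (data.frame \code{image_id,
#'   cx, cy, r} in px) and \code{channels}.
#' @export
simulateEnFaceStack <- function(ringRadiusNm = 500, nImages = 20L,
                                imageShape = c(96L, 96L), pixelSizeNm = 45,
                                ringSigmaNm = 90, cargoSigmaNm = 220,
                                offsetMaxPx = 6, radiusJitter = 0.04,
                                photonScale = 5000, backgroundLevel = 5,
                                readNoiseSd = 1, noise = TRUE, seed = 1L) {
  h <- imageShape[1]; w <- imageShape[2]
  centre <- c((w - 1) / 2, (h - 1) / 2)
  px <- pixelSizeNm
  withSeed(seed, {
    images <- vector("list", nImages)
    ann <- data.frame(image_id = seq_len(nImages), cx = NA_real_,
                      cy = NA_real_, r = NA_real_)
    g <- pixelGrid(imageShape)
    for (i in seq_len(nImages)) {
      off <- runif(2, -offsetMaxPx, offsetMaxPx)
      cx <- centre[1] + off[1]; cy <- centre[2] + off[2]
      rPx <- ringRadiusNm * (1 + rnorm(1, 0, radiusJitter)) / px
      rad <- sqrt((g$x - cx)^2 + (g$y - cy)^2)
      ringAmp <- photonScale / (2 * pi * rPx * sqrt(2 * pi) *
                                  (ringSigmaNm / px))
      ring <- ringAmp * exp(-(rad - rPx)^2 / (2 * (ringSigmaNm / px)^2))
      cargo <- renderSpot(matrix(0, h, w), cx, cy, cargoSigmaNm / px,
                          photonScale)
      planes <- lapply(list(ring, cargo), function(m) {
        m <- m + backgroundLevel
        if (noise) applyCameraNoise(m, readNoiseSd) else m
      })
      images[[i]] <- array(unlist(planes, use.names = FALSE), c(h, w, 2L))
      ann[i, c("cx", "cy", "r")] <- c(cx, cy, rPx)
    }
    list(images = images, annotations = ann, channels = c("ring", "cargo"))
  })
}

#' Simulate a two-channel Golgi decay time-lapse
#'
#' A stationary Golgi blob in the marker channel and a co-localized
#' reporter blob whose integrated intensity decays as
#' \code{y0 + A1 * exp(-t / t1Min)}; used to test segmentation-based
#' residence-time measurement.
#'
#' @param t1Min reporter decay constant (min).
#' @param y0Frac asymptotic reporter fraction (of the initial amplitude).
#' @param durationMin,dtMin time-lapse length and frame interval.
#' @param imageShape,pixelSizeNm geometry.
#' @param golgiSigmaNm blob sigma in nm.
#' @param photonScale initial reporter photons; marker photons are constant.
#' @param backgroundLevel,readNoiseSd,noise camera model.
#' @param seed RNG seed.
#' @return list \code{frames} (h x w x 2 x T array), \code{channels}
#'   (\code{marker, reporter}), \code{times} (min).
#' @export
simulateDecayMovie <- function(t1Min = 10, y0Frac = 0.1, durationMin = 40,
                               dtMin = 2, imageShape = c(64L, 64L),
                               pixelSizeNm = 65, golgiSigmaNm = 400,
                               photonScale = 20000, backgroundLevel = 10,
                               readNoiseSd = 2, noise = TRUE, seed = 1L) {
  if (dtMin <= 0) stop("dtMin must be positive")
  times <- seq(0, durationMin, by = dtMin)
  h <- imageShape[1]; w <- imageShape[2]
  centre <- c((w - 1) / 2, (h - 1) / 2)
  px <- pixelSizeNm
  withSeed(seed, {
    frames <- array(0, c(h, w, 2L, length(times)))
    for (k in seq_along(times)) {
      amp <- photonScale * (y0Frac + (1 - y0Frac) * exp(-times[k] / t1Min))
      marker <- renderSpot(matrix(0, h, w), centre[1], centre[2],
                           golgiSigmaNm / px, photonScale) + backgroundLevel
      reporter <- renderSpot(matrix(0, h, w), centre[1], centre[2],
                             golgiSigmaNm / px, amp) + backgroundLevel
      if (noise) {
        marker <- applyCameraNoise(marker, readNoiseSd)
        reporter <- applyCameraNoise(reporter, readNoiseSd)
      }
      frames[, , 1L, k] <- marker
      frames[, , 2L, k] <- reporter
    }
    list(frames = frames, channels = c("marker", "reporter"), times = times)
  })
}
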
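#' @import methods
NULL

#' Multi-channel ministack image
#'
#' Container for a multi-channel 2D fluorescence image of Golgi ministacks
#' (or beads). Pixel values are photon counts (arbitrary camera units);
#' channels are named by their role, conventionally \code{"cis"} (GM130),
#' \code{"trans"} (GalT-mCherry) and \code{"cargo"} (the testing protein).
#'
#' Coordinate convention used throughout the package: pixel indices are
#' 0-based, physical coordinates in nm are measured from the centre of the
#' top-left pixel, x runs along columns and y along rows (downwards).
#'
#' @slot data numeric array \code{height x width x channels}.
#' @slot channels character vector of channel role names, one per plane.
#' @slot pixelSizeNm physical pixel size in nm.
#' @export
setClass("MinistackImage",
  representation(data = "array", channels = "character",
                 pixelSizeNm = "numeric"))

setValidity("MinistackImage", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L)
    return("data must be a height x width x channel array")
  if (length(object@channels) != d[3L])
    return("length(channels) must equal the number of image planes")
  if (anyDuplicated(object@channels))
    return("channel roles must be unique")
  if (length(object@pixelSizeNm) != 1L || !is.finite(object@pixelSizeNm) ||
      object@pixelSizeNm <= 0)
    return("pixelSizeNm must be a single positive number")
  TRUE
})

#' Construct a MinistackImage
#'
#' @param data numeric array \code{height x width x channels}, or a matrix
#'   for a single channel.
#' @param channels character vector of channel roles.
#' @param pixelSizeNm pixel size in nm.
#' @return A \linkS4class{MinistackImage}.
#' @examples
#' img <- MinistackImage(array(0, c(32, 32, 3)),
#'                       c("cis", "trans", "cargo"), 65)
#' channelRoles(img)
#' @export
MinistackImage <- function(data, channels, pixelSizeNm) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  dimnames(data) <- list(NULL, NULL, channels)
  new("MinistackImage", data = data, channels = as.character(channels),
      pixelSizeNm = as.numeric(pixelSizeNm))
}

#' Chromatic aberration model
#'
#' Per-channel 2D transform mapping a channel's coordinates into the
#' reference channel's frame, estimated from a multi-colour bead field.
#' The reference channel's transform is the identity.
#'
#' @slot reference name of the reference channel.
#' @slot model \code{"translation"} or \code{"affine"}.
#' @slot shiftsPx channels x 2 matrix of (dx, dy) shifts in pixels: the
#'   displacement of each channel's bead images relative to the reference,
#'   i.e. corrected = measured - shift.
#' @slot affineCoef list of per-channel 3 x 2 coefficient matrices
#'   (intercept, x, y), empty for the translation model.
#' @slot residualRmsPx named numeric, post-correction residual RMS in px.
#' @slot nBeads number of matched beads used.
#' @export
setClass("ChromaticModel",
  representation(reference = "character", model = "character",
                 shiftsPx = "matrix", affineCoef = "list",
                 residualRmsPx = "numeric", nBeads = "integer"))

setValidity("ChromaticModel", function(object) {
  if (ncol(object@shiftsPx) != 2L)
    return("shiftsPx must have two columns (dx, dy)")
  ref <- object@reference
  if (!ref %in% rownames(object@shiftsPx))
    return("reference channel missing from shiftsPx")
  if (any(object@shiftsPx[ref, ] != 0))
    return("reference channel transform must be the identity")
  if (any(!is.finite(object@residualRmsPx)))
    return("residual RMS must be finite")
  TRUE
})

#' First-order intra-Golgi kinetic fit
#'
#' Parameters of the first-order exponential
#' \eqn{LQ(t) = y_0 - A e^{-\ln 2\, t / t_{intra}}} fitted to an LQ-versus-
#' chase-time series. \code{y0} is the LQ of the Golgi exit site, and
#' \code{tIntraMin} the time at which the cargo has covered half of its
#' transport range (the intra-Golgi transport time).
#'
#' @slot cargoId reporter identifier.
#' @slot y0,A,tIntraMin fitted parameters (LQ units; minutes).
#' @slot adjR2 adjusted R-squared of the fit.
#' @slot cov 3 x 3 parameter covariance matrix.
#' @slot nPoints number of timepoints used.
#' @slot weighted whether 1/SEM^2 weighting was applied.
#' @export
setClass("KineticFit",
  representation(cargoId = "character", y0 = "numeric", A = "numeric",
                 tIntraMin = "numeric", adjR2 = "numeric", cov = "matrix",
                 nPoints = "integer", weighted = "logical"))

setValidity("KineticFit", function(object) {
  if (object@tIntraMin <= 0) return("tIntraMin must be positive")
  if (is.finite(object@adjR2) && object@adjR2 > 1)
    return("adjusted R-squared cannot exceed 1")
  TRUE
})

#' Golgi residence decay fit
#'
#' Fit of a Golgi-intensity decay trace to
#' \eqn{y = y_0 + A_1 e^{-x/t_1}}. The Golgi residence time is
#' \code{tHalfMin = 0.693 * t1Min}. A fit is accepted only when
#' \code{adjR2 >= 0.80} and the acquisition length is at least
#' \code{1.33 * tHalfMin}.
#'
#' @slot cellId cell identifier.
#' @slot y0,A1,t1Min fitted parameters.
#' @slot tHalfMin residence half-time, exactly \code{0.693 * t1Min}.
#' @slot adjR2 adjusted R-squared.
#' @slot accepted logical QC flag.
#' @slot rejectionReason empty string when accepted.
#' @export
setClass("DecayFit",
  representation(cellId = "character", y0 = "numeric", A1 = "numeric",
                 t1Min = "numeric", tHalfMin = "numeric", adjR2 = "numeric",
                 accepted = "logical", rejectionReason = "character"))

setValidity("DecayFit", function(object) {
  if (is.finite(object@t1Min) &&
      abs(object@tHalfMin - 0.693 * object@t1Min) > 1e-12 * max(1, object@t1Min))
    return("tHalfMin must equal 0.693 * t1Min")
  TRUE
})

#' Gaussian peak fit of an axial intensity profile
#'
#' Single Gaussian plus constant baseline; \code{centerNm} (Xc) is the
#' axial position of the fitted marker.
#'
#' @slot centerNm,widthNm,amplitude,baseline fitted parameters.
#' @slot adjR2 adjusted R-squared.
#' @export
setClass("GaussianPeakFit",
  representation(centerNm = "numeric", widthNm = "numeric",
                 amplitude = "numeric", baseline = "numeric",
                 adjR2 = "numeric"))

setValidity("GaussianPeakFit", function(object) {
  if (object@widthNm <= 0) return("widthNm must be positive")
  TRUE
})

#' Stack of annotated side-view ministack images
#'
#' Cropped multi-channel images of ministacks seen edge-on, each annotated
#' with the two punctum coordinates of the axis-defining marker (giantin
#' double puncta), in 0-based pixels.
#'
#' @slot images list of \code{height x width x channel} arrays.
#' @slot annotations data.frame with columns \code{image_id, x1, y1, x2, y2}.
#' @slot channels channel role names.
#' @slot pixelSizeNm pixel size in nm.
#' @export
setClass("SideViewStack",
  representation(images = "list", annotations = "data.frame",
                 channels = "character", pixelSizeNm = "numeric"))

setValidity("SideViewStack", function(object) {
  if (nrow(object@annotations) != length(object@images))
    return("one annotation row per image is required")
  need <- c("image_id", "x1", "y1", "x2", "y2")
  if (!all(need %in% names(object@annotations)))
    return("annotations must have columns image_id, x1, y1, x2, y2")
  TRUE
})

#' Side-averaged ministack image
#'
#' Pixelwise mean of registered (rotated, rescaled, normalized) side views,
#' with per-channel axial positions: \code{axialYNm[i]} is the y component
#' of channel i's centre of mass along the cis-to-trans axis, in nm from
#' the top image row.
#'
#' @slot data averaged array \code{height x width x channels}.
#' @slot channels channel role names.
#' @slot pixelSizeNm pixel size in nm.
#' @slot nAveraged number of images averaged.
#' @slot axialYNm named numeric of per-channel axial centres of mass.
#' @export
setClass("SideAverageImage",
  representation(data = "array", channels = "character",
                 pixelSizeNm = "numeric", nAveraged = "integer",
                 axialYNm = "numeric"))

setValidity("SideAverageImage", function(object) {
  if (object@nAveraged < 1L) return("nAveraged must be >= 1")
  if (any(!is.finite(object@axialYNm)))
    return("axial centres of mass must be finite")
  TRUE
})

#' Synthetic imaging configuration
#'
#' Parameters of the synthetic ministack/bead image generator. Defaults
#' emulate wide-field imaging of nocodazole-induced ministacks: 65 nm
#' pixels, a 300 nm GM130-to-GalT axis, and a Poisson + Gaussian camera
#' noise model.
#'
#' @slot imageShape integer (height, width) in pixels.
#' @slot pixelSizeNm pixel size in nm (65 wide-field, 89 spinning disk,
#'   45 Airyscan side views).
#' @slot axisLengthNm GM130-to-GalT distance in nm.
#' @slot cargoLqTrue ground-truth LQ at which the cargo spot is placed.
#' @slot lateralOffsetNm optional cargo offset perpendicular to the axis.
#' @slot stackAngleDeg in-plane orientation of the cis-to-trans axis,
#'   counter-clockwise from +x; \code{NA} draws a random angle per stack.
#' @slot psfSigmaNm Gaussian spot sigma in nm (scalar, or one per channel).
#' @slot chromaticShiftPx channels x 2 matrix of per-channel (dx, dy)
#'   shifts in px relative to the reference channel.
#' @slot photonScale expected total photon count per spot.
#' @slot backgroundLevel constant background in photons/pixel.
#' @slot readNoiseSd Gaussian read noise SD in counts.
#' @slot noise logical; \code{FALSE} renders noiseless expected intensities.
#' @slot nStacks number of ministacks (or beads) per field.
#' @slot seed RNG seed; identical config + seed gives bit-identical output.
#' @export
setClass("SimulationConfig",
  representation(imageShape = "integer", pixelSizeNm = "numeric",
                 axisLengthNm = "numeric", cargoLqTrue = "numeric",
                 lateralOffsetNm = "numeric", stackAngleDeg = "numeric",
                 psfSigmaNm = "numeric", chromaticShiftPx = "matrix",
                 photonScale = "numeric", backgroundLevel = "numeric",
                 readNoiseSd = "numeric", noise = "logical",
                 nStacks = "integer", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  if (length(object@imageShape) != 2L || any(object@imageShape < 16L))
    return("imageShape must be (height, width), each >= 16 px")
  if (object@pixelSizeNm <= 0) return("pixelSizeNm must be positive")
  if (any(object@psfSigmaNm <= 0)) return("psfSigmaNm must be positive")
  if (object@nStacks < 1L) return("nStacks must be >= 1")
  if (ncol(object@chromaticShiftPx) != 2L)
    return("chromaticShiftPx must have columns (dx, dy)")
  TRUE
})

#' @describeIn MinistackImage-class printing
#' @param object a \code{MinistackImage}
#' @export
setMethod("show", "MinistackImage", function(object) {
  d <- dim(object@data)
  cat("MinistackImage:", d[1], "x", d[2], "px,",
      object@pixelSizeNm, "nm/px\n")
  cat("  channels:", paste(object@channels, collapse = ", "), "\n")
})

#' @describeIn ChromaticModel-class printing
#' @param object a \code{ChromaticModel}
#' @export
setMethod("show", "ChromaticModel", function(object) {
  cat("ChromaticModel (", object@model, "), reference: ",
      object@reference, ", beads: ", object@nBeads, "\n", sep = "")
  print(round(object@shiftsPx, 4))
  cat("  residual RMS (px):",
      paste(sprintf("%s=%.4f", names(object@residualRmsPx),
                    object@residualRmsPx), collapse = ", "), "\n")
})

#' @describeIn KineticFit-class printing
#' @param object a \code{KineticFit}
#' @export
setMethod("show", "KineticFit", function(object) {
  cat("KineticFit [", object@cargoId, "]: LQ(t) = ",
      sprintf("%.3f - %.3f exp(-ln2 t / %.2f)", object@y0, object@A,
              object@tIntraMin),
      ", adj R2 = ", sprintf("%.3f", object@adjR2),
      " (n = ", object@nPoints, ")\n", sep = "")
})

#' @describeIn DecayFit-class printing
#' @param object a \code{DecayFit}
#' @export
setMethod("show", "DecayFit", function(object) {
  cat("DecayFit [", object@cellId, "]: t1/2 = ",
      sprintf("%.2f", object@tHalfMin), " min, adj R2 = ",
      sprintf("%.3f", object@adjR2), ", ",
      if (object@accepted) "accepted" else
        paste("rejected:", object@rejectionReason), "\n", sep = "")
})

#' @describeIn SideAverageImage-class printing
#' @param object a \code{SideAverageImage}
#' @export
setMethod("show", "SideAverageImage", function(object) {
  cat("SideAverageImage: n =", object@nAveraged, "images,",
      object@pixelSizeNm, "nm/px\n")
  cat("  axial y (nm):",
      paste(sprintf("%s=%.1f", object@channels, object@axialYNm),
            collapse = ", "), "\n")
})
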
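#' Accessors for image and fit objects
#'
#' Slot access for the package's S4 containers.
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("channelRoles", function(x) standardGeneric("channelRoles"))

#' @rdname accessors
#' @export
setMethod("channelRoles", "MinistackImage", function(x) x@channels)

#' @rdname accessors
#' @export
setMethod("channelRoles", "SideViewStack", function(x) x@channels)

#' @rdname accessors
#' @export
setMethod("channelRoles", "SideAverageImage", function(x) x@channels)

#' @rdname accessors
#' @export
setGeneric("pixelSizeNm", function(x) standardGeneric("pixelSizeNm"))

#' @rdname accessors
#' @export
setMethod("pixelSizeNm", "MinistackImage", function(x) x@pixelSizeNm)

#' @rdname accessors
#' @export
setMethod("pixelSizeNm", "SideViewStack", function(x) x@pixelSizeNm)

#' @rdname accessors
#' @export
setMethod("pixelSizeNm", "SideAverageImage", function(x) x@pixelSizeNm)

#' Extract one channel of an image as a matrix
#'
#' @param x a \linkS4class{MinistackImage} or \linkS4class{SideAverageImage}.
#' @param role channel role name (e.g. \code{"cis"}).
#' @return numeric matrix (rows = y, columns = x).
#' @export
setGeneric("channelMatrix", function(x, role) standardGeneric("channelMatrix"))

.channelPlane <- function(data, channels, role) {
  i <- match(role, channels)
  if (is.na(i)) stop("channel role '", role, "' not present (have: ",
                     paste(channels, collapse = ", "), ")")
  data[, , i]
}

#' @rdname channelMatrix
#' @export
setMethod("channelMatrix", "MinistackImage", function(x, role)
  .channelPlane(x@data, x@channels, role))

#' @rdname channelMatrix
#' @export
setMethod("channelMatrix", "SideAverageImage", function(x, role)
  .channelPlane(x@data, x@channels, role))

#' Fitted kinetic parameters as a named vector
#'
#' @param x a \linkS4class{KineticFit} or \linkS4class{DecayFit}.
#' @return named numeric vector of the fitted parameters.
#' @export
setGeneric("fitParams", function(x) standardGeneric("fitParams"))

#' @rdname fitParams
#' @export
setMethod("fitParams", "KineticFit", function(x)
  c(y0 = x@y0, A = x@A, t_intra_min = x@tIntraMin, adj_r2 = x@adjR2))

#' @rdname fitParams
#' @export
setMethod("fitParams", "DecayFit", function(x)
  c(y0 = x@y0, A1 = x@A1, t1_min = x@t1Min, t_half_min = x@tHalfMin,
    adj_r2 = x@adjR2))

#' @rdname accessors
#' @export
setGeneric("isAccepted", function(x) standardGeneric("isAccepted"))

#' @rdname accessors
#' @export
setMethod("isAccepted", "DecayFit", function(x) x@accepted)

#' Axial positions of the channels in a side average
#'
#' @param x a \linkS4class{SideAverageImage}.
#' @return named numeric vector, nm from the top image row.
#' @export
setGeneric("axialPositions", function(x) standardGeneric("axialPositions"))

#' @rdname axialPositions
#' @export
setMethod("axialPositions", "SideAverageImage", function(x) {
  y <- x@axialYNm
  names(y) <- x@channels
  y
})
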
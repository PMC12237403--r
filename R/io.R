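# Interchange formats: multi-page TIFF for images (one page per channel,
# 16-bit integer counts), CSV for all tabular results, YAML for run
# configuration. Numeric CSV output uses a fixed %.15g format so re-running
# a stage with the same inputs reproduces byte-identical files.

.fmtNum <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x == floor(x) & abs(x) < 1e15, sprintf("%d", as.integer(x)),
                sprintf("%.15g", x)))
}

# Write a data.frame as CSV with deterministic numeric formatting.
.writeCsv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- .fmtNum(out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a multi-channel image as multi-page TIFF
#'
#' One page per channel, stored as 16-bit integer counts (values are
#' clipped to [0, 65535] and quantized to whole counts, the native camera
#' format). Channel roles and pixel size travel in a small YAML sidecar
#' written next to the image (\code{<path>.meta.yaml}) and are re-read
#' automatically; both can also be given explicitly.
#'
#' @param image a \linkS4class{MinistackImage}.
#' @param path TIFF file path.
#' @return \code{writeMinistackTiff}: the path, invisibly.
#' @export
writeMinistackTiff <- function(image, path) {
  stopifnot(is(image, "MinistackImage"))
  planes <- lapply(channelRoles(image), function(ch)
    pmin(pmax(channelMatrix(image, ch), 0), 65535) / 65535)
  tiff::writeTIFF(planes, path, bits.per.sample = 16L)
  yaml::write_yaml(list(channels = as.list(channelRoles(image)),
                        pixel_size_nm = pixelSizeNm(image)),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname writeMinistackTiff
#' @param channels,pixelSizeNm channel roles and pixel size; defaults come
#'   from the sidecar written by \code{writeMinistackTiff}.
#' @return \code{readMinistackTiff}: a \linkS4class{MinistackImage}.
#' @export
readMinistackTiff <- function(path, channels = NULL, pixelSizeNm = NULL) {
  if (!file.exists(path)) stop("TIFF not found: ", path)
  meta <- paste0(path, ".meta.yaml")
  if (file.exists(meta)) {
    info <- yaml::read_yaml(meta)
    if (is.null(channels)) channels <- unlist(info$channels)
    if (is.null(pixelSizeNm)) pixelSizeNm <- info$pixel_size_nm
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.null(channels))
    stop("channel roles are required (no metadata sidecar found)")
  if (length(pages) != length(channels))
    stop("TIFF has ", length(pages), " pages but ", length(channels),
         " channel roles were given")
  data <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) data[, , k] <- pages[[k]] * 65535
  MinistackImage(data, channels, pixelSizeNm)
}

#' Write / read per-stack LQ tables
#'
#' The per-ministack LQ table produced by \code{\link{measureMinistacks}}
#' (\code{stack_id, cargo_id, chase_time_min, lq, d_axis_nm, pass_qc} plus
#' coordinate/intensity columns) as CSV.
#'
#' @param records LQ record data.frame.
#' @param path CSV path.
#' @export
writeLQTable <- function(records, path) .writeCsv(records, path)

#' @rdname writeLQTable
#' @export
readLQTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read LQ-versus-time kinetic series
#'
#' CSV schema \code{cargo_id, t_min, mean_lq, sem_lq, n}.
#'
#' @param series kinetic series data.frame.
#' @param path CSV path.
#' @export
writeKineticSeries <- function(series, path) .writeCsv(series, path)

#' @rdname writeKineticSeries
#' @export
readKineticSeries <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cargo_id", "t_min", "mean_lq")
  if (!all(need %in% names(s)))
    stop("kinetic series CSV must have columns ",
         paste(need, collapse = ", "))
  s
}

#' Read Golgi decay traces
#'
#' CSV schema \code{cell_id, t_min, intensity}; returns a list of
#' per-cell traces ready for \code{\link{fitGolgiDecay}}.
#'
#' @param path CSV path.
#' @return named list of data.frames, one per cell.
#' @export
readDecayTraces <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "t_min", "intensity")
  if (!all(need %in% names(d)))
    stop("decay trace CSV must have columns ", paste(need, collapse = ", "))
  split(d, d$cell_id)
}

#' Write a kinetics results table
#'
#' Serializes the output of \code{\link{tabulateKinetics}} as two CSVs:
#' \code{<path>} with per-replicate rows and \code{<path>} with
#' \code{_summary} inserted before the extension for the group summaries.
#'
#' @param tab list from \code{\link{tabulateKinetics}}.
#' @param path CSV path for the per-replicate table.
#' @export
writeKineticTable <- function(tab, path) {
  .writeCsv(tab$perReplicate, path)
  .writeCsv(tab$groupSummary,
            sub("(\\.[^.]*)?$", "_summary\\1", path))
  invisible(path)
}

.runConfigKeys <- c("stage", "seed", "input", "output", "params")

#' Write / read a run configuration
#'
#' YAML run configuration with keys \code{stage, seed, input, output,
#' params}; unknown top-level keys are rejected on read so that typos do
#' not silently fall back to defaults. Writing a resolved configuration
#' next to a stage's outputs makes a run reproducible from its artifacts.
#'
#' @param config named list.
#' @param path YAML path.
#' @export
writeRunConfig <- function(config, path) {
  unknown <- setdiff(names(config), .runConfigKeys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  config <- yaml::read_yaml(path)
  unknown <- setdiff(names(config), .runConfigKeys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  config
}

#' Append timestamped lines to a run log
#'
#' @param path log file path.
#' @param ... message parts, pasted together.
#' @export
logRunMessage <- function(path, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " ",
                 paste0(..., collapse = ""))
  cat(line, "\n", file = path, append = TRUE, sep = "")
  invisible(line)
}

#' Write ground-truth tables from the simulator
#'
#' CSV schema \code{stack_id, channel, x_nm, y_nm, lq_true}.
#'
#' @param truth ground-truth data.frame from
#'   \code{\link{simulateMinistackField}}.
#' @param path CSV path.
#' @export
writeGroundTruth <- function(truth, path) .writeCsv(truth, path)
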
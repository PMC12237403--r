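#' Nanometres per LQ unit
#'
#' Conversion constant between localization-quotient units and physical
#' axial distance along the Golgi ministack axis: one LQ unit corresponds
#' to 274 nm (determined by side averaging). Used to express intra-Golgi
#' transport velocities in nm/min.
#' @export
NM_PER_LQ <- 274

#' First-order intra-Golgi transport kinetics
#'
#' \eqn{LQ(t) = y_0 - A e^{-\ln 2 \, t / t_{intra}}}: the cargo's axial
#' Golgi position as a function of chase time. \code{y0} is the LQ of the
#' Golgi exit site; \code{tIntraMin}, the intra-Golgi transport time, is
#' the time at which the cargo has covered half of its transport range.
#'
#' @param t chase time in minutes (biotin addition at t = 0).
#' @param y0,A,tIntraMin model parameters.
#' @return LQ value(s).
#' @examples
#' lqKinetic(c(0, 8, 1e6), y0 = 1, A = 1.2, tIntraMin = 8)
#' @export
lqKinetic <- function(t, y0, A, tIntraMin) {
  y0 - A * exp(-log(2) * t / tIntraMin)
}

#' Fit LQ-versus-time kinetics
#'
#' Nonlinear least squares of the first-order exponential
#' \code{\link{lqKinetic}} to a chase series, with the initialization
#' y0 = last observed LQ, A = y0 - first observed LQ, t_intra = the time
#' nearest half-range, refined over a 5-point multiplicative multi-start
#' grid on t_intra. Optionally weighted by 1/SEM^2 (default unweighted).
#'
#' @param series data.frame with columns \code{t_min}, \code{mean_lq} and
#'   (for weighting) \code{sem_lq}; at least 4 timepoints.
#' @param weighted use 1/SEM^2 weights.
#' @param tMinExclude optionally drop points with \code{t_min} below this
#'   value (early chase points carry a high ER background).
#' @param cargoId label stored in the fit.
#' @return a \linkS4class{KineticFit} with adjusted R-squared
#'   \eqn{1 - (1 - R^2)(n - 1)/(n - p - 1)}, p = 3.
#' @examples
#' s <- simulateLQSeries(1.0, 1.2, 8, seq(5, 60, 5), noiseSd = 0, seed = 1)
#' fitParams(fitIntraGolgiKinetics(s))
#' @export
fitIntraGolgiKinetics <- function(series, weighted = FALSE,
                                  tMinExclude = NULL, cargoId = NULL) {
  if (is.null(cargoId))
    cargoId <- if ("cargo_id" %in% names(series))
      as.character(series$cargo_id[1]) else "unknown"
  if (!is.null(tMinExclude)) series <- series[series$t_min >= tMinExclude, ]
  if (nrow(series) < 4) stop("at least 4 timepoints are required")
  if (is.unsorted(series$t_min, strictly = TRUE))
    stop("chase times must be strictly increasing")
  d <- data.frame(t = series$t_min, lq = series$mean_lq)
  wts <- if (weighted) {
    if (!"sem_lq" %in% names(series) || any(series$sem_lq <= 0))
      stop("weighted fit requires positive sem_lq")
    1 / series$sem_lq^2
  } else NULL
  y0s <- d$lq[nrow(d)]
  As <- y0s - d$lq[1]
  half <- y0s - As / 2
  t0 <- d$t[which.min(abs(d$lq - half))]
  if (!is.finite(t0) || t0 <= 0) t0 <- stats::median(d$t)
  starts <- lapply(c(0.25, 0.5, 1, 2, 4) * t0, function(ti)
    list(y0 = y0s, A = As, tIntra = max(ti, 1e-3)))
  fit <- bestNlsFit(lq ~ y0 - A * exp(-log(2) * t / tIntra), d, starts,
                    weights = wts, lower = c(-Inf, -Inf, 1e-6))
  if (is.null(fit))
    stop("kinetic fit did not converge from any of the starts t_intra = ",
         paste(sprintf("%.3g", vapply(starts, `[[`, numeric(1), "tIntra")),
               collapse = ", "))
  cf <- coef(fit)
  new("KineticFit", cargoId = cargoId, y0 = unname(cf["y0"]),
      A = unname(cf["A"]), tIntraMin = unname(cf["tIntra"]),
      adjR2 = adjustedR2(d$lq, fitted(fit), 3, wts),
      cov = tryCatch(stats::vcov(fit), error = function(e)
        matrix(NA_real_, 3, 3)),
      nPoints = nrow(d), weighted = isTRUE(weighted))
}

#' Instantaneous transport velocity at a chase time
#'
#' The time derivative of the kinetic model,
#' \eqn{dLQ/dt = (A \ln 2 / t_{intra}) e^{-\ln 2\, t / t_{intra}}},
#' converted to nm/min with 274 nm per LQ unit.
#'
#' @param fit a \linkS4class{KineticFit}.
#' @param t chase time(s) in minutes, non-negative.
#' @return data.frame \code{evaluated_at, dlq_dt, v_nm_per_min}.
#' @export
velocityAtTime <- function(fit, t) {
  if (any(t < 0)) stop("chase time must be non-negative")
  dlq <- fit@A * log(2) / fit@tIntraMin *
    exp(-log(2) * t / fit@tIntraMin)
  data.frame(evaluated_at = t, dlq_dt = dlq,
             v_nm_per_min = dlq * NM_PER_LQ)
}

#' Instantaneous transport velocity at an LQ position
#'
#' Eliminating time between the kinetic model and its derivative gives
#' \eqn{dLQ/dt = \ln 2\,(y_0 - LQ) / t_{intra}}: the velocity a cargo has
#' while passing the axial position \code{lq}, independent of A. Scaled by
#' 274 nm per LQ unit for nm/min.
#'
#' @param tIntraMin,y0 kinetic parameters (scalars or vectors).
#' @param lq LQ position(s) at which to evaluate, default 0.40 (the
#'   medial-Golgi reference position).
#' @return data.frame \code{evaluated_at, dlq_dt, v_nm_per_min}.
#' @examples
#' velocityAtLQ(10.6, 0.74, 0.40)  # 0.0222 LQ/min, 6.09 nm/min
#' @export
velocityAtLQ <- function(tIntraMin, y0, lq = 0.40) {
  if (any(tIntraMin <= 0)) stop("tIntraMin must be positive")
  dlq <- log(2) * (y0 - lq) / tIntraMin
  data.frame(evaluated_at = lq, dlq_dt = dlq,
             v_nm_per_min = dlq * NM_PER_LQ)
}

#' Replicate summary of intra-Golgi transport times
#'
#' Mean and sample SD (n - 1 denominator) over replicate \code{t_intra}
#' fits, with the print convention used for replicate tables: the SD is
#' rounded (half-up) to one significant figure and the mean to the same
#' decimal place.
#'
#' @param x numeric vector of replicate values (e.g. t_intra in minutes).
#' @return list \code{mean, sd, n, label}; for a single replicate the SD
#'   is \code{NA} and the label carries no plus-minus term.
#' @examples
#' replicateStats(c(9.0, 9.5, 6.9))$label  # "8±1"
#' @export
replicateStats <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (!n) stop("no finite values")
  m <- mean(x)
  s <- if (n >= 2) stats::sd(x) else NA_real_
  list(mean = m, sd = s, n = n, label = formatMeanSd(m, s))
}

#' Format a mean and SD at one-significant-figure SD precision
#'
#' @param m mean.
#' @param s sample SD (\code{NA} formats the mean alone at one decimal).
#' @return character label such as \code{"8±1"} or
#'   \code{"14.2±0.6"}.
#' @export
formatMeanSd <- function(m, s = NA_real_) {
  if (!is.finite(s)) return(sprintf("%.1f", roundHalfUp(m, 1)))
  if (s <= 0) {
    digits <- 1L
  } else {
    digits <- -floor(log10(s))  # one significant figure of the SD
  }
  sR <- roundHalfUp(s, digits)
  mR <- roundHalfUp(m, digits)
  dec <- max(digits, 0L)
  sprintf(paste0("%.", dec, "f±%.", dec, "f"), mR, sR)
}

#' Tabulate kinetic fits with velocities and group summaries
#'
#' Builds a kinetics results table: one row per replicate with t_intra,
#' y0, adjusted R-squared and the instantaneous velocity at
#' \code{lqEval} in LQ units/min and nm/min (nm/min is exactly 274 times
#' the LQ/min column before rounding), plus per-group mean +/- SD
#' summaries of t_intra.
#'
#' @param params data.frame with columns \code{reporter, group,
#'   t_intra_min, y0} and optionally \code{adj_r2}; or a list of
#'   \linkS4class{KineticFit} objects (grouped by \code{cargoId}).
#' @param lqEval LQ at which velocities are evaluated (default 0.40).
#' @return list with \code{perReplicate} (row table) and
#'   \code{groupSummary} (group, mean, sd, n, label).
#' @examples
#' tab <- tabulateKinetics(rushKineticParams())
#' head(tab$perReplicate)
#' @export
tabulateKinetics <- function(params, lqEval = 0.40) {
  if (is.list(params) && !is.data.frame(params)) {
    params <- do.call(rbind, lapply(params, function(f)
      data.frame(reporter = f@cargoId, group = f@cargoId,
                 t_intra_min = f@tIntraMin, y0 = f@y0, adj_r2 = f@adjR2)))
  }
  if (!nrow(params))
    return(list(perReplicate = params,
                groupSummary = data.frame(group = character(0),
                                          mean = numeric(0), sd = numeric(0),
                                          n = integer(0),
                                          label = character(0))))
  v <- velocityAtLQ(params$t_intra_min, params$y0, lqEval)
  per <- cbind(params, dlq_dt = v$dlq_dt, v_nm_per_min = v$v_nm_per_min)
  groups <- unique(params$group)
  summary <- do.call(rbind, lapply(groups, function(g) {
    st <- replicateStats(params$t_intra_min[params$group == g])
    data.frame(group = g, mean = st$mean, sd = st$sd, n = st$n,
               label = st$label)
  }))
  rownames(summary) <- NULL
  list(perReplicate = per, groupSummary = summary)
}

#' Published RUSH-reporter kinetic parameters
#'
#' The per-replicate first-order kinetic fit parameters (t_intra in
#' minutes, y0, adjusted R-squared) for the panel of RUSH secretory
#' reporters measured by GLIM in HeLa and 293T Golgi ministacks, together
#' with the velocities at LQ = 0.40 and replicate-group summaries as
#' printed in the source table. Used to regenerate the velocity columns
#' and group statistics, and as reference inputs for worked examples.
#'
#' @return data.frame with columns \code{reporter, replicate, cell_line,
#'   group, t_intra_min, y0, adj_r2, printed_dlq_dt, printed_v_nm_per_min,
#'   printed_dlq_decimals, printed_group_label}.
#' @examples
#' k <- rushKineticParams()
#' subset(k, reporter == "SBP-GFP")
#' @export
rushKineticParams <- function() {
  path <- system.file("extdata", "rush_reporter_kinetics.csv",
                      package = "GLIMtools", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
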
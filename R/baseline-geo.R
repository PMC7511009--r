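#' Great-circle distance in km
#'
#' Haversine distance on a 6371-km sphere.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (vectorised).
#' @return Distance(s) in km.
#' @examples
#' haversineKm(50, 0, 51, 0)  # ~111.2 km per degree of latitude
#' @export
haversineKm <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90))
    stop("latitude outside [-90, 90]")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371000) / 1000
}

# full pairwise distance matrix (km) for a data.frame with lat/lon
pairwiseDistanceKm <- function(coords) {
  m <- geosphere::distm(cbind(coords$lon, coords$lat),
                        fun = function(p1, p2)
                          geosphere::distHaversine(p1, p2, r = 6371000))
  m / 1000
}

#' Empirical spatial covariogram
#'
#' Bins all point pairs by great-circle distance and estimates the
#' covariance in each bin as the mean of
#' \eqn{(z_i - \bar z)(z_j - \bar z)} over the pairs it contains, with
#' \eqn{\bar z} the global mean. The pair count per bin is recorded: it is
#' the weight of the subsequent weighted-least-squares model fit. Empty
#' bins are dropped.
#'
#' @param obs data.frame with columns \code{lat}, \code{lon}, \code{d15N}.
#' @param bin_width Bin width in km.
#' @param max_lag Largest lag retained (km); default half the maximum
#'   pairwise distance, standard variography practice.
#' @return data.frame of class \code{"empiricalCovariogram"}: columns
#'   \code{bin_mid} (km), \code{cov_hat}, \code{n_pairs}.
#' @export
empiricalCovariogram <- function(obs, bin_width = 10, max_lag = NULL) {
  if (nrow(obs) < 2) stop("need at least 2 observations")
  if (bin_width <= 0) stop("bin_width must be > 0")
  D <- pairwiseDistanceKm(obs)
  iu <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[iu]
  if (is.null(max_lag)) max_lag <- max(d) / 2
  keep <- d <= max_lag
  if (!any(keep)) stop("all point pairs lie beyond max_lag = ", max_lag, " km")
  z <- obs$d15N - mean(obs$d15N)
  prod <- z[iu[keep, 1]] * z[iu[keep, 2]]
  bin <- floor(d[keep] / bin_width)
  cov_hat <- tapply(prod, bin, mean)
  n_pairs <- tapply(prod, bin, length)
  out <- data.frame(bin_mid = (as.numeric(names(cov_hat)) + 0.5) * bin_width,
                    cov_hat = as.numeric(cov_hat),
                    n_pairs = as.integer(n_pairs))
  out <- out[order(out$bin_mid), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("empiricalCovariogram", "data.frame")
  out
}

#' Parametric spatial covariance model
#'
#' @param family "gaussian", "exponential" or "spherical".
#' @param sill Partial sill (variance at lag 0 above the nugget).
#' @param range Range parameter in km.
#' @param nugget Nugget variance (discontinuity at lag 0), default 0.
#' @param adj_r2 Adjusted weighted R-squared of the fit (if fitted).
#' @return Object of class \code{"covarianceModel"}.
#' @export
covarianceModel <- function(family = c("gaussian", "exponential", "spherical"),
                            sill, range, nugget = 0, adj_r2 = NA_real_) {
  family <- match.arg(family)
  if (sill <= 0 || range <= 0 || nugget < 0)
    stop("need sill > 0, range > 0, nugget >= 0")
  structure(list(family = family, sill = sill, range = range,
                 nugget = nugget, adj_r2 = adj_r2),
            class = "covarianceModel")
}

#' Evaluate a covariance model at lags h
#'
#' The nugget contributes only at h = 0 (measurement-scale variance).
#'
#' @param model A \code{\link{covarianceModel}}.
#' @param h Lag distance(s), km.
#' @return Covariance value(s).
#' @export
covValue <- function(model, h) {
  base <- switch(model$family,
    gaussian    = model$sill * exp(-(h / model$range)^2),
    exponential = model$sill * exp(-h / model$range),
    spherical   = ifelse(h < model$range,
                         model$sill * (1 - 1.5 * h / model$range +
                                         0.5 * (h / model$range)^3), 0))
  base + ifelse(h == 0, model$nugget, 0)
}

#' @export
print.covarianceModel <- function(x, ...) {
  cat(sprintf("%s covariance model: sill %.4g, range %.4g km, nugget %.4g",
              x$family, x$sill, x$range, x$nugget))
  if (is.finite(x$adj_r2)) cat(sprintf(" (adj R2 = %.3f)", x$adj_r2))
  cat("\n")
  invisible(x)
}

#' Fit a covariance model to an empirical covariogram by weighted least squares
#'
#' Minimises \eqn{\sum_b n_b (\hat c_b - c(h_b))^2} over (sill, range
#' [, nugget]) with the per-bin pair counts as weights, using bounded
#' quasi-Newton optimisation from a small deterministic grid of starts.
#' The adjusted weighted R-squared
#' \eqn{1 - (1 - R^2)(n - 1)/(n - p - 1)} summarises the fit.
#'
#' @param emp An \code{\link{empiricalCovariogram}} (>= 3 retained bins).
#' @param family Covariance family (see \code{\link{covarianceModel}}).
#' @param fit_nugget Also estimate a nugget (3-parameter fit)?
#' @return A \code{\link{covarianceModel}} with \code{adj_r2} filled in.
#' @export
fitCovariance <- function(emp, family = "gaussian", fit_nugget = FALSE) {
  need_bins <- if (fit_nugget) 4 else 3
  if (nrow(emp) < need_bins)
    stop("need at least ", need_bins, " covariogram bins, got ", nrow(emp))
  h <- emp$bin_mid; chat <- emp$cov_hat; w <- as.numeric(emp$n_pairs)
  modelFun <- function(par) {
    m <- list(family = family, sill = par[1], range = par[2],
              nugget = if (fit_nugget) par[3] else 0)
    class(m) <- "covarianceModel"
    covValue(m, h)
  }
  obj <- function(par) sum(w * (chat - modelFun(par))^2)
  s0 <- max(max(chat), 1e-6)
  starts <- expand.grid(sill = s0 * c(0.5, 1, 2),
                        range = max(h) * c(0.1, 0.3, 0.6))
  lower <- c(1e-10, 1e-6); upper <- c(Inf, Inf)
  if (fit_nugget) { lower <- c(lower, 0); upper <- c(upper, Inf) }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    par0 <- c(starts$sill[i], starts$range[i], if (fit_nugget) s0 * 0.1)
    res <- tryCatch(
      optim(par0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best))
    stop("covariance fit failed to converge from all starts")
  p <- if (fit_nugget) 3 else 2
  n <- length(h)
  cw <- sum(w * chat) / sum(w)
  sst <- sum(w * (chat - cw)^2)
  r2 <- if (sst > 0) 1 - best$value / sst else NA_real_
  adj <- if (is.na(r2) || n - p - 1 <= 0) r2 else 1 - (1 - r2) * (n - 1) / (n - p - 1)
  covarianceModel(family, sill = best$par[1], range = best$par[2],
                  nugget = if (fit_nugget) best$par[3] else 0, adj_r2 = adj)
}

#' Ordinary kriging of baseline values
#'
#' Solves, for each target, the ordinary-kriging system in covariance
#' form: the weights \eqn{\lambda} satisfy
#' \eqn{C \lambda + \mu 1 = c_0}, \eqn{\sum \lambda_i = 1}
#' (augmented system with a Lagrange multiplier). The prediction is
#' \eqn{\sum \lambda_i z_i} and the kriging variance
#' \eqn{sill + nugget - \lambda' c_0 - \mu} (clamped at 0 against
#' round-off). With a zero nugget the predictor interpolates the data
#' exactly at observation sites.
#'
#' @param obs data.frame with \code{lat}, \code{lon}, \code{d15N}
#'   (duplicate locations must be averaged first, see
#'   \code{\link{dedupBaseline}}).
#' @param model A \code{\link{covarianceModel}}.
#' @param targets data.frame with \code{lat}, \code{lon}.
#' @return data.frame: \code{lat}, \code{lon}, \code{d15N_pred},
#'   \code{krig_var}, \code{weights_negative} (flag: some weights < 0,
#'   so the prediction may leave the observed value range).
#' @export
krige <- function(obs, model, targets) {
  if (nrow(obs) < 1) stop("need at least 1 observation")
  stopifnot(inherits(model, "covarianceModel"))
  D <- pairwiseDistanceKm(obs)
  if (any(D[upper.tri(D)] < 1e-9))
    stop("duplicate observation locations make the kriging system singular; ",
         "deduplicate by averaging, e.g. with dedupBaseline()")
  C <- covValue(model, D)
  diag(C) <- model$sill + model$nugget + 1e-8 * model$sill
  n <- nrow(obs)
  A <- rbind(cbind(C, 1), c(rep(1, n), 0))
  Dt <- outer(seq_len(n), seq_len(nrow(targets)), function(i, j)
    haversineKm(obs$lat[i], obs$lon[i], targets$lat[j], targets$lon[j]))
  B <- rbind(covValue(model, Dt), rep(1, nrow(targets)))
  sol <- tryCatch(solve(A, B), error = function(e)
    stop("singular kriging system (duplicate observation locations?); ",
         "deduplicate by averaging, e.g. with dedupBaseline()"))
  lambda <- sol[seq_len(n), , drop = FALSE]
  mu <- sol[n + 1, ]
  pred <- as.numeric(crossprod(lambda, obs$d15N))
  kv <- model$sill + model$nugget -
    colSums(lambda * covValue(model, Dt)) - mu
  data.frame(lat = targets$lat, lon = targets$lon,
             d15N_pred = pred, krig_var = pmax(kv, 0),
             weights_negative = apply(lambda < -1e-10, 2, any))
}

#' Average duplicate observation locations
#'
#' Observations closer than \code{tol} km are merged (coordinates and
#' values averaged) so the kriging covariance matrix stays non-singular.
#'
#' @param obs data.frame with \code{lat}, \code{lon}, \code{d15N}.
#' @param tol Merge tolerance in km.
#' @return Deduplicated data.frame.
#' @export
dedupBaseline <- function(obs, tol = 1e-6) {
  D <- pairwiseDistanceKm(obs)
  grp <- seq_len(nrow(obs))
  for (i in seq_len(nrow(obs))) {
    near <- which(D[i, ] < tol)
    grp[near] <- min(grp[near])
  }
  out <- do.call(rbind, lapply(split(obs, grp), function(d)
    data.frame(lat = mean(d$lat), lon = mean(d$lon), d15N = mean(d$d15N))))
  rownames(out) <- NULL
  out
}

#' Station-specific baseline values by covariogram fit and kriging
#'
#' Runs the full spatial chain: empirical covariogram of the baseline
#' observations, weighted-least-squares fit of the covariance model, and
#' ordinary kriging at the requested stations. Stations co-located with an
#' observation (within \code{tol} km) take the observed value directly.
#'
#' @param obs Baseline observations (\code{lat}, \code{lon}, \code{d15N}).
#' @param stations data.frame with \code{station_id}, \code{lat}, \code{lon}.
#' @param bin_width,family,fit_nugget Passed to the covariogram/fit steps.
#' @param tol Co-location tolerance in km.
#' @return list with \code{baseline} (data.frame: \code{station_id},
#'   \code{lat}, \code{lon}, \code{d15N_baseline}, \code{krig_var},
#'   \code{source} = "observed"/"kriged") and \code{model} (the fitted
#'   \code{\link{covarianceModel}}, including \code{adj_r2}).
#' @export
baselineForStations <- function(obs, stations, bin_width = 10,
                                family = "gaussian", fit_nugget = FALSE,
                                tol = 1e-6) {
  obs <- dedupBaseline(obs, tol)
  emp <- empiricalCovariogram(obs, bin_width = bin_width)
  model <- fitCovariance(emp, family = family, fit_nugget = fit_nugget)
  Dst <- outer(seq_len(nrow(stations)), seq_len(nrow(obs)), function(i, j)
    haversineKm(stations$lat[i], stations$lon[i], obs$lat[j], obs$lon[j]))
  nearest <- apply(Dst, 1, which.min)
  colocated <- Dst[cbind(seq_len(nrow(stations)), nearest)] < tol
  out <- data.frame(station_id = stations$station_id,
                    lat = stations$lat, lon = stations$lon,
                    d15N_baseline = NA_real_, krig_var = NA_real_,
                    source = ifelse(colocated, "observed", "kriged"),
                    stringsAsFactors = FALSE)
  out$d15N_baseline[colocated] <- obs$d15N[nearest[colocated]]
  out$krig_var[colocated] <- 0
  if (any(!colocated)) {
    kr <- krige(obs, model, stations[!colocated, c("lat", "lon")])
    out$d15N_baseline[!colocated] <- kr$d15N_pred
    out$krig_var[!colocated] <- kr$krig_var
  }
  list(baseline = out, model = model, covariogram = emp)
}
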
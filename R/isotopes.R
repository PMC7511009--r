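#' Delta notation for an isotope ratio
#'
#' \eqn{\delta X = (R_{sample}/R_{standard} - 1) \times 10^3} (permil),
#' with R the heavy/light isotope ratio and the standard fixed by
#' convention (Vienna Pee Dee Belemnite for carbon, atmospheric N2 for
#' nitrogen).
#'
#' @param r_sample,r_standard Isotope ratios (r_standard > 0).
#' @return Delta value(s) in permil.
#' @export
deltaValue <- function(r_sample, r_standard) {
  if (any(r_standard <= 0)) stop("r_standard must be > 0")
  (r_sample / r_standard - 1) * 1e3
}

#' C:N quality screen for lipid bias
#'
#' Muscle samples with C:N at or below the threshold (3.5 by convention,
#' the point above which lipid correction of d13C is usually considered)
#' pass untouched — raw ratios are used, no correction is applied.
#' Samples above the threshold are flagged for inspection, never silently
#' corrected.
#'
#' @param measurements data.frame with a \code{cn_ratio} column.
#' @param threshold C:N cutoff (> 0).
#' @return list with \code{passed} and \code{flagged} data.frames.
#' @export
cnScreen <- function(measurements, threshold = 3.5) {
  if (threshold <= 0) stop("threshold must be > 0")
  ok <- measurements$cn_ratio <= threshold
  list(passed = measurements[ok, , drop = FALSE],
       flagged = measurements[!ok, , drop = FALSE])
}

#' Trophic level from baseline-corrected d15N (Post equation)
#'
#' \eqn{TL_i = TL_B + (\delta^{15}N_i - \delta^{15}N_B) / TDF}, with
#' \eqn{TL_B = 2} the theoretical trophic level of the suspension-feeding
#' baseline organism and TDF the trophic discrimination factor
#' (3.4 permil per level for nitrogen).
#'
#' @param d15n_i Consumer d15N (permil).
#' @param d15n_b Baseline d15N at the consumer's station (permil).
#' @param tl_base Baseline trophic level (default 2).
#' @param tdf Trophic discrimination factor, permil per level (> 0).
#' @return Trophic level(s).
#' @examples
#' trophicLevel(14.42, 7.69)  # ~3.98
#' @export
trophicLevel <- function(d15n_i, d15n_b, tl_base = 2, tdf = 3.4) {
  if (tdf <= 0) stop("tdf must be > 0")
  tl_base + (d15n_i - d15n_b) / tdf
}

#' Per-fish trophic levels with station-specific baselines
#'
#' Joins isotope measurements to fish records and a station -> baseline
#' map, applies the C:N screen, and computes each fish's trophic level
#' with the baseline of its own station (the station-specific mode); a
#' pooled mode using the mean baseline everywhere is available for
#' sensitivity analysis.
#'
#' @param isotopes data.frame: \code{fish_id}, \code{d13C}, \code{d15N},
#'   \code{cn_ratio}.
#' @param fish data.frame: \code{fish_id}, \code{station_id}, \code{season},
#'   \code{size_class} (and \code{gape_mm} if available).
#' @param baseline data.frame: \code{station_id}, \code{d15N_baseline}.
#' @param mode "station" (default) or "pooled".
#' @param tl_base,tdf See \code{\link{trophicLevel}}.
#' @param cn_threshold Passed to \code{\link{cnScreen}}; flagged fish are
#'   kept but marked \code{cn_flagged = TRUE}.
#' @return data.frame with per-fish \code{TL} and \code{d15N_B_used}.
#' @export
trophicLevelTable <- function(isotopes, fish, baseline, mode = "station",
                              tl_base = 2, tdf = 3.4, cn_threshold = 3.5) {
  mode <- match.arg(mode, c("station", "pooled"))
  d <- merge(isotopes, fish, by = "fish_id")
  if (nrow(d) < nrow(isotopes))
    stop("isotope measurements with no matching fish record")
  d <- merge(d, baseline[, c("station_id", "d15N_baseline")],
             by = "station_id", all.x = TRUE)
  if (any(is.na(d$d15N_baseline)))
    stop("stations without a baseline value: ",
         paste(unique(d$station_id[is.na(d$d15N_baseline)]), collapse = ", "))
  b <- if (mode == "pooled") rep(mean(d$d15N_baseline), nrow(d)) else
    d$d15N_baseline
  d$d15N_B_used <- b
  d$TL <- trophicLevel(d$d15N, b, tl_base, tdf)
  d$cn_flagged <- d$cn_ratio > cn_threshold
  d[order(d$fish_id), , drop = FALSE]
}

#' Summary of isotope ratios and trophic levels per size class and season
#'
#' One row per (size class, season) cell: sample size and mean +/- sample
#' SD (n - 1 denominator) of d13C, d15N, C:N, trophic level and gape.
#' Cells with no record are omitted with a message; cells with one record
#' report \code{NA} SDs.
#'
#' @param tl_table Result of \code{\link{trophicLevelTable}}.
#' @return data.frame with the per-cell summary statistics.
#' @export
summarizeIsotopes <- function(tl_table) {
  need <- c("season", "size_class", "d13C", "d15N", "cn_ratio", "TL")
  if (!all(need %in% names(tl_table)))
    stop("tl_table must have columns: ", paste(need, collapse = ", "))
  cells <- unique(tl_table[, c("season", "size_class")])
  cells <- cells[order(cells$season, cells$size_class), , drop = FALSE]
  all_cells <- expand.grid(season = unique(tl_table$season),
                           size_class = unique(tl_table$size_class),
                           stringsAsFactors = FALSE)
  missing <- all_cells[!paste(all_cells$season, all_cells$size_class) %in%
                         paste(cells$season, cells$size_class), , drop = FALSE]
  if (nrow(missing))
    message("cells with no isotope record omitted: ",
            paste(missing$size_class, missing$season, sep = "/", collapse = ", "))
  stat <- function(x) c(mean = mean(x), sd = if (length(x) > 1) sd(x) else NA_real_)
  rows <- lapply(seq_len(nrow(cells)), function(r) {
    d <- tl_table[tl_table$season == cells$season[r] &
                    tl_table$size_class == cells$size_class[r], , drop = FALSE]
    gape <- if ("gape_mm" %in% names(d)) stat(d$gape_mm) else c(mean = NA, sd = NA)
    data.frame(season = cells$season[r], size_class = cells$size_class[r],
               n = nrow(d),
               d13C_mean = stat(d$d13C)[1], d13C_sd = stat(d$d13C)[2],
               d15N_mean = stat(d$d15N)[1], d15N_sd = stat(d$d15N)[2],
               cn_mean = stat(d$cn_ratio)[1], cn_sd = stat(d$cn_ratio)[2],
               TL_mean = stat(d$TL)[1], TL_sd = stat(d$TL)[2],
               gape_mean = gape[1], gape_sd = gape[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
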
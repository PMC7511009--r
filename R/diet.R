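#' Parsimonious enumeration of prey individuals from stomach parts
#'
#' Estimates the most plausible (minimal) number of prey individuals that
#' could have produced the parts recovered from one stomach for one taxon:
#' whole individuals count as themselves; paired hard parts (otoliths,
#' eyes, claws) are pooled and divided by two, rounded up (the minimal
#' number of donors); uncountable remains (muscle, gills, bristles) attest
#' a single individual, and only when no countable part of the same taxon
#' is present — countable parts already attest at least one individual.
#'
#' @param items data.frame with columns \code{part_type} (one of
#'   \code{"whole"}, \code{"paired_part"}, \code{"uncountable_remains"})
#'   and \code{raw_count} (parts, or individuals if whole), for a single
#'   stomach and taxon.
#' @return Integer number of individuals (0 for an empty item set).
#' @examples
#' # four paired otoliths -> two individuals
#' enumeratePrey(data.frame(part_type = "paired_part", raw_count = 4))
#' # muscle remains only -> one individual
#' enumeratePrey(data.frame(part_type = "uncountable_remains", raw_count = 1))
#' @export
enumeratePrey <- function(items) {
  if (NROW(items) == 0) return(0L)
  pt <- as.character(items$part_type)
  known <- c("whole", "paired_part", "uncountable_remains")
  if (!all(pt %in% known))
    stop("unknown part_type: ", paste(setdiff(pt, known), collapse = ", "))
  rc <- items$raw_count
  countable <- pt %in% c("whole", "paired_part")
  if (any(countable & (!is.finite(rc) | rc < 1 | rc != floor(rc))))
    stop("raw_count must be a positive integer for whole and paired_part items")
  n_whole <- sum(rc[pt == "whole"])
  pool <- sum(rc[pt == "paired_part"])
  n <- n_whole + ceiling(pool / 2)
  if (n == 0 && any(pt == "uncountable_remains")) n <- 1L
  as.integer(n)
}

# enumerate individuals per (stomach, taxon), then sum within prey group;
# returns one row per stomach x group with column 'individuals'
preyCounts <- function(prey_items) {
  if (NROW(prey_items) == 0)
    return(data.frame(stomach_id = character(0), fish_id = character(0),
                      group = character(0), individuals = integer(0),
                      stringsAsFactors = FALSE))
  key <- interaction(prey_items$stomach_id, prey_items$taxon, drop = TRUE)
  per_taxon <- do.call(rbind, lapply(split(prey_items, key), function(d)
    data.frame(stomach_id = d$stomach_id[1], fish_id = d$fish_id[1],
               group = d$group[1], individuals = enumeratePrey(d),
               stringsAsFactors = FALSE)))
  agg <- aggregate(individuals ~ stomach_id + fish_id + group,
                   data = per_taxon, FUN = sum)
  agg[order(agg$stomach_id, agg$group), , drop = FALSE]
}

#' Vacuity rate (fraction of empty stomachs)
#'
#' Every fish record is one stomach; a stomach is empty when it has no
#' prey-item record. The vacuity rate, an inverse proxy of feeding
#' intensity, is the number of empty stomachs over the total, in percent.
#'
#' @param fish data.frame of fish records (one stomach per fish; needs
#'   \code{fish_id}, and \code{season} when \code{by = "season"}).
#' @param prey_items data.frame of prey items (needs \code{fish_id}).
#' @param by Optional grouping column of \code{fish} (e.g. "season").
#' @return data.frame with \code{n_empty}, \code{n_total}, \code{pct_V}
#'   (one row per group when \code{by} is given).
#' @export
vacuity <- function(fish, prey_items, by = NULL) {
  if (NROW(fish) == 0) stop("no stomachs: 'fish' is empty")
  empty <- !(fish$fish_id %in% prey_items$fish_id)
  if (is.null(by)) {
    data.frame(n_empty = sum(empty), n_total = nrow(fish),
               pct_V = 100 * sum(empty) / nrow(fish))
  } else {
    g <- fish[[by]]
    out <- do.call(rbind, lapply(split(empty, g), function(e)
      data.frame(n_empty = sum(e), n_total = length(e),
                 pct_V = 100 * sum(e) / length(e))))
    out <- cbind(setNames(data.frame(rownames(out)), by), out)
    rownames(out) <- NULL
    out
  }
}

#' Frequency-of-occurrence diet index
#'
#' For each prey group i, \eqn{O_i = J_i / P}: the number of non-empty
#' stomachs containing the group over the number of non-empty stomachs.
#' Because a stomach may contain several groups, the \eqn{O_i} sum to more
#' than 1 in mixed diets; \eqn{\%O} rescales them to sum to 100 for
#' graphical comparison.
#'
#' @inheritParams vacuity
#' @param groups Prey groups to report (default the six canonical groups).
#' @return data.frame with \code{group}, \code{J_i}, \code{P}, \code{O_i},
#'   \code{pct_O}.
#' @export
occurrenceIndices <- function(fish, prey_items, groups = preyGroups()) {
  if (NROW(fish) == 0) stop("no stomachs: 'fish' is empty")
  nonempty <- fish$fish_id[fish$fish_id %in% prey_items$fish_id]
  P <- length(nonempty)
  if (P == 0) stop("no non-empty stomachs (P = 0): occurrence undefined")
  pc <- preyCounts(prey_items[prey_items$fish_id %in% nonempty, , drop = FALSE])
  J <- vapply(groups, function(g)
    length(unique(pc$fish_id[pc$group == g])), integer(1))
  O <- J / P
  data.frame(group = groups, J_i = J, P = P, O_i = O,
             pct_O = if (sum(O) > 0) 100 * O / sum(O) else rep(NA_real_, length(O)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Numerical-abundance diet index
#'
#' \eqn{\%N_i = N_i / \sum N_i}: enumerated prey individuals of group i
#' (parsimonious enumeration per stomach and taxon, see
#' \code{\link{enumeratePrey}}) relative to all enumerated individuals.
#'
#' @inheritParams occurrenceIndices
#' @return data.frame with \code{group}, \code{N_i}, \code{pct_N}.
#' @export
abundanceIndices <- function(fish, prey_items, groups = preyGroups()) {
  if (NROW(fish) == 0) stop("no stomachs: 'fish' is empty")
  pc <- preyCounts(prey_items[prey_items$fish_id %in% fish$fish_id, , drop = FALSE])
  N <- vapply(groups, function(g)
    sum(pc$individuals[pc$group == g]), numeric(1))
  if (sum(N) < 1) stop("no enumerated prey individuals (sum N_i = 0)")
  data.frame(group = groups, N_i = N, pct_N = 100 * N / sum(N),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Diet index table per size class and season
#'
#' Computes occurrence and abundance indices for every (size class,
#' season) cell with at least one stomach, plus a pooled row set (labelled
#' \code{"all"}) over all stomachs. Cells whose stomachs are all empty get
#' \code{NA} indices with a message.
#'
#' @inheritParams occurrenceIndices
#' @return data.frame of class \code{"dietIndexTable"}: columns
#'   \code{season}, \code{size_class}, \code{group}, \code{J_i}, \code{P},
#'   \code{O_i}, \code{pct_O}, \code{N_i}, \code{pct_N}.
#' @export
dietTable <- function(fish, prey_items, groups = preyGroups()) {
  need <- c("fish_id", "season", "size_class")
  if (!all(need %in% names(fish)))
    stop("fish must have columns: ", paste(need, collapse = ", "))
  cells <- unique(fish[, c("season", "size_class")])
  cells <- cells[order(cells$season, cells$size_class), , drop = FALSE]
  cells <- rbind(cells, data.frame(season = "all", size_class = "all"))
  out <- list()
  for (r in seq_len(nrow(cells))) {
    sea <- cells$season[r]; cls <- cells$size_class[r]
    f <- if (sea == "all") fish else
      fish[fish$season == sea & fish$size_class == cls, , drop = FALSE]
    pi_cell <- prey_items[prey_items$fish_id %in% f$fish_id, , drop = FALSE]
    row <- tryCatch({
      occ <- occurrenceIndices(f, pi_cell, groups)
      ab <- abundanceIndices(f, pi_cell, groups)
      cbind(season = sea, size_class = cls, merge(occ, ab, by = "group"))
    }, error = function(e) {
      message("diet cell ", cls, "/", sea, " skipped: ", conditionMessage(e))
      cbind(season = sea, size_class = cls,
            data.frame(group = groups, J_i = NA, P = NA, O_i = NA,
                       pct_O = NA, N_i = NA, pct_N = NA))
    })
    out[[r]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("dietIndexTable", "data.frame")
  res
}
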
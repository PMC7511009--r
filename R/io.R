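# stable CSV writing: UTF-8, "." decimal, no row names, fixed column order
writeCsvStable <- function(df, path) {
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}

studySchemas <- function() {
  list(
    stations = list(required = c("station_id", "lat", "lon", "season"),
                    numeric = c("lat", "lon")),
    baseline = list(required = c("id", "lat", "lon", "d15N"),
                    numeric = c("lat", "lon", "d15N")),
    fish = list(required = c("fish_id", "station_id", "season", "size_class",
                             "length_mm", "gape_mm"),
                numeric = c("length_mm", "gape_mm")),
    prey_items = list(required = c("stomach_id", "fish_id", "taxon",
                                   "part_type", "raw_count"),
                      numeric = "raw_count"),
    isotopes = list(required = c("fish_id", "d13C", "d15N", "cn_ratio"),
                    numeric = c("d13C", "d15N", "cn_ratio")))
}

#' Read one validated study table
#'
#' Loads a CSV with a declared header set (UTF-8, "." decimal). Unknown
#' extra columns are preserved. A header mismatch is an error listing
#' expected versus found columns; numeric columns containing
#' comma-decimal values are rejected with a clear message; coordinate
#' columns are range-checked.
#'
#' @param path CSV file path.
#' @param table One of "stations", "baseline", "fish", "prey_items",
#'   "isotopes".
#' @return The validated data.frame.
#' @export
readStudyTable <- function(path, table) {
  schema <- studySchemas()[[table]]
  if (is.null(schema)) stop("unknown table type: ", table)
  if (!file.exists(path)) stop("input file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(schema$required, names(d))
  if (length(missing))
    stop("header mismatch in ", path, ": expected {",
         paste(schema$required, collapse = ", "), "}, found {",
         paste(names(d), collapse = ", "), "}; missing: ",
         paste(missing, collapse = ", "))
  for (col in schema$numeric) {
    if (is.character(d[[col]])) {
      if (any(grepl(",", d[[col]], fixed = TRUE)))
        stop("column '", col, "' in ", path, " contains comma decimal ",
             "separators; use '.' as the decimal mark")
      suppressWarnings(num <- as.numeric(d[[col]]))
      if (any(is.na(num) & !is.na(d[[col]]) & nzchar(d[[col]])))
        stop("column '", col, "' in ", path, " is not numeric")
      d[[col]] <- num
    }
  }
  if ("lat" %in% names(d) && any(abs(d$lat) > 90, na.rm = TRUE))
    stop("latitude outside [-90, 90] in ", path)
  if ("lon" %in% names(d) && any(abs(d$lon) > 180, na.rm = TRUE))
    stop("longitude outside [-180, 180] in ", path)
  d
}

#' Read the five input tables of a study directory
#'
#' Expects stations.csv, baseline.csv, fish.csv, prey_items.csv,
#' isotopes.csv under \code{dir} (see \code{\link{writeStudyCsv}} for the
#' layout).
#'
#' @param dir Directory containing the CSVs.
#' @return Named list of validated data.frames.
#' @export
readStudyCsv <- function(dir) {
  tabs <- names(studySchemas())
  out <- lapply(tabs, function(t)
    readStudyTable(file.path(dir, paste0(t, ".csv")), t))
  names(out) <- tabs
  out
}

# map taxa to prey groups; every taxon must be mapped
applyGroupMap <- function(prey_items, group_map = NULL) {
  if ("group" %in% names(prey_items) && is.null(group_map)) return(prey_items)
  if (is.null(group_map))
    stop("prey_items has no 'group' column and no taxon-to-group map was given")
  m <- setNames(group_map$group, group_map$taxon)
  unmapped <- setdiff(unique(prey_items$taxon), names(m))
  if (length(unmapped))
    stop("unmapped prey taxa: ", paste(unmapped, collapse = ", "))
  prey_items$group <- unname(m[prey_items$taxon])
  prey_items
}
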
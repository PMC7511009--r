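#' Size-class scheme for total length
#'
#' Left-closed, right-open 5-cm bins of fish total length, labelled as in
#' survey summary tables ("10-15cm" ... "35+"). The last class is open to
#' the right; fish exactly on an internal edge belong to the upper class
#' of the pair below it (half-open convention).
#'
#' @param edges Lower edges of the classes in mm, strictly increasing.
#' @param labels Class labels, one per edge.
#' @return An object of class \code{"sizeClassScheme"}: a list with
#'   \code{edges} (mm) and \code{labels}.
#' @examples
#' sc <- sizeClassScheme()
#' assignSizeClass(c(106, 150, 528), sc)
#' @export
sizeClassScheme <- function(edges = c(100, 150, 200, 250, 300, 350),
                            labels = c("10-15cm", "15-20cm", "20-25cm",
                                       "25-30cm", "30-35cm", "35+")) {
  if (length(edges) != length(labels))
    stop("'edges' and 'labels' must have the same length")
  if (any(diff(edges) <= 0)) stop("'edges' must be strictly increasing")
  structure(list(edges = as.numeric(edges), labels = as.character(labels)),
            class = "sizeClassScheme")
}

#' Assign fish to size classes
#'
#' @param length_mm Numeric vector of total lengths in mm.
#' @param scheme A \code{\link{sizeClassScheme}}.
#' @return A factor with the scheme's labels as levels.
#'   Lengths below the first edge are an error (the offenders are listed).
#' @export
assignSizeClass <- function(length_mm, scheme = sizeClassScheme()) {
  stopifnot(inherits(scheme, "sizeClassScheme"))
  bad <- which(!is.finite(length_mm) | length_mm < scheme$edges[1])
  if (length(bad))
    stop("lengths outside the class scheme (below ", scheme$edges[1],
         " mm) at positions: ", paste(bad, collapse = ", "),
         " [values: ", paste(signif(length_mm[bad], 4), collapse = ", "), "]")
  idx <- findInterval(length_mm, scheme$edges)
  factor(scheme$labels[idx], levels = scheme$labels)
}

#' @export
print.sizeClassScheme <- function(x, ...) {
  cat("Size-class scheme (total length, mm):\n")
  up <- c(x$edges[-1], Inf)
  for (i in seq_along(x$edges))
    cat(sprintf("  %-8s [%g, %g)\n", x$labels[i], x$edges[i], up[i]))
  invisible(x)
}

# canonical prey groups of the diet analysis
preyGroups <- function() {
  c("fish", "benthic_crustacean", "pelagic_crustacean",
    "unidentified_crustacean", "mollusk", "other")
}
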
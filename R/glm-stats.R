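#' Full-rank design matrix with sum-to-zero contrasts
#'
#' Builds the design for the two-factor model
#' \code{~ size_class * season} with sum-to-zero contrasts — the
#' parameterisation under which type-III tests of main effects in the
#' presence of the interaction are meaningful. When a factor cell is empty
#' (e.g. no small fish in one season) the interaction block is
#' rank-deficient; aliased columns are detected by pivoted QR and dropped
#' with a warning, which reduces the interaction's degrees of freedom
#' accordingly.
#'
#' @param data data.frame with factor (or character) columns
#'   \code{size_class} and \code{season}.
#' @param interaction Include the interaction term?
#' @return list with \code{X} (full-rank design), \code{assign} (term id
#'   per column: 0 intercept, 1 size_class, 2 season, 3 interaction),
#'   \code{terms} (term labels) and \code{dropped} (aliased column names).
#' @export
buildDesign <- function(data, interaction = TRUE) {
  need <- c("size_class", "season")
  if (!all(need %in% names(data)))
    stop("data must have columns: ", paste(need, collapse = ", "))
  if (any(is.na(data$size_class)) || any(is.na(data$season)))
    stop("size_class and season must be complete")
  d <- data.frame(size_class = droplevels(factor(data$size_class)),
                  season = droplevels(factor(data$season)))
  form <- if (interaction) ~ size_class * season else ~ size_class + season
  X <- model.matrix(form, d,
                    contrasts.arg = list(size_class = "contr.sum",
                                         season = "contr.sum"))
  assign <- attr(X, "assign")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    warning("design is rank-deficient (empty factor cells); dropping aliased ",
            "column(s): ", paste(dropped, collapse = ", "))
    X <- X[, keep, drop = FALSE]
    assign <- assign[keep]
  } else dropped <- character(0)
  list(X = X, assign = assign,
       terms = c("size_class", "season",
                 if (interaction) "size_class:season"),
       dropped = dropped)
}

familyObject <- function(family) {
  switch(family,
         gaussian_identity = gaussian(),
         binomial_logit = binomial("logit"),
         poisson_log = poisson("log"),
         stop("unknown family: ", family,
              " (use gaussian_identity, binomial_logit or poisson_log)"))
}

#' Maximum-likelihood GLM fit by iteratively reweighted least squares
#'
#' Fits a generalized linear model for a given design matrix by IRLS
#' (via \code{stats::glm.fit}), with convergence declared when the
#' relative deviance change falls below 1e-8, up to 100 iterations.
#' The Gaussian-identity family reproduces ordinary least squares
#' exactly; complete separation in a binomial fit is detected from
#' runaway coefficients, flagged and reported (coefficients are capped
#' at +/- 30 on the link scale for downstream numerical stability).
#'
#' @param X Design matrix (e.g. from \code{\link{buildDesign}}).
#' @param y Response: numeric (gaussian), 0/1 (binomial) or non-negative
#'   integer (poisson).
#' @param family "gaussian_identity", "binomial_logit" or "poisson_log".
#' @return Object of class \code{"trophlinkGlm"}: coefficients, deviance,
#'   \code{df_resid} (n minus design rank), \code{converged},
#'   \code{iterations}, \code{fitted}, \code{separation} flag.
#' @export
irlsFit <- function(X, y, family) {
  fam <- familyObject(family)
  if (family == "binomial_logit" && !all(y %in% c(0, 1)))
    stop("binomial response must be 0/1")
  if (family == "poisson_log" && any(y < 0 | y != floor(y)))
    stop("poisson response must be non-negative integers")
  fit <- glm.fit(X, y, family = fam,
                 control = glm.control(epsilon = 1e-8, maxit = 100))
  coefs <- fit$coefficients
  separation <- FALSE
  if (family == "binomial_logit" && any(abs(coefs[!is.na(coefs)]) > 15)) {
    separation <- TRUE
    warning("possible complete separation: |coefficient| > 15 on the logit ",
            "scale; estimates capped at +/- 30")
    coefs <- pmin(pmax(coefs, -30), 30)
  }
  structure(list(family = family, coefficients = coefs,
                 deviance = fit$deviance, rank = fit$rank,
                 df_resid = length(y) - fit$rank,
                 converged = fit$converged, iterations = fit$iter,
                 fitted = fit$fitted.values, y = y, X = X,
                 separation = separation),
            class = "trophlinkGlm")
}

#' @export
print.trophlinkGlm <- function(x, ...) {
  cat(sprintf("GLM (%s): deviance %.4g on %d residual df, %d IRLS iteration(s)%s\n",
              x$family, x$deviance, x$df_resid, x$iterations,
              if (x$converged) "" else " [NOT converged]"))
  invisible(x)
}

#' Type-III deviance table for size-class and season effects
#'
#' Fits the full model \code{response ~ size_class * season} under
#' sum-to-zero contrasts, then refits once per term with that term's
#' design columns removed — main effects are therefore tested in the
#' presence of the interaction (type-III likelihood-ratio tests). Each
#' row reports the term's df (full rank minus reduced rank), the
#' likelihood-ratio deviance (reduced minus full deviance), the reduced
#' model's residual deviance and df, and a chi-square p-value. For the
#' Gaussian family the LR statistic is scaled by the full model's
#' dispersion estimate (residual deviance over residual df) before the
#' chi-square comparison; binomial and Poisson deviances are used as is.
#'
#' @param data data.frame with \code{size_class}, \code{season} and the
#'   response column.
#' @param response Name of the response column.
#' @param family See \code{\link{irlsFit}}.
#' @return data.frame of class \code{"devianceTable"} with one row per
#'   term; attributes \code{full_deviance}, \code{full_df_resid},
#'   \code{dispersion}, \code{n}.
#' @export
type3Table <- function(data, response, family) {
  if (!response %in% names(data)) stop("no column '", response, "' in data")
  y <- data[[response]]
  des <- buildDesign(data, interaction = TRUE)
  full <- irlsFit(des$X, y, family)
  phi <- if (family == "gaussian_identity")
    full$deviance / full$df_resid else 1
  term_ids <- seq_along(des$terms)
  rows <- lapply(term_ids, function(ti) {
    cols <- which(des$assign == ti)
    if (!length(cols))
      return(data.frame(term = des$terms[ti], df = 0, deviance = 0,
                        resid_deviance = full$deviance,
                        resid_df = full$df_resid, p_value = NA_real_))
    red <- irlsFit(des$X[, -cols, drop = FALSE], y, family)
    lr <- red$deviance - full$deviance
    if (lr < -1e-8)
      stop("non-nested refit for term ", des$terms[ti],
           " (negative LR deviance ", lr, ")")
    lr <- max(lr, 0)
    df <- full$rank - red$rank
    data.frame(term = des$terms[ti], df = df, deviance = lr,
               resid_deviance = red$deviance, resid_df = red$df_resid,
               p_value = pchisq(lr / phi, df, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "full_deviance") <- full$deviance
  attr(out, "full_df_resid") <- full$df_resid
  attr(out, "dispersion") <- phi
  attr(out, "n") <- length(y)
  attr(out, "family") <- family
  class(out) <- c("devianceTable", "data.frame")
  out
}

#' @export
print.devianceTable <- function(x, ...) {
  cat(sprintf("Type-III deviance table (%s), full model: deviance %.4g on %d df\n",
              attr(x, "family"), attr(x, "full_deviance"),
              attr(x, "full_df_resid")))
  df <- as.data.frame(x)
  df$signif <- ifelse(is.na(df$p_value), "", ifelse(df$p_value < 0.05, "*", ""))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Normal quantile-quantile pairs for Gaussian GLM residuals
#'
#' Orders the standardized response residuals and pairs them with
#' standard-normal quantiles at probabilities (i - 0.5)/n. The
#' correlation of the pairs is returned as a scalar normality
#' diagnostic (near 1 for normal residuals; \code{NA} when the residuals
#' are constant).
#'
#' @param fit A Gaussian \code{\link{irlsFit}} result.
#' @return list with \code{qq} (data.frame: \code{theoretical},
#'   \code{sample}) and \code{correlation}.
#' @export
qqResiduals <- function(fit) {
  stopifnot(inherits(fit, "trophlinkGlm"))
  if (fit$family != "gaussian_identity")
    stop("QQ residual diagnostic is defined for the gaussian family")
  r <- fit$y - fit$fitted
  n <- length(r)
  if (n < 3) stop("need at least 3 residuals")
  s <- sd(r)
  std <- if (s > 0) (r - mean(r)) / s else rep(0, n)
  qq <- data.frame(theoretical = qnorm((seq_len(n) - 0.5) / n),
                   sample = sort(std))
  corr <- if (s > 0) cor(qq$theoretical, qq$sample) else NA_real_
  list(qq = qq, correlation = corr)
}

#' Per-fish occurrence and abundance responses for the GLMs
#'
#' One row per fish: for each prey group, a 0/1 occurrence indicator and
#' the enumerated number of individuals. Every fish is one observation
#' (each individual is a replicate of its size class); empty stomachs
#' contribute absences and zero counts.
#'
#' @param fish,prey_items See \code{\link{dietTable}}.
#' @param groups Prey groups to include.
#' @return data.frame: \code{fish_id}, \code{season}, \code{size_class},
#'   then \code{occ_<group>} and \code{n_<group>} columns.
#' @export
fishResponseTable <- function(fish, prey_items, groups = preyGroups()) {
  pc <- preyCounts(prey_items)
  out <- fish[, c("fish_id", "season", "size_class")]
  for (g in groups) {
    cnt <- setNames(rep(0L, nrow(fish)), fish$fish_id)
    gi <- pc[pc$group == g, , drop = FALSE]
    cnt[gi$fish_id] <- gi$individuals
    out[[paste0("occ_", g)]] <- as.integer(cnt > 0)
    out[[paste0("n_", g)]] <- as.integer(cnt)
  }
  out
}

#' Type-III deviance tables for every standard response
#'
#' Assembles the full inference table of the analysis: binomial-logit
#' models of each main prey group's occurrence, Poisson-log models of
#' each group's abundance, and Gaussian models of d13C, d15N and trophic
#' level — each tested for size class, season and their interaction.
#'
#' @param fish,prey_items See \code{\link{dietTable}}.
#' @param tl_table Result of \code{\link{trophicLevelTable}} (or NULL to
#'   skip the isotope blocks).
#' @param groups Prey groups modelled individually (default: the five
#'   main categories, excluding "other").
#' @return data.frame with a \code{response} block column followed by the
#'   \code{\link{type3Table}} columns.
#' @export
devianceReport <- function(fish, prey_items, tl_table = NULL,
                           groups = setdiff(preyGroups(), "other")) {
  resp <- fishResponseTable(fish, prey_items, groups)
  blocks <- list()
  for (g in groups) {
    blocks[[paste0("occurrence_", g)]] <-
      type3Table(resp, paste0("occ_", g), "binomial_logit")
    blocks[[paste0("abundance_", g)]] <-
      type3Table(resp, paste0("n_", g), "poisson_log")
  }
  if (!is.null(tl_table)) {
    for (v in c("d13C", "d15N", "TL"))
      blocks[[v]] <- type3Table(tl_table, v, "gaussian_identity")
  }
  out <- do.call(rbind, lapply(names(blocks), function(nm) {
    b <- as.data.frame(blocks[[nm]])
    cbind(response = nm, b,
          full_resid_deviance = attr(blocks[[nm]], "full_deviance"),
          full_resid_df = attr(blocks[[nm]], "full_df_resid"))
  }))
  rownames(out) <- NULL
  out
}
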
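balancedData <- function(reps = 10, classes = sizeClassScheme()$labels,
                         seasons = c("autumn", "winter")) {
  expand.grid(size_class = classes, season = seasons, rep = seq_len(reps),
              stringsAsFactors = FALSE)
}

test_that("sum-to-zero designs are built and aliased columns dropped", {
  d <- balancedData(2)
  des <- buildDesign(d)
  # 2-level season: one column with entries +/- 1 summing to zero
  seas_col <- des$X[, which(des$assign == 2)]
  expect_true(all(seas_col %in% c(-1, 1)))
  expect_equal(sum(seas_col), 0)
  # k classes: k - 1 columns each summing to zero on balanced data
  cls_cols <- des$X[, which(des$assign == 1), drop = FALSE]
  expect_equal(ncol(cls_cols), 5)
  expect_equal(colSums(cls_cols), rep(0, 5), ignore_attr = TRUE)
  expect_equal(length(des$dropped), 0)
  # empty winter small-fish cell: interaction loses one aliased column
  d2 <- d[!(d$size_class == "10-15cm" & d$season == "winter"), ]
  expect_warning(des2 <- buildDesign(d2), "aliased")
  expect_equal(sum(des2$assign == 1), 5)
  expect_equal(sum(des2$assign == 3), 4)
  expect_equal(qr(des2$X)$rank, ncol(des2$X))
})

test_that("IRLS fits reproduce closed forms and OLS", {
  set.seed(51)
  y <- rnorm(30, 5, 2)
  X1 <- matrix(1, 30, 1)
  g <- irlsFit(X1, y, "gaussian_identity")
  expect_equal(unname(g$coefficients), mean(y), tolerance = 1e-12)
  expect_equal(g$deviance, sum((y - mean(y))^2), tolerance = 1e-12)
  # gaussian equals the normal-equations solution
  X <- cbind(1, rnorm(30), rnorm(30))
  gf <- irlsFit(X, y, "gaussian_identity")
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_equal(unname(gf$coefficients), as.numeric(beta), tolerance = 1e-10)
  # binomial intercept-only: logit of the observed proportion
  yb <- c(rep(1, 7), rep(0, 3))
  b <- irlsFit(matrix(1, 10, 1), yb, "binomial_logit")
  expect_equal(unname(b$coefficients), log(0.7 / 0.3), tolerance = 1e-8)
  # poisson intercept-only: log of the sample mean
  yp <- rpois(40, 3.2)
  p <- irlsFit(matrix(1, 40, 1), yp, "poisson_log")
  expect_equal(unname(p$coefficients), log(mean(yp)), tolerance = 1e-8)
  expect_error(irlsFit(X1, y, "binomial_logit"), "0/1")
  expect_error(irlsFit(matrix(1, 3, 1), c(-1, 0, 2), "poisson_log"),
               "non-negative")
})

test_that("small-problem deviances match brute-force likelihood maximisation", {
  set.seed(53)
  for (fam in c("binomial_logit", "poisson_log")) {
    X <- cbind(1, rnorm(12), runif(12))
    y <- if (fam == "binomial_logit") rbinom(12, 1, 0.5) else rpois(12, 2)
    fit <- irlsFit(X, y, fam)
    expect_equal(fit$deviance, oracleGlmDeviance(X, y, fam), tolerance = 1e-4)
  }
})

test_that("separation in a binomial fit is flagged and capped", {
  X <- cbind(1, c(rep(0, 5), rep(1, 5)))
  y <- c(rep(0, 5), rep(1, 5))
  expect_warning(fit <- irlsFit(X, y, "binomial_logit"), "separation")
  expect_true(fit$separation)
  expect_true(all(abs(fit$coefficients) <= 30))
})

test_that("type-III tables test each term in the presence of the others", {
  set.seed(57)
  d <- balancedData(30)
  # strong size effect, no season effect
  eff <- setNames(seq(-2, 2, length.out = 6), sizeClassScheme()$labels)
  d$y <- rbinom(nrow(d), 1, plogis(eff[d$size_class]))
  t3 <- type3Table(d, "y", "binomial_logit")
  expect_equal(t3$term, c("size_class", "season", "size_class:season"))
  expect_equal(t3$df, c(5, 1, 5))
  expect_lt(t3$p_value[t3$term == "size_class"], 0.001)
  expect_gt(t3$p_value[t3$term == "season"], 0.05)
  # LR deviances are the reduced-minus-full deviance and non-negative
  expect_true(all(t3$deviance >= 0))
  expect_equal(t3$resid_deviance - attr(t3, "full_deviance"), t3$deviance,
               tolerance = 1e-8)
  # invariant to factor level ordering
  d2 <- d
  d2$size_class <- factor(d2$size_class, levels = rev(sizeClassScheme()$labels))
  t3b <- type3Table(d2, "y", "binomial_logit")
  expect_equal(t3b$deviance, t3$deviance, tolerance = 1e-6)
  # adding a duplicated (then aliased) design column changes nothing
  des <- buildDesign(d)
  f1 <- irlsFit(des$X, d$y, "binomial_logit")
  f2 <- irlsFit(cbind(des$X, dup = des$X[, 2]), d$y, "binomial_logit")
  expect_equal(f2$deviance, f1$deviance, tolerance = 1e-8)
  expect_equal(f2$rank, f1$rank)
})

test_that("type-III tables agree with an independent implementation", {
  set.seed(59)
  d <- balancedData(6)
  d$y <- rbinom(nrow(d), 1, 0.5)
  d$cnt <- rpois(nrow(d), 2)
  d$iso <- rnorm(nrow(d))
  for (spec in list(list("y", "binomial_logit", binomial()),
                    list("cnt", "poisson_log", poisson()))) {
    t3 <- type3Table(d, spec[[1]], spec[[2]])
    m <- glm(stats::reformulate("size_class * season", spec[[1]]),
             data = d, family = spec[[3]],
             contrasts = list(size_class = "contr.sum", season = "contr.sum"))
    ca <- car::Anova(m, type = 3, test.statistic = "LR")
    expect_equal(t3$deviance, ca[["LR Chisq"]], tolerance = 1e-8)
    expect_equal(t3$p_value, ca[["Pr(>Chisq)"]], tolerance = 1e-8)
  }
  # gaussian: dispersion-scaled statistic matches the F numerator of car
  t3g <- type3Table(d, "iso", "gaussian_identity")
  mg <- glm(iso ~ size_class * season, data = d,
            contrasts = list(size_class = "contr.sum", season = "contr.sum"))
  cag <- car::Anova(mg, type = 3, test.statistic = "F")
  expect_equal(t3g$deviance / attr(t3g, "dispersion") / t3g$df,
               cag$F[seq_len(3)], tolerance = 1e-8)
})

test_that("QQ residual pairs diagnose normality", {
  set.seed(61)
  d <- balancedData(4)
  # residuals that are exact normal scores correlate perfectly
  X <- matrix(1, 100, 1)
  y <- qnorm((seq_len(100) - 0.5) / 100)
  fit <- irlsFit(X, y, "gaussian_identity")
  qq <- qqResiduals(fit)
  expect_equal(qq$correlation, 1, tolerance = 1e-12)
  # constant residuals: undefined correlation reported as NA
  fc <- irlsFit(cbind(rep(1, 5)), rep(2, 5), "gaussian_identity")
  expect_true(is.na(qqResiduals(fc)$correlation))
  expect_error(qqResiduals(irlsFit(matrix(1, 2, 1), c(1, 2),
                                   "gaussian_identity")),
               "at least 3")
  expect_error(qqResiduals(irlsFit(matrix(1, 5, 1), c(0, 1, 0, 1, 1),
                                   "binomial_logit")), "gaussian")
  # normal draws give correlations near 1 in nearly all replicates
  hits <- 0
  for (r in 1:40) {
    f <- irlsFit(matrix(1, 1000, 1), rnorm(1000), "gaussian_identity")
    if (qqResiduals(f)$correlation > 0.995) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.95)
})

test_that("the deviance report assembles all response blocks", {
  study <- simulateStudy(smallConfig(seed = 7))
  res <- baselineForStations(study$baseline, study$stations)
  tl <- trophicLevelTable(study$isotopes, study$fish, res$baseline)
  rep_ <- suppressWarnings(devianceReport(study$fish, study$prey_items, tl))
  expect_setequal(unique(rep_$response),
                  c(paste0("occurrence_", setdiff(preyGroups(), "other")),
                    paste0("abundance_", setdiff(preyGroups(), "other")),
                    "d13C", "d15N", "TL"))
  expect_true(all(rep_$deviance >= 0))
  # every block carries the three model terms
  expect_true(all(table(rep_$response) == 3))
})
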
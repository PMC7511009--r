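# Independent oracles and tiny fixture builders shared across tests.

# Minimal-explanation oracle for prey enumeration: searches upward for the
# smallest number of individuals that can account for the recovered parts.
# Model: a whole individual is intact (donates no loose parts); any other
# individual can donate at most 2 parts to the pooled paired-structure
# count of its taxon; uncountable remains require at least one individual
# of the taxon to exist, whatever its kind.
oracleEnumerate <- function(items) {
  if (NROW(items) == 0) return(0L)
  w <- sum(items$raw_count[items$part_type == "whole"])
  p <- sum(items$raw_count[items$part_type == "paired_part"])
  has_rem <- any(items$part_type == "uncountable_remains")
  for (m in 0:1000) {
    donors <- m - w
    if (donors < 0) next
    if (2 * donors < p) next
    if (has_rem && m == 0) next
    return(as.integer(m))
  }
  stop("oracle failed")
}

# random single-taxon item sets with <= max_items rows
randomItems <- function(max_items = 6) {
  n <- sample.int(max_items + 1, 1) - 1L
  if (n == 0) return(data.frame(part_type = character(0), raw_count = integer(0)))
  data.frame(
    part_type = sample(c("whole", "paired_part", "uncountable_remains"),
                       n, replace = TRUE),
    raw_count = sample.int(5, n, replace = TRUE))
}

# closed-form dual-route ordinary-kriging oracle (explicit inverse)
oracleKrige <- function(obs, model, target) {
  D <- trophlink:::pairwiseDistanceKm(obs)
  C <- covValue(model, D)
  diag(C) <- model$sill + model$nugget + 1e-8 * model$sill
  c0 <- covValue(model, haversineKm(obs$lat, obs$lon, target$lat, target$lon))
  Ci <- solve(C)
  one <- rep(1, nrow(obs))
  mu <- (sum(one * (Ci %*% c0)) - 1) / sum(Ci %*% one)
  lambda <- Ci %*% (c0 - mu * one)
  pred <- sum(lambda * obs$d15N)
  kvar <- model$sill + model$nugget - sum(lambda * c0) - mu
  list(pred = pred, var = kvar, lambda = as.numeric(lambda))
}

# brute-force maximum-likelihood GLM deviance via direct optimisation of
# the log-likelihood (no IRLS)
oracleGlmDeviance <- function(X, y, family) {
  negll <- switch(family,
    binomial_logit = function(b) {
      eta <- X %*% b
      -sum(y * eta - log1p(exp(eta)))
    },
    poisson_log = function(b) {
      eta <- X %*% b
      -sum(y * eta - exp(eta))
    })
  opt <- optim(rep(0, ncol(X)), negll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  satll <- switch(family,
    binomial_logit = 0,
    poisson_log = sum(ifelse(y > 0, y * log(y) - y, 0)))
  2 * (satll + opt$value)
}

# dense grid-search oracle for the weighted covariance fit
oracleGridFit <- function(emp, sill_grid, range_grid) {
  best <- c(obj = Inf, sill = NA, range = NA)
  for (s in sill_grid) for (r in range_grid) {
    pred <- s * exp(-(emp$bin_mid / r)^2)
    obj <- sum(emp$n_pairs * (emp$cov_hat - pred)^2)
    if (obj < best["obj"]) best <- c(obj = obj, sill = s, range = r)
  }
  best
}

# fixture: fish table with one stomach each; ids F1..Fn
makeFish <- function(n, season = "autumn", size_class = "20-25cm") {
  data.frame(fish_id = paste0("F", seq_len(n)),
             station_id = "S1", season = season, size_class = size_class,
             length_mm = 210, gape_mm = 20, stringsAsFactors = FALSE)
}

# fixture: one whole-prey item row per (fish, group)
makeItems <- function(fish_ids, group, count = 1) {
  data.frame(stomach_id = paste0("ST-", fish_ids), fish_id = fish_ids,
             taxon = group, group = group, part_type = "whole",
             raw_count = count, stringsAsFactors = FALSE)
}

# small config for fast end-to-end runs (keeps the default study structure)
smallConfig <- function(seed = 1, ...) {
  syntheticConfig(seed = seed, n_stations = 12, n_baseline = 30, ...)
}
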
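test_that("parsimonious enumeration follows the part-type rules", {
  # four paired otoliths -> two individuals
  expect_identical(
    enumeratePrey(data.frame(part_type = "paired_part", raw_count = 4)), 2L)
  # odd paired counts round up (minimal donor count)
  expect_identical(
    enumeratePrey(data.frame(part_type = "paired_part", raw_count = 5)), 3L)
  # muscle remains only attest one individual
  expect_identical(
    enumeratePrey(data.frame(part_type = "uncountable_remains", raw_count = 1)), 1L)
  # paired claws already explain the gill remains of the same taxon
  expect_identical(
    enumeratePrey(data.frame(part_type = c("paired_part", "uncountable_remains"),
                             raw_count = c(3, 1))), 2L)
  # whole individuals count as themselves and silence remains too
  expect_identical(
    enumeratePrey(data.frame(part_type = c("whole", "uncountable_remains"),
                             raw_count = c(2, 1))), 2L)
  expect_identical(enumeratePrey(data.frame(part_type = character(0),
                                            raw_count = integer(0))), 0L)
  expect_error(enumeratePrey(data.frame(part_type = "gizzard", raw_count = 1)),
               "unknown part_type")
  expect_error(enumeratePrey(data.frame(part_type = "whole", raw_count = 0)),
               "positive integer")
})

test_that("enumeration equals the minimal-explanation oracle on small item sets", {
  set.seed(101)
  for (i in 1:500) {
    items <- randomItems(6)
    expect_identical(enumeratePrey(items), oracleEnumerate(items),
                     info = paste(capture.output(print(items)), collapse = "\n"))
  }
})

test_that("vacuity is the exact empty-stomach percentage", {
  fish <- makeFish(10)
  items <- makeItems(fish$fish_id, "fish")
  expect_equal(vacuity(fish, items)$pct_V, 0)
  # 124 stomachs with 20 empty -> 16.1%
  fish2 <- makeFish(124)
  items2 <- makeItems(fish2$fish_id[1:104], "fish")
  v <- vacuity(fish2, items2)
  expect_equal(v$n_empty, 20)
  expect_equal(v$pct_V, 100 * 20 / 124)
  # all empty -> 100%
  expect_equal(vacuity(fish2, items2[0, ])$pct_V, 100)
  expect_error(vacuity(fish2[0, ], items2), "empty")
  # invariant to stomach ordering
  shuf <- fish2[sample.int(nrow(fish2)), ]
  expect_equal(vacuity(shuf, items2)$pct_V, v$pct_V)
})

test_that("occurrence indices follow O_i = J_i / P over non-empty stomachs", {
  fish <- makeFish(12)
  # 10 non-empty: fish in 6, mollusks in 4, both in 2, other prey in the
  # remaining 2; plus 2 empty stomachs
  itemsA <- makeItems(fish$fish_id[1:6], "fish")
  itemsB <- makeItems(fish$fish_id[5:8], "mollusk")
  itemsC <- makeItems(fish$fish_id[9:10], "other")
  items <- rbind(itemsA, itemsB, itemsC)
  occ <- occurrenceIndices(fish, items, groups = c("fish", "mollusk"))
  expect_equal(occ$P, c(10, 10))
  expect_equal(occ$O_i, c(0.6, 0.4))
  expect_equal(occ$pct_O, c(60, 40))
  expect_equal(sum(occ$pct_O), 100, tolerance = 1e-9)
  # mixed stomachs make the full O_i sum exceed 1
  occ_all <- occurrenceIndices(fish, items, groups = c("fish", "mollusk", "other"))
  expect_gt(sum(occ_all$O_i), 1)
  expect_equal(sum(occ_all$pct_O), 100, tolerance = 1e-9)
  # every non-empty stomach contains the group -> O = 1
  occ1 <- occurrenceIndices(fish[1:6, ], itemsA, groups = "fish")
  expect_equal(occ1$O_i, 1)
  # P = 0 is an error distinct from the empty-input error
  expect_error(occurrenceIndices(fish, items[0, ]), "non-empty")
  expect_error(occurrenceIndices(fish[0, ], items), "empty")
})

test_that("abundance indices normalise enumerated individuals to 100", {
  fish <- makeFish(3)
  items <- rbind(makeItems(fish$fish_id[1], "fish", 63),
                 makeItems(fish$fish_id[2], "mollusk", 27),
                 makeItems(fish$fish_id[3], "other", 10))
  ab <- abundanceIndices(fish, items, groups = c("fish", "mollusk", "other"))
  expect_equal(ab$N_i, c(63, 27, 10))
  expect_equal(ab$pct_N, c(63, 27, 10))
  # single group present -> 100
  ab1 <- abundanceIndices(fish[1, ], items[1, ], groups = "fish")
  expect_equal(ab1$pct_N, 100)
  expect_error(abundanceIndices(fish, items[0, ]), "sum N_i = 0")
})

test_that("mixed part types aggregate as a per-stomach oracle sum", {
  set.seed(202)
  fish <- makeFish(3)
  rows <- list()
  for (f in fish$fish_id) for (g in c("fish", "benthic_crustacean")) {
    it <- randomItems(4)
    if (nrow(it) == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      stomach_id = paste0("ST-", f), fish_id = f, taxon = g, group = g,
      part_type = it$part_type, raw_count = it$raw_count)
  }
  items <- do.call(rbind, rows)
  ab <- abundanceIndices(fish, items, groups = c("fish", "benthic_crustacean"))
  manual <- vapply(c("fish", "benthic_crustacean"), function(g) {
    sum(vapply(fish$fish_id, function(f) {
      it <- items[items$fish_id == f & items$group == g, ]
      oracleEnumerate(it)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(ab$N_i, unname(manual))
  # invariance to item row ordering
  ab2 <- abundanceIndices(fish, items[sample.int(nrow(items)), ],
                          groups = c("fish", "benthic_crustacean"))
  expect_equal(ab2$N_i, ab$N_i)
})

test_that("diet table covers cells plus pooled rows and stays consistent", {
  study <- simulateStudy(smallConfig(seed = 3))
  tab <- dietTable(study$fish, study$prey_items)
  pooled <- tab[tab$season == "all", ]
  direct_occ <- occurrenceIndices(study$fish, study$prey_items)
  direct_ab <- abundanceIndices(study$fish, study$prey_items)
  expect_equal(pooled$O_i[match(direct_occ$group, pooled$group)],
               direct_occ$O_i)
  expect_equal(pooled$N_i[match(direct_ab$group, pooled$group)],
               direct_ab$N_i)
  # %O and %N sum to 100 in every populated cell
  for (cell in split(tab, paste(tab$season, tab$size_class))) {
    if (all(is.na(cell$pct_O))) next
    expect_equal(sum(cell$pct_O), 100, tolerance = 1e-6)
    expect_equal(sum(cell$pct_N), 100, tolerance = 1e-6)
  }
  # configured ontogenetic rise of fish prey shows as a monotone %O trend
  aut <- tab[tab$season == "autumn" & tab$group == "fish", ]
  aut <- aut[match(sizeClassScheme()$labels, aut$size_class), ]
  expect_gt(cor(seq_len(6), aut$pct_O, method = "spearman"), 0.5)
})

test_that("size classes use half-open 5-cm bins with an open top class", {
  sc <- sizeClassScheme()
  expect_equal(as.character(assignSizeClass(c(106, 149.9, 150, 528), sc)),
               c("10-15cm", "10-15cm", "15-20cm", "35+"))
  expect_error(assignSizeClass(c(120, 80), sc), "outside the class scheme")
})
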
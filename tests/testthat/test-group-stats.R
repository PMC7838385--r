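toy_annotation <- function(probes, categories) {
  tibble::tibble(probe_id = probes, category = categories,
                 gene_family = paste0("fam_", probes),
                 subcategory = categories, lineage = "Bacteria;X")
}

test_that("richness counts detected probes per sample and per group", {
  design <- toy_design(1) # 4 samples, L1S1/L2S1 low, L3S1/L4S1 high
  probes <- paste0("p", 1:10)
  ann <- toy_annotation(probes, rep(c("carbon cycling", "stress response"), 5))
  m <- matrix(0, 10, 4, dimnames = list(probes, design$sample_id))
  m[1:6, 1] <- 1   # sample 1 (low): p1..p6
  m[4:8, 3] <- 1   # sample 3 (high): p4..p8
  r <- richness(signal_from_matrix(m), design, ann)
  expect_equal(r$richness[r$level == "sample" & r$id == "L1S1" & r$category == "all"], 6)
  expect_equal(r$richness[r$level == "group" & r$id == "low" & r$category == "all"], 6)
  expect_equal(r$richness[r$level == "group" & r$id == "high" & r$category == "all"], 5)
  # per-category counts sum to the overall count
  low_cats <- r[r$level == "group" & r$id == "low" & r$category != "all", ]
  expect_equal(sum(low_cats$richness), 6)
  # all-zero matrix: nothing detected anywhere
  r0 <- richness(signal_from_matrix(m * 0), design, ann)
  expect_equal(nrow(r0), 0)
  # adding a detection never decreases counts (monotonicity)
  m2 <- m; m2[9, 2] <- 1
  r2 <- richness(signal_from_matrix(m2), design, ann)
  both <- dplyr::inner_join(r, r2, by = c("level", "id", "category"))
  expect_true(all(both$richness.y >= both$richness.x))
})

test_that("overlap performs set algebra with union percentages", {
  design <- toy_design(1)
  probes <- paste0("p", 1:14)
  ann <- toy_annotation(probes, rep("carbon cycling", 14))
  m <- matrix(0, 14, 4, dimnames = list(probes, design$sample_id))
  m[1:8, 1] <- 1    # low group detects p1..p8
  m[5:14, 3] <- 1   # high group detects p5..p14
  ov <- overlap(signal_from_matrix(m), design)
  expect_equal(ov$n_shared, 4)
  expect_equal(ov$n_unique_low, 4)
  expect_equal(ov$n_unique_high, 6)
  expect_equal(ov$pct_shared, 100 * 4 / 14, tolerance = 1e-9)
  expect_equal(ov$pct_shared + ov$pct_unique_low + ov$pct_unique_high, 100,
               tolerance = 0.01)
  # identical sets
  m2 <- matrix(1, 3, 4, dimnames = list(paste0("q", 1:3), design$sample_id))
  ov2 <- overlap(signal_from_matrix(m2), design)
  expect_equal(ov2$pct_shared, 100)
  expect_equal(ov2$n_unique_low + ov2$n_unique_high, 0)
  # disjoint sets
  m3 <- matrix(0, 4, 4, dimnames = list(paste0("r", 1:4), design$sample_id))
  m3[1:2, 1] <- 1; m3[3:4, 3] <- 1
  ov3 <- overlap(signal_from_matrix(m3), design)
  expect_equal(ov3$pct_shared, 0)
})

test_that("category t test matches an independent Welch computation", {
  design <- toy_design(2) # 4 samples per group
  probes <- "p1"
  ann <- toy_annotation(probes, "stress response")
  a <- c(1.1, 0.9, 1.0, 1.2)  # low group sample sums
  b <- c(1.6, 1.5, 1.7, 1.4)  # high group
  m <- matrix(c(a, b)[match(design$sample_id, design$sample_id)], nrow = 1,
              dimnames = list(probes, design$sample_id))
  m[1, design$elevation_group == "low"] <- a
  m[1, design$elevation_group == "high"] <- b
  tt <- category_ttest(signal_from_matrix(m), design, ann)
  # hand-coded Welch formula
  se2 <- var(b) / 4 + var(a) / 4
  t_hand <- (mean(b) - mean(a)) / sqrt(se2)
  df_hand <- se2^2 / ((var(b) / 4)^2 / 3 + (var(a) / 4)^2 / 3)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  expect_equal(tt$statistic, t_hand, tolerance = 1e-9)
  expect_equal(tt$df, df_hand, tolerance = 1e-9)
  expect_equal(tt$p_value, p_hand, tolerance = 1e-9)
  expect_equal(tt$se_low, sd(a) / 2, tolerance = 1e-12)
})

test_that("degenerate and separated groups are handled", {
  design <- toy_design(2)
  ann <- toy_annotation(c("p1", "p2"), c("carbon cycling", "stress response"))
  m <- matrix(0, 2, 8, dimnames = list(c("p1", "p2"), design$sample_id))
  m[1, ] <- rep(c(1, 2, 3, 1), 2)              # identical group profiles
  m[2, design$elevation_group == "low"] <- c(1, 2, 3, 1)
  m[2, design$elevation_group == "high"] <- c(11, 12, 13, 11) # +10 shift
  tt <- category_ttest(signal_from_matrix(m), design, ann)
  expect_equal(tt$statistic[tt$unit == "carbon cycling"], 0)
  expect_equal(tt$p_value[tt$unit == "carbon cycling"], 1)
  expect_lt(tt$p_value[tt$unit == "stress response"], 0.05)
  # unit absent from one group: flagged, not an exception
  m2 <- m; m2[2, design$elevation_group == "low"] <- 0
  tt2 <- category_ttest(signal_from_matrix(m2), design, ann)
  expect_false(tt2$testable[tt2$unit == "stress response"])
  expect_true(is.na(tt2$p_value[tt2$unit == "stress response"]))
})

test_that("taxa-function aggregation splits a category by lineage", {
  design <- toy_design(1)
  ann <- tibble::tibble(probe_id = c("p1", "p2", "p3"),
                        category = "carbon cycling",
                        gene_family = "fam", subcategory = "sub",
                        lineage = c("Firmicutes", "Firmicutes", "Actinobacteria"))
  m <- matrix(c(7, 0, 3,   0, 0, 0,   2, 1, 3,   1, 1, 3), nrow = 3,
              dimnames = list(ann$probe_id, design$sample_id))
  agg <- taxa_function_aggregate(signal_from_matrix(m), ann, design,
                                 "carbon cycling")
  # hand sums: Firmicutes low = 7+0+0+0 = 7, high = 2+1+1+1 = 5
  expect_equal(agg$s_low[agg$lineage == "Firmicutes"], 7)
  expect_equal(agg$s_high[agg$lineage == "Firmicutes"], 5)
  # lineage absent from one group is exclusive, untested
  m2 <- m; m2["p3", design$elevation_group == "low"] <- 0
  agg2 <- taxa_function_aggregate(signal_from_matrix(m2), ann, design,
                                  "carbon cycling")
  expect_equal(agg2$exclusive_to[agg2$lineage == "Actinobacteria"], "high")
  expect_true(is.na(agg2$p_value[agg2$lineage == "Actinobacteria"]))
  expect_error(taxa_function_aggregate(signal_from_matrix(m), ann, design,
                                       "nope"), "unknown")
})

test_that("single lineage carries the whole category total", {
  design <- toy_design(1)
  ann <- tibble::tibble(probe_id = c("p1", "p2"), category = "carbon cycling",
                        gene_family = "fam", subcategory = "sub",
                        lineage = "Firmicutes")
  m <- matrix(1:8 + 0, 2, 4, dimnames = list(ann$probe_id, design$sample_id))
  agg <- taxa_function_aggregate(signal_from_matrix(m), ann, design,
                                 "carbon cycling")
  expect_equal(agg$s_low + agg$s_high, sum(m))
})
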
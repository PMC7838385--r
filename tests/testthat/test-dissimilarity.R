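test_that("distance metrics obey their closed forms", {
  x <- rbind(s1 = c(1, 2, 3), s2 = c(1, 2, 3))
  for (m in c("euclidean", "bray", "horn")) {
    expect_equal(as.numeric(distance_matrix(x, m)), 0, tolerance = 1e-12)
  }
  # disjoint supports
  y <- rbind(s1 = c(5, 0, 2, 0), s2 = c(0, 3, 0, 1))
  expect_equal(as.numeric(distance_matrix(y, "bray")), 1)
  expect_equal(as.numeric(distance_matrix(y, "horn")), 1)
  # pythagorean toy
  z <- rbind(s1 = c(0, 0), s2 = c(3, 4))
  expect_equal(as.numeric(distance_matrix(z, "euclidean")), 5)
  # all-zero sample undefined for abundance metrics
  w <- rbind(s1 = c(0, 0), s2 = c(1, 2))
  expect_error(distance_matrix(w, "bray"), "all-zero")
  expect_error(distance_matrix(rbind(s1 = 1:3), "euclidean"), "two samples")
})

test_that("permutation p-values on small designs match brute-force enumeration", {
  set.seed(21)
  m <- matrix(abs(rnorm(4 * 5)), 4, dimnames = list(paste0("s", 1:4), NULL))
  D <- distance_matrix(m, "euclidean")
  groups <- c("a", "a", "b", "b")
  dm <- as.matrix(D)
  # independent brute force over all C(4,2) = 6 labelings
  combos <- combn(4, 2, simplify = FALSE)
  brute <- function(stat_fn, tail) {
    stats <- sapply(combos, function(idx) {
      lab <- rep("b", 4); lab[idx] <- "a"
      stat_fn(dm, lab)
    })
    obs <- stat_fn(dm, groups)
    if (tail == "greater") mean(stats >= obs - 1e-12) else mean(stats <= obs + 1e-12)
  }
  expect_equal(permanova(D, groups, exact = TRUE)$p_value,
               brute(fmenr:::permanova_stat, "greater"))
  expect_equal(anosim(D, groups, exact = TRUE)$p_value,
               brute(fmenr:::anosim_stat, "greater"))
  expect_equal(mrpp(D, groups, exact = TRUE)$p_value,
               brute(fmenr:::mrpp_stat, "less"))
  expect_equal(permanova(D, groups, exact = TRUE)$n_permutations, 6)
})

test_that("PERMANOVA on 1-D euclidean distances equals classical ANOVA F", {
  set.seed(31)
  y <- rnorm(9)
  groups <- rep(c("a", "b", "c"), each = 3)
  D <- dist(matrix(y))
  f_perm <- permanova(D, groups, n_perm = 9, seed = 1)$statistic
  f_aov <- summary(stats::aov(y ~ groups))[[1]]$`F value`[1]
  expect_equal(f_perm, f_aov, tolerance = 1e-9)
})

test_that("statistics agree with vegan's implementations", {
  set.seed(41)
  m <- matrix(abs(rnorm(6 * 10)), 6, dimnames = list(paste0("s", 1:6), NULL))
  groups <- rep(c("x", "y"), each = 3)
  for (metric in c("euclidean", "bray", "horn")) {
    D <- distance_matrix(m, metric)
    expect_equal(permanova(D, groups, n_perm = 9, seed = 1)$statistic,
                 vegan::adonis2(D ~ groups, permutations = 2)$F[1],
                 tolerance = 1e-9)
    expect_equal(anosim(D, groups, n_perm = 9, seed = 1)$statistic,
                 as.numeric(vegan::anosim(D, groups, permutations = 2)$statistic),
                 tolerance = 1e-9)
    expect_equal(mrpp(D, groups, n_perm = 9, seed = 1)$statistic,
                 vegan::mrpp(D, groups, permutations = 2)$delta,
                 tolerance = 1e-9)
  }
})

test_that("ANOSIM hits its closed-form extremes", {
  # complete separation: every between distance above every within distance
  m <- rbind(s1 = c(0, 0), s2 = c(0.1, 0), s3 = c(10, 10), s4 = c(10.1, 10))
  D <- distance_matrix(m, "euclidean")
  expect_equal(anosim(D, c("a", "a", "b", "b"), n_perm = 9, seed = 1)$statistic, 1)
  # total ties: all distances equal
  dm <- matrix(1, 4, 4); diag(dm) <- 0
  expect_equal(fmenr:::anosim_stat(dm, c("a", "a", "b", "b")), 0)
  # expectation of R over all labelings is zero
  set.seed(3)
  dm6 <- as.matrix(dist(matrix(rnorm(12), 6)))
  labs <- fmenr:::enumerate_labelings(rep(c("a", "b"), each = 3))
  expect_equal(mean(sapply(labs, function(l) fmenr:::anosim_stat(dm6, l))), 0,
               tolerance = 1e-12)
})

test_that("MRPP delta is the weighted within-group mean distance", {
  # each group a pair of identical samples -> delta 0
  m <- rbind(s1 = c(1, 2), s2 = c(1, 2), s3 = c(5, 7), s4 = c(5, 7))
  D <- distance_matrix(m, "euclidean")
  expect_equal(mrpp(D, c("a", "a", "b", "b"), n_perm = 9, seed = 1)$statistic, 0)
  # one group: delta reduces to the overall mean pairwise distance
  set.seed(7)
  dm <- as.matrix(dist(matrix(rnorm(10), 5)))
  expect_equal(fmenr:::mrpp_stat(dm, rep("g", 5)),
               mean(dm[upper.tri(dm)]), tolerance = 1e-12)
})

test_that("observed statistic is always in its own null", {
  set.seed(51)
  m <- matrix(abs(rnorm(8 * 6)), 8, dimnames = list(paste0("s", 1:8), NULL))
  D <- distance_matrix(m, "bray")
  groups <- rep(c("a", "b"), each = 4)
  for (f in list(permanova, anosim, mrpp)) {
    r <- f(D, groups, n_perm = 99, seed = 2)
    expect_gte(r$p_value, 1 / 100)
    expect_lte(r$p_value, 1)
  }
})

test_that("relabeling samples together leaves the statistic unchanged", {
  set.seed(61)
  m <- matrix(abs(rnorm(6 * 8)), 6, dimnames = list(paste0("s", 1:6), NULL))
  D <- as.matrix(distance_matrix(m, "euclidean"))
  groups <- c("a", "a", "a", "b", "b", "b")
  perm <- sample(6)
  expect_equal(fmenr:::permanova_stat(D, groups),
               fmenr:::permanova_stat(D[perm, perm], groups[perm]),
               tolerance = 1e-12)
})

test_that("group contrasts are rejected by every test on clean planted data", {
  d <- clean_planted_dataset(seed = 13, stress_effect = 2)
  sig <- preprocess_dataset(d)
  res <- compare_groups_dissim(sig, d$design, n_perm = 199, seed = 5)
  expect_true(all(res$p_value < 0.05))
  expect_equal(nrow(res), 9)
})

test_that("invalid group structures are rejected", {
  D <- dist(matrix(rnorm(8), 4))
  expect_error(permanova(D, c("a", "a", "a", "b")), "at least two samples")
  expect_error(permanova(D, rep("a", 4)), "two groups")
  expect_error(permanova(D, c("a", "b")), "length")
})

test_that("stratified permutation swaps whole lakes", {
  design <- toy_design(3)
  set.seed(71)
  m <- matrix(abs(rnorm(12 * 8)), 12,
              dimnames = list(design$sample_id, NULL))
  D <- distance_matrix(m, "euclidean")
  r <- permanova(D, design$elevation_group, strata = design$lake_id,
                 exact = TRUE)
  # 4 strata in two groups of two: C(4,2) = 6 distinct stratum labelings
  expect_equal(r$n_permutations, 6)
  expect_gte(r$p_value, 1 / 6)
  expect_error(permanova(D, rep(c("a", "b"), 6), strata = design$lake_id),
               "single group label")
})
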
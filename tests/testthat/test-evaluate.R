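test_that("ARI matches its definition on hand-built and random partitions", {
  a <- label_vector(c(1, 1, 2, 2), cell_ids(4))
  b <- label_vector(c(2, 2, 1, 1), cell_ids(4))
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, b), 1)      # relabel invariance

  d <- label_vector(c(1, 2, 1, 2), cell_ids(4))
  expect_equal(adjusted_rand_index(a, d), ari_oracle(c(1, 1, 2, 2), c(1, 2, 1, 2)),
               tolerance = 1e-12)

  for (seed in 1:25) {
    x <- random_labels(40, 3, seed)
    y <- random_labels(40, 4, seed + 1000)
    expect_equal(adjusted_rand_index(x, y),
                 ari_oracle(unclass(x), unclass(y)), tolerance = 1e-12)
    # symmetry and permutation invariance
    expect_equal(adjusted_rand_index(x, y), adjusted_rand_index(y, x))
    perm <- sample(0:3)
    yp <- label_vector(perm[unclass(y) + 1], names(y))
    expect_equal(adjusted_rand_index(x, yp), adjusted_rand_index(x, y),
                 tolerance = 1e-12)
  }
  expect_error(adjusted_rand_index(a, random_labels(5, 2)), "length")
})

test_that("ARI agrees with the mclust reference implementation", {
  for (seed in 1:10) {
    x <- random_labels(60, 4, seed)
    y <- random_labels(60, 3, seed + 99)
    expect_equal(adjusted_rand_index(x, y),
                 mclust::adjustedRandIndex(unclass(x), unclass(y)),
                 tolerance = 1e-12)
  }
})

test_that("NMI uses the arithmetic-mean normalization with the zero-entropy convention", {
  a <- label_vector(c(1, 1, 2, 2), cell_ids(4))
  expect_equal(normalized_mutual_information(a, a), 1)
  expect_equal(normalized_mutual_information(
    a, label_vector(rep(1, 4), cell_ids(4))), 0)    # constant partition -> 0

  d <- label_vector(c(1, 2, 1, 2), cell_ids(4))
  expect_equal(normalized_mutual_information(a, d),
               nmi_oracle(c(1, 1, 2, 2), c(1, 2, 1, 2)), tolerance = 1e-12)

  for (seed in 1:25) {
    x <- random_labels(40, 3, seed)
    y <- random_labels(40, 4, seed + 2000)
    expect_equal(normalized_mutual_information(x, y),
                 nmi_oracle(unclass(x), unclass(y)), tolerance = 1e-12)
    expect_equal(normalized_mutual_information(x, y),
                 normalized_mutual_information(y, x))
    expect_gte(normalized_mutual_information(x, y), 0)
    expect_lte(normalized_mutual_information(x, y), 1)
  }
})

test_that("ARI of independent uniform partitions centers on zero", {
  set.seed(123)
  vals <- replicate(2000, {
    x <- sample(0:3, 200, replace = TRUE)
    y <- sample(0:3, 200, replace = TRUE)
    adjusted_rand_index(label_vector(x, cell_ids(200)),
                        label_vector(y, cell_ids(200)))
  })
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("marker ranking handles degenerate, separated and over-asking cases", {
  set.seed(31)
  n <- 10
  labels <- label_vector(rep(c("A", "B"), each = 5), cell_ids(n))
  X <- matrix(rnorm(n * 3, mean = 10), n, 3,
              dimnames = list(cell_ids(n), c("flat", "up_in_A", "noise")))
  X[, "flat"] <- 5                                   # constant: p = 1
  X[1:5, "up_in_A"] <- 100 + (1:5)                   # strictly above the rest
  X[6:10, "up_in_A"] <- 1:5                          # no ties anywhere

  mt <- rank_markers(X, labels, top_n = 10)          # top_n > p: all returned
  expect_equal(sum(mt$cluster == "A"), 3)
  a <- mt[mt$cluster == "A", ]
  expect_equal(a$p_value[a$feature == "flat"], 1)
  # perfectly separated 5v5 feature: in-group rank sum takes its extreme
  # value 6+7+8+9+10 = 40 (and 15 for the complementary group)
  expect_equal(a$statistic[a$feature == "up_in_A"], 40)
  b <- mt[mt$cluster == "B", ]
  expect_equal(b$statistic[b$feature == "up_in_A"], 15)
  expect_equal(a$feature[a$rank == 1], "up_in_A")

  expect_error(rank_markers(X, label_vector(rep(1, n), cell_ids(n))),
               "at least 2 clusters")
  lab1 <- label_vector(c("A", rep("B", n - 1)), cell_ids(n))
  expect_warning(rank_markers(X, lab1, top_n = 2), "fewer than 2 cells")
})

test_that("marker p-values match the tie-corrected normal-approximation rank-sum test", {
  set.seed(77)
  n <- 30
  labels <- label_vector(rep(c("A", "B", "C"), each = 10), cell_ids(n))
  X <- matrix(rpois(n * 8, 4), n, 8,
              dimnames = list(cell_ids(n), paste0("g", 1:8)))
  X <- X * 1.0
  mt <- rank_markers(X, labels, top_n = 8)
  for (cl in c("A", "B", "C")) {
    in_cl <- label_values(labels) == cl
    for (g in paste0("g", 1:8)) {
      got <- mt$p_value[mt$cluster == cl & mt$feature == g]
      ref <- suppressWarnings(
        stats::wilcox.test(X[in_cl, g], X[!in_cl, g],
                           exact = FALSE, correct = TRUE))$p.value
      expect_equal(got, ref, tolerance = 1e-12)
    }
  }
})

test_that("a planted up-regulated feature ranks first in almost all simulations", {
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    n <- 40
    z <- rep(0:1, each = 20)
    X <- matrix(rpois(n * 10, 5), n, 10,
                dimnames = list(cell_ids(n), paste0("g", 1:10))) * 1.0
    X[z == 1, "g1"] <- X[z == 1, "g1"] + rpois(20, 15)  # planted marker
    mt <- rank_markers(X, label_vector(z, cell_ids(n)), top_n = 1)
    if (mt$feature[mt$cluster == "1" & mt$rank == 1] == "g1") hits <- hits + 1
  }
  expect_gte(hits, 95)
})
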
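test_that("juvenile filtering keeps the 20 mm boundary and reports ids", {
  vals <- cbind(SL = c(15, 20, 25), M1 = c(3, 4, 5))
  m <- morpho_table(vals, c("a", "b", "c"), rep("g", 3),
                    c("SL", "morphometric_SL"))
  f <- filter_juveniles(m)
  expect_equal(rownames(f), c("b", "c"))
  expect_equal(attr(f, "removed_ids"), "a")
  # nothing below the cutoff: identical table, nothing removed
  f2 <- filter_juveniles(f)
  expect_equal(unname(unclass(f2)), unname(unclass(f)),
               ignore_attr = TRUE)
  expect_equal(rownames(f2), rownames(f))
  expect_length(attr(f2, "removed_ids"), 0L)
  expect_error(filter_juveniles(m, min_sl = 1000), "no specimens")
  # generator ground truth: removed count equals simulated juvenile count
  sim <- simulate_morpho(n_pop = 3, n_per_pop = 10, juvenile_frac = 0.1,
                         seed = 11)
  fs <- filter_juveniles(sim)
  expect_setequal(attr(fs, "removed_ids"),
                  attr(sim, "truth")$juvenile_ids)
})

test_that("imputation is within-group least squares on SL", {
  # variable = 2 * SL exactly: missing row at SL = 50 imputes to 100
  vals <- cbind(SL = c(40, 60, 50), M1 = c(80, 120, NA))
  m <- morpho_table(vals, c("a", "b", "c"), rep("g", 3),
                    c("SL", "morphometric_SL"))
  mi <- impute_missing(m)
  expect_equal(unname(mi["c", "M1"]), 100)
  expect_equal(attr(mi, "imputed")$id, "c")
  # table with no missing cells is unchanged (and nothing is imputed)
  mi_again <- impute_missing(mi)
  expect_equal(unname(unclass(mi_again)), unname(unclass(mi)),
               ignore_attr = TRUE)
  expect_equal(nrow(attr(mi_again, "imputed")), 0L)
  # constant variable within group imputes the constant (slope 0)
  vals2 <- cbind(SL = c(40, 60, 50), M1 = c(7, 7, NA))
  m2 <- morpho_table(vals2, c("a", "b", "c"), rep("g", 3),
                     c("SL", "morphometric_SL"))
  expect_equal(unname(impute_missing(m2)["c", "M1"]), 7)
  # too few observed values in the group is an error naming the group
  vals3 <- cbind(SL = c(40, 60, 50), M1 = c(7, NA, NA))
  m3 <- morpho_table(vals3, c("a", "b", "c"), c("g1", "g2", "g2"),
                     c("SL", "morphometric_SL"))
  expect_error(impute_missing(m3), "g2")
  # imputed meristics stay on the half-integer grid
  vals4 <- cbind(SL = c(40, 60, 55), C1 = c(10, 12, NA))
  m4 <- morpho_table(vals4, c("a", "b", "c"), rep("g", 3),
                     c("SL", "meristic"))
  mi4 <- impute_missing(m4)
  expect_equal(unname(mi4["c", "C1"]) %% 0.5, 0)
})

test_that("standardization log-ratios, centers and unit-scales", {
  # ratio column {e, e^2}: pre-scaling {1, 2}, post-scaling {-1, +1}
  vals <- cbind(SL = c(10, 20), M1 = c(10 * exp(1), 20 * exp(2)))
  m <- morpho_table(vals, c("a", "b"), c("g", "g"),
                    c("SL", "morphometric_SL"))
  Z <- standardize(m)
  expect_equal(unname(Z[, "M1"]), c(-1, 1))
  # column equal to SL gives an all-zero log ratio -> zero variance error
  vals2 <- cbind(SL = c(10, 20), M1 = c(10, 20))
  m2 <- morpho_table(vals2, c("a", "b"), c("g", "g"),
                     c("SL", "morphometric_SL"))
  expect_error(standardize(m2), "zero-variance")
  # every column has mean 0 and (population) variance 1
  sim <- impute_missing(simulate_morpho(seed = 3))
  Zs <- standardize(sim)
  expect_lt(max(abs(colMeans(Zs))), 1e-12)
  expect_equal(unname(colMeans(Zs^2)), rep(1, ncol(Zs)))
  # meristic columns enter raw (centered-scaled only): monotone map
  expect_equal(order(Zs[, "C01"]), order(unclass(sim)[, "C01"]))
  # configurable log base changes only morphometric columns by a factor
  Z10 <- standardize(sim, log_base = 10)
  expect_equal(unname(Z10[, "M01"]), unname(Zs[, "M01"]))  # scale-invariant
})

test_that("HL-denominated variables standardize by the head-length column", {
  vals <- cbind(SL = c(40, 50, 60), HL = c(10, 12, 15),
                E1 = c(2, 3, 4.5))
  m <- morpho_table(vals, c("a", "b", "c"), rep("g", 3),
                    c("SL", "morphometric_SL", "morphometric_HL"),
                    hl_column = "HL")
  Z <- standardize(m)
  raw <- log(vals[, "E1"] / vals[, "HL"])
  expect_equal(unname(Z[, "E1"]),
               unname((raw - mean(raw)) / sqrt(mean((raw - mean(raw))^2))))
  expect_error(morpho_table(vals, c("a", "b", "c"), rep("g", 3),
                            c("SL", "morphometric_SL", "morphometric_HL")),
               "hl_column")
})

test_that("BGA ratio endpoints, oracle and permutation test behave", {
  set.seed(5)
  X <- scale(matrix(rnorm(48), 8, 6)) * sqrt(8 / 7)  # population scaled
  # each specimen its own group: the group means are the data
  b1 <- bga(X, groups = paste0("g", 1:8), n_perm = 0)
  expect_equal(b1$ratio, 1)
  # a single group: centered mean is the origin
  b0 <- suppressWarnings(bga(X, groups = rep("g", 8), n_perm = 0))
  expect_equal(b0$ratio, 0, tolerance = 1e-12)

  # brute-force oracle: between-class inertia = sum_k (n_k/n)||mean_k||^2
  g <- c("a", "a", "a", "b", "b", "b", "b", "a")
  bo <- bga(X, groups = g, n_perm = 0)
  means <- rowsum(X, g) / as.vector(table(g))
  oracle <- sum((table(g) / 8) * rowSums(means^2))
  expect_equal(sum(bo$eigenvalues), oracle, tolerance = 1e-12)
  expect_equal(bo$ratio, oracle / (sum(X^2) / 8), tolerance = 1e-12)

  # invariant to column permutation and group relabeling
  b2 <- bga(X[, 6:1], groups = g, n_perm = 0)
  expect_equal(b2$ratio, bo$ratio)
  b3 <- bga(X, groups = chartr("ab", "xy", g), n_perm = 0)
  expect_equal(b3$ratio, bo$ratio)

  # permutation p-value floor and determinism
  bp <- bga(X, groups = g, n_perm = 99, seed = 1)
  expect_gte(bp$p_value, 1 / 100)
  bp2 <- bga(X, groups = g, n_perm = 99, seed = 1)
  expect_identical(bp$perm_distribution, bp2$perm_distribution)
})

test_that("zero within-group noise gives a BGA ratio of exactly 1", {
  sim <- simulate_morpho(n_pop = 4, n_per_pop = 6, noise_sd = 0,
                         meristic_sd = 0, missing_rate = 0,
                         sl_by_pop = TRUE, seed = 21)
  Z <- standardize(sim)
  b <- bga(Z, n_perm = 0)
  expect_equal(b$ratio, 1, tolerance = 1e-10)
})
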
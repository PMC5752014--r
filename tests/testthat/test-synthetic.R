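test_that("Yule simulation has the right shape and expected depth", {
  tr2 <- simulate_tree(2, birth = 1, seed = 1)
  expect_equal(length(tr2$tip.label), 2L)
  expect_equal(tr2$Nnode, 1L)
  tr50 <- simulate_tree(50, birth = 1, seed = 2)
  expect_equal(tr50$Nnode, 49L)
  expect_true(ape::is.binary(tr50))
  expect_true(ape::is.ultrametric(tr50, tol = 1e-8))
  # mean root-to-tip depth across replicates within 3 SE of the Yule
  # expectation sum_{k=2}^{n} 1/(birth k)
  n <- 10; birth <- 2
  depths <- vapply(1:100, function(i) {
    tr <- simulate_tree(n, birth = birth, seed = 1000 + i)
    max(ape::node.depth.edgelength(tr))
  }, 0)
  expectation <- sum(1 / (birth * (2:n)))
  se <- sd(depths) / sqrt(length(depths))
  expect_lt(abs(mean(depths) - expectation), 3 * se)
  # byte-identical regeneration from the same seed
  expect_identical(simulate_tree(12, 1, seed = 9),
                   simulate_tree(12, 1, seed = 9))
})

test_that("two-parameter sequence simulation matches its model", {
  tr <- simulate_tree(6, birth = 1, seed = 3)
  s0 <- simulate_sequences(tr, length = 120, kappa = 4, rate = 0, seed = 4)
  expect_equal(length(unique(unclass(s0))), 1L)  # rate 0: identical
  # the analytic K80 transition matrix equals the matrix exponential
  Qk <- matrix(1 / 6, 4, 4,
               dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  Qk["A", "G"] <- Qk["G", "A"] <- Qk["C", "T"] <- Qk["T", "C"] <- 4 / 6
  diag(Qk) <- 0; diag(Qk) <- -rowSums(Qk)
  P_closed <- integrotax:::k80_pmatrix(0.3, kappa = 4)
  P_exp <- as.matrix(Matrix::expm(Qk * 0.3))
  expect_equal(unname(P_closed), unname(P_exp), tolerance = 1e-10)
  # near-infinite kappa: transversions vanish
  cherry <- ape::read.tree(text = "(a:0.2,b:0.2);")
  sk <- simulate_sequences(cherry, length = 2000, kappa = 1e9, seed = 5)
  av <- strsplit(sk[["a"]], "")[[1]]; bv <- strsplit(sk[["b"]], "")[[1]]
  diff <- av != bv
  purine <- function(x) x %in% c("A", "G")
  expect_equal(sum(diff & (purine(av) != purine(bv))), 0L)
  # estimator consistency: mean K2P over replicates within 3 SE of the
  # total path length separating a cherry's tips
  T_true <- 0.1
  ch <- ape::read.tree(text = "(a:0.05,b:0.05);")
  d_hat <- vapply(1:200, function(i) {
    s <- simulate_sequences(ch, length = 500, kappa = 4, seed = 2000 + i)
    k2p(s[["a"]], s[["b"]])
  }, 0)
  se <- sd(d_hat) / sqrt(length(d_hat))
  expect_lt(abs(mean(d_hat) - T_true), 3 * se)
})

test_that("morphometric generator honors its declared structure", {
  sim <- simulate_morpho(n_pop = 4, n_per_pop = 25, n_morpho = 6,
                         n_meristic = 3, missing_rate = 0.05, seed = 6)
  # missing cells binomial around rate * cells (non-SL columns only)
  n_cells <- nrow(sim) * (ncol(sim) - 1L)
  n_miss <- sum(is.na(sim))
  expect_lt(abs(n_miss - 0.05 * n_cells),
            4 * sqrt(n_cells * 0.05 * 0.95))
  expect_false(anyNA(sl_of(sim)))
  # allometry: observed value/SL ratio tracks the generating slope
  tr <- attr(sim, "truth")
  obs <- unclass(sim)[groups_of(sim) == "pop01", "M01"] /
    sl_of(sim)[groups_of(sim) == "pop01"]
  expect_equal(mean(obs, na.rm = TRUE), tr$slope[1, 1], tolerance = 0.05)
  # determinism
  expect_identical(unclass(simulate_morpho(seed = 8)),
                   unclass(simulate_morpho(seed = 8)))
})

test_that("range simulation follows the generating DEC process", {
  sp <- build_state_space(c("A", "B", "C"), 3)
  tr <- simulate_tree(12, birth = 1, seed = 7)
  # d = e = j = 0: every tip inherits the root range
  rg0 <- simulate_ranges(tr, sp, 0, 0, 0, seed = 8)
  ns <- attr(rg0, "node_states")
  root_state <- ns[length(tr$tip.label) + 1L]
  # with |root| = 1 nothing changes; with |root| > 1 cladogenesis still
  # splits, so compare against the root's area set union over tips
  if (length(sp$states[[root_state]]) == 1L) {
    expect_true(all(vapply(rg0, identical,
                           TRUE, sp$areas[sp$states[[root_state]]])))
  } else {
    expect_true(all(vapply(unclass(rg0), function(r)
      all(r %in% sp$areas[sp$states[[root_state]]]), TRUE)))
  }
  # strong extirpation: tip ranges mostly single-area
  rg_e <- simulate_ranges(tr, sp, 0.05, 0.8, 0, seed = 9,
                          max_tries = 2000)
  expect_gt(mean(lengths(rg_e) == 1L), 0.8)
  # large founder weight: daughters frequently jump outside the parent
  rg_j <- simulate_ranges(tr, sp, 0.01, 0.01, 2.5, seed = 10)
  # reconstruct parent-child area relations from stored node states
  nsj <- attr(rg_j, "node_states")
  edge <- tr$edge
  internal <- edge[, 2] > length(tr$tip.label)
  jumps <- 0L; events <- 0L
  for (i in seq_len(nrow(edge))) {
    pa <- sp$states[[nsj[edge[i, 1]]]]
    ch <- sp$states[[nsj[edge[i, 2]]]]
    events <- events + 1L
    if (length(ch) == 1L && !(ch %in% pa)) jumps <- jumps + 1L
  }
  expect_gt(jumps, 0L)
  # determinism
  expect_identical(unclass(simulate_ranges(tr, sp, .2, .02, 0, seed = 11)),
                   unclass(simulate_ranges(tr, sp, .2, .02, 0, seed = 11)))
})

test_that("the three-species preset is coherent and serializable", {
  st <- simulate_study(n_per_species = 5, seed = 17)
  expect_equal(length(st$tree$tip.label), 15L)
  expect_equal(names(st$sequences), st$tree$tip.label)
  expect_setequal(rownames(st$morpho), st$tree$tip.label)
  expect_equal(st$gps$id, names(st$sequences))
  expect_setequal(names(st$ranges), st$tree$tip.label)
  # regeneration from the same seed is identical
  st2 <- simulate_study(n_per_species = 5, seed = 17)
  expect_identical(unclass(st$sequences), unclass(st2$sequences))
  expect_identical(st$tree, st2$tree)
  # files round-trip
  dir <- withr::local_tempdir()
  simulate_study(n_per_species = 5, seed = 17, dir = dir)
  expect_true(all(file.exists(file.path(dir,
    c("tree.nwk", "seqs.fasta", "morpho.csv", "gps.csv", "ranges.tsv",
      "truth.json")))))
  s_in <- read_fasta(file.path(dir, "seqs.fasta"))
  expect_identical(unclass(s_in), unclass(st$sequences))
})
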
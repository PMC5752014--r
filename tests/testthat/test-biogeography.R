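test_that("range state spaces enumerate subsets up to the size cap", {
  sp2 <- build_state_space(c("A", "B"), 2)
  expect_equal(length(sp2$states) - 1L, 3L)
  expect_equal(sp2$labels, c("0", "A", "B", "A+B"))
  sp31 <- build_state_space(c("A", "B", "C"), 1)
  expect_equal(length(sp31$states) - 1L, 3L)
  # 11 areas capped at 4: 11 + 55 + 165 + 330 by direct enumeration
  sp11 <- build_state_space(LETTERS[1:11], 4)
  expect_equal(length(sp11$states) - 1L,
               sum(choose(11, 1:4)))
  expect_equal(length(sp11$states) - 1L, 561L)
  expect_error(build_state_space(c("A", "B"), 0), "max_range_size")
})

test_that("the anagenetic generator has DEC rates and zero row sums", {
  sp <- build_state_space(c("A", "B"), 2)
  expect_equal(build_rate_matrix(sp, 0, 0),
               matrix(0, 4, 4, dimnames = list(sp$labels, sp$labels)))
  Q <- build_rate_matrix(sp, 0.3, 0.07)
  expect_equal(Q["A", "A+B"], 0.3)         # |range| * d with |range| = 1
  expect_equal(Q["A+B", "A"], 0.07)        # extirpation of one area
  expect_equal(Q["A", "0"], 0.07)          # size-1 range decays to null
  expect_equal(unname(Q["0", ]), rep(0, 4))  # null range absorbing
  expect_equal(max(abs(rowSums(Q))), 0)
  # expansion rate scales with range size (two source areas)
  sp3 <- build_state_space(c("A", "B", "C"), 3)
  Q3 <- build_rate_matrix(sp3, 0.3, 0)
  expect_equal(Q3["A+B", "A+B+C"], 0.6)
})

test_that("cladogenetic pair distributions enumerate DEC events", {
  sp <- build_state_space(c("A", "B"), 2)
  # single-area ancestor with j = 0: sympatric copy with probability 1
  cw1 <- clado_event_weights(sp, 1, j = 0)
  expect_equal(nrow(cw1), 1L)
  expect_equal(cw1$prob, 1)
  expect_equal(cw1$left, cw1$right)
  # {A,B} ancestor, j = 0: subset sympatry (4 ordered pairs) and
  # vicariance (2 ordered pairs), uniform over the 6
  cwAB <- clado_event_weights(sp, c(1, 2), j = 0)
  expect_equal(nrow(cwAB), 6L)
  expect_equal(cwAB$prob, rep(1 / 6, 6))
  pairs <- paste(sp$labels[cwAB$left], sp$labels[cwAB$right])
  expect_setequal(pairs, c("A+B A", "A A+B", "A+B B", "B A+B",
                           "A B", "B A"))
  # j > 0 adds jump pairs; probabilities still sum to 1
  sp3 <- build_state_space(c("A", "B", "C"), 3)
  cwj <- clado_event_weights(sp3, 1, j = 0.5)
  expect_equal(sum(cwj$prob), 1)
  jump_rows <- cwj$left != cwj$right
  expect_equal(sum(jump_rows), 4L)         # two outside areas, two orders
  expect_error(clado_event_weights(sp, integer(0)), "empty")
  expect_error(clado_event_weights(sp, 1, j = 3), "j must be")
})

test_that("branch transition matrices are stochastic and exact", {
  sp <- build_state_space(c("A", "B", "C"), 3)
  Q <- build_rate_matrix(sp, 0.4, 0.15)
  Pm <- integrotax:::expm_branches(Q, c(0.01, 0.5, 2, 10))
  for (P in Pm) {
    expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-8)
    expect_true(all(P >= 0))
  }
  # single-area chain: P(still occupied) = exp(-e t)
  sp1 <- build_state_space("A", 1)
  Q1 <- build_rate_matrix(sp1, 0, 1)
  P1 <- integrotax:::expm_branches(Q1, 1)[[1]]
  expect_equal(P1["A", "A"], exp(-1), tolerance = 1e-10)
  expect_equal(P1["A", "A"], 0.3678794, tolerance = 1e-6)
})

test_that("pruning equals exhaustive summation and nests DEC in DEC+j", {
  sp <- build_state_space(c("A", "B"), 2)
  # cherry with d = e = j = 0 and matching single-area tips: the only
  # uncertainty left is the uniform root prior
  cherry <- ape::read.tree(text = "(t1:1,t2:1);")
  rgc <- tip_ranges(c("t1", "t2"), list("A", "A"), c("A", "B"))
  expect_equal(dec_likelihood(cherry, rgc, sp, 0, 0, 0), log(1 / 3))

  # brute-force oracle over all internal state assignments
  set.seed(13)
  sp3 <- build_state_space(c("A", "B", "C"), 3)
  for (rep in 1:4) {
    tr <- simulate_tree(4, birth = 1, seed = 40 + rep)
    rg <- simulate_ranges(tr, sp3, 0.3, 0.05, 0.3, seed = 50 + rep)
    pars <- c(runif(1, 0.05, 0.6), runif(1, 0.01, 0.3),
              runif(1, 0, 1.5))
    l_prune <- dec_likelihood(tr, rg, sp3, pars[1], pars[2], pars[3])
    l_brute <- dec_brute(tr, rg, sp3, pars[1], pars[2], pars[3])
    expect_equal(l_prune, l_brute, tolerance = 1e-10)
  }

  # DEC+j at j = 0 equals DEC
  for (rep in 1:10) {
    tr <- simulate_tree(6, birth = 1, seed = 60 + rep)
    rg <- simulate_ranges(tr, sp3, 0.2, 0.02, 0, seed = 70 + rep)
    d <- runif(1, 0.05, 1); e <- runif(1, 0.01, 0.5)
    expect_equal(dec_likelihood(tr, rg, sp3, d, e, 0),
                 dec_likelihood(tr, rg, sp3, d, e, 1e-14),
                 tolerance = 1e-10)
  }

  # likelihood invariant to child order at every node
  tr <- simulate_tree(6, birth = 1, seed = 81)
  rg <- simulate_ranges(tr, sp3, 0.2, 0.05, 0, seed = 82)
  trr <- ape::rotateConstr(tr, rev(tr$tip.label))
  rgr <- tip_ranges(names(rg), unclass(rg), sp3$areas)
  expect_equal(dec_likelihood(trr, rgr, sp3, 0.3, 0.05, 0.2),
               dec_likelihood(tr, rg, sp3, 0.3, 0.05, 0.2),
               tolerance = 1e-10)
})

test_that("ancestral marginals are distributions that track the data", {
  sp <- build_state_space(c("A", "B", "C"), 3)
  tr <- simulate_tree(8, birth = 1, seed = 91)
  rg <- simulate_ranges(tr, sp, 0.3, 0.05, 0, seed = 92)
  fit <- dec_fit(tr, rg, sp, "DEC", n_starts = 2, seed = 93)
  expect_equal(unname(rowSums(fit$node_marginals)),
               rep(1, nrow(fit$node_marginals)), tolerance = 1e-10)
  # near-zero rates with a shared single-area tip range concentrate on
  # that range (sympatric copying is the only near-free history)
  rg_same <- tip_ranges(tr$tip.label, rep(list("B"), 8), sp$areas)
  pr <- integrotax:::dec_prune(tr, rg_same, sp, 1e-9, 1e-9, 0)
  marg <- integrotax:::dec_marginals(pr, sp)
  expect_true(all(marg[, "B"] > 0.999))
})

test_that("ML fitting respects the model and the LRT follows chi-squared", {
  sp <- build_state_space(c("A", "B", "C"), 3)
  tr <- simulate_tree(10, birth = 0.5, seed = 101)
  rg <- simulate_ranges(tr, sp, 0.3, 0.02, 0, seed = 102)
  fit <- dec_fit(tr, rg, sp, "DEC", n_starts = 2, seed = 103)
  expect_equal(unname(fit$params["j"]), 0)   # DEC forces j = 0
  expect_equal(fit$n_params, 2L)
  expect_named(coef(fit), c("d", "e"))
  fitj <- dec_fit(tr, rg, sp, "DECJ", n_starts = 2, seed = 104)
  expect_equal(fitj$n_params, 3L)
  expect_gte(fitj$lnL, fit$lnL - 1e-6)       # nested models
  lrt <- dec_lrt(fit, fitj)
  expect_equal(lrt$df, 1L)
  expect_equal(lrt$p_value,
               pchisq(lrt$D, 1, lower.tail = FALSE))
  # chi-squared anchors
  eq <- list(lnL = -10, model = "DEC")
  eqj <- list(lnL = -10, model = "DECJ")
  expect_equal(dec_lrt(eq, eqj)$p_value, 1)
  crit <- list(lnL = -10, model = "DEC")
  critj <- list(lnL = -10 + 3.841 / 2, model = "DECJ")
  expect_equal(dec_lrt(crit, critj)$p_value, 0.05, tolerance = 1e-3)
  bad <- list(lnL = -9, model = "DEC")
  expect_error(dec_lrt(bad, eqj), "optimizer failure")
})
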
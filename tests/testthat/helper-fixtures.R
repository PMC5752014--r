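# Small in-code fixtures shared across test files.

toy_morpho <- function() {
  vals <- rbind(c(50, 10, 5, 12),
                c(60, 12, 6, 13),
                c(70, 14, NA, 14.5),
                c(55, 11, 5.5, 12))
  colnames(vals) <- c("SL", "M1", "M2", "C1")
  morpho_table(vals, paste0("s", 1:4), c("g1", "g1", "g1", "g2"),
               c("SL", "morphometric_SL", "morphometric_SL", "meristic"))
}

toy_morpho_csv <- function(path) {
  writeLines(c("id,pop,SL,M1,M2,C1",
               "s1,g1,50,10,5,12",
               "s2,g1,60,12,,13",
               "s3,g2,70,14,7,14.5"), path)
  path
}

toy_schema <- function() {
  list(id_column = "id", group_column = "pop", sl_column = "SL",
       variable_kind = list(M1 = "morphometric_SL",
                            M2 = "morphometric_SL",
                            C1 = "meristic"))
}

toy_seqs <- function() {
  sequence_set(c("a1", "a2", "b1"),
               c("ACGTACGTAC", "ACGTACGTAT", "ACGTTTTTAC"),
               c("spA", "spA", "spB"))
}

# distance matrix with a clean gap: within <= w, between >= b
gap_matrix <- function(n_per = 3, w = 0.005, b = 0.05) {
  labels <- rep(c("A", "B"), each = n_per)
  n <- length(labels)
  D <- matrix(b, n, n)
  for (g in unique(labels)) {
    i <- which(labels == g)
    D[i, i] <- w
  }
  diag(D) <- 0
  dimnames(D) <- list(paste0("i", 1:n), paste0("i", 1:n))
  list(D = D, labels = labels)
}

# independent per-site counting K2P oracle (no shared code with k2p)
k2p_oracle <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  ts_pairs <- c("AG", "GA", "CT", "TC")
  n <- 0L; ts <- 0L; tv <- 0L
  for (i in seq_along(av)) {
    x <- av[i]; y <- bv[i]
    if (!x %in% c("A", "C", "G", "T") || !y %in% c("A", "C", "G", "T"))
      next
    n <- n + 1L
    if (x != y) {
      if (paste0(x, y) %in% ts_pairs) ts <- ts + 1L else tv <- tv + 1L
    }
  }
  if (n == 0) return(NA_real_)
  P <- ts / n; Q <- tv / n
  arg1 <- 1 - 2 * P - Q; arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) return(NA_real_)
  -0.5 * log(arg1 * sqrt(arg2))
}

random_dna <- function(n, len, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), "")
}

# brute-force DEC likelihood by summation over internal-node states
dec_brute <- function(tree, rg, sp, d, e, j) {
  S <- length(sp$states)
  Q <- build_rate_matrix(sp, d, e)
  nt <- length(tree$tip.label)
  Pm <- lapply(tree$edge.length, function(t) as.matrix(Matrix::expm(Q * t)))
  keys <- vapply(sp$states, paste, "", collapse = "+")
  tipidx <- vapply(tree$tip.label, function(tl)
    match(paste(sort(match(rg[[tl]], sp$areas)), collapse = "+"), keys), 0L)
  clado <- lapply(1:S, function(s)
    if (s > 1) clado_event_weights(sp, sp$states[[s]], j))
  edge <- tree$edge
  nodes <- (nt + 1):(nt + tree$Nnode)
  grid <- as.matrix(expand.grid(rep(list(2:S), tree$Nnode)))
  tot <- 0
  for (gi in seq_len(nrow(grid))) {
    assign_ <- grid[gi, ]
    state_of <- function(v) if (v <= nt) tipidx[v] else assign_[v - nt]
    like <- 1 / (S - 1)
    for (v in nodes) {
      s <- state_of(v); ce <- which(edge[, 1] == v); cw <- clado[[s]]
      acc <- 0
      for (q in seq_len(nrow(cw)))
        acc <- acc + cw$prob[q] *
          Pm[[ce[1]]][cw$left[q], state_of(edge[ce[1], 2])] *
          Pm[[ce[2]]][cw$right[q], state_of(edge[ce[2], 2])]
      like <- like * acc
    }
    tot <- tot + like
  }
  log(tot)
}
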
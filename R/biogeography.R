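#' Geographic range state space
#'
#' Enumerates all nonempty subsets of the declared areas up to
#' `max_range_size`, plus the (absorbing) null range, in canonical order
#' (null first, then by size, then lexicographically by area index).
#'
#' @param areas ordered character vector of area codes.
#' @param max_range_size largest allowed range size (e.g. 4 in analyses
#'   capping ancestral ranges at four areas).
#' @return Object of class `range_state_space`: `areas`, `max_range_size`,
#'   `states` (list of integer index vectors; `states[[1]]` is the null
#'   range), `labels`.
#' @export
build_state_space <- function(areas, max_range_size = length(areas)) {
  areas <- as.character(areas)
  m <- length(areas)
  if (max_range_size < 1 || max_range_size > m)
    stop("max_range_size must be in [1, number of areas]")
  states <- list(integer(0))
  for (k in seq_len(max_range_size))
    states <- c(states, combn(m, k, simplify = FALSE))
  labels <- c("0", vapply(states[-1], function(s)
    paste(areas[s], collapse = "+"), ""))
  structure(list(areas = areas, max_range_size = max_range_size,
                 states = states, labels = labels),
            class = "range_state_space")
}

#' @export
print.range_state_space <- function(x, ...) {
  cat("Range state space:", length(x$areas), "areas, max range size",
      x$max_range_size, "->", length(x$states) - 1L,
      "non-null states (+ null)\n")
  invisible(x)
}

#' Anagenetic DEC rate matrix
#'
#' Dispersal adds one area at rate `|range| * d` per reachable area
#' (uniform adjacency); extirpation removes one area at rate `e` per
#' occupied area, single-area ranges decaying to the absorbing null
#' range. Diagonal entries make row sums zero.
#'
#' @param space a [build_state_space()] object.
#' @param d dispersal (range expansion) rate per source area.
#' @param e extirpation (range contraction) rate per area.
#' @return Dense generator matrix Q over all states (null state first).
#' @export
build_rate_matrix <- function(space, d, e) {
  if (d < 0 || e < 0) stop("rates must be nonnegative")
  S <- length(space$states)
  m <- length(space$areas)
  keys <- vapply(space$states, paste, "", collapse = "+")
  Q <- matrix(0, S, S, dimnames = list(space$labels, space$labels))
  for (i in seq_len(S)) {
    r <- space$states[[i]]
    if (!length(r)) next                    # null range absorbing
    if (length(r) < space$max_range_size) {
      for (b in setdiff(seq_len(m), r)) {
        j <- match(paste(sort(c(r, b)), collapse = "+"), keys)
        Q[i, j] <- Q[i, j] + length(r) * d
      }
    }
    for (a in r) {
      j <- match(paste(setdiff(r, a), collapse = "+"), keys)
      Q[i, j] <- Q[i, j] + e
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Cladogenetic event distribution for an ancestral range
#'
#' Enumerates the ordered daughter-range pairs allowed at a speciation
#' event and their probabilities. Event categories: sympatry (single-area
#' ancestor copied to both daughters), subset sympatry (one daughter
#' keeps the range, the other one area within it), vicariance (disjoint
#' split with one single-area daughter), and founder-event jump (one
#' daughter keeps the range, the other a single area outside it).
#' Per-pair base weights are `(3 - j)/3` for the three non-jump
#' categories and `j` for jumps; probabilities are normalized over all
#' allowed ordered pairs.
#'
#' @param space a [build_state_space()] object.
#' @param range integer vector of area indices (nonempty), or a state
#'   index.
#' @param j founder-event weight in `[0, 3)`; `j = 0` recovers plain DEC.
#' @return data.frame with columns `left`, `right` (state indices) and
#'   `prob`.
#' @export
clado_event_weights <- function(space, range, j = 0) {
  if (j < 0 || j >= 3) stop("j must be in [0, 3)")
  r <- sort(unique(as.integer(range)))
  if (!length(r)) stop("empty ancestor range")
  m <- length(space$areas)
  ysv <- (3 - j) / 3
  left <- integer(0); right <- integer(0); wt <- numeric(0)
  keys <- vapply(space$states, paste, "", collapse = "+")
  idx <- function(s) match(paste(sort(s), collapse = "+"), keys)
  add <- function(l, rr, w) {
    left <<- c(left, idx(l)); right <<- c(right, idx(rr)); wt <<- c(wt, w)
  }
  if (length(r) == 1L) {
    add(r, r, ysv)                           # sympatric copy
  } else {
    for (a in r) {                           # subset sympatry
      add(r, a, ysv); add(a, r, ysv)
    }
    for (a in r) {                           # vicariance (one singleton)
      rest <- setdiff(r, a)
      if (length(rest) == 1L && a > rest) next  # avoid double count at |r|=2
      add(a, rest, ysv); add(rest, a, ysv)
    }
  }
  if (j > 0) {
    for (b in setdiff(seq_len(m), r)) {      # founder-event jump
      add(r, b, j); add(b, r, j)
    }
  }
  data.frame(left = left, right = right, prob = wt / sum(wt))
}

# Transition matrices exp(Q t) for a set of branch lengths.
# Primary path: one eigendecomposition of Q, reused for every branch;
# falls back to scaling-and-squaring when the decomposition is
# ill-conditioned (row-sum check).
expm_branches <- function(Q, ts) {
  S <- nrow(Q)
  out <- vector("list", length(ts))
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  ok <- FALSE
  if (!is.null(eg)) {
    Vi <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Vi)) {
      ok <- TRUE
      for (i in seq_along(ts)) {
        P <- Re(eg$vectors %*% (exp(eg$values * ts[i]) * Vi))
        if (max(abs(rowSums(P) - 1)) > 1e-8 || min(P) < -1e-8) {
          ok <- FALSE; break
        }
        P[P < 0] <- 0
        dimnames(P) <- dimnames(Q)
        out[[i]] <- P
      }
    }
  }
  if (!ok) {
    for (i in seq_along(ts))
      out[[i]] <- as.matrix(Matrix::expm(Q * ts[i]))
  }
  names(out) <- as.character(ts)
  out
}

# tip state indices, checking coverage
tip_state_indices <- function(tree, ranges, space) {
  miss <- setdiff(tree$tip.label, names(ranges))
  if (length(miss))
    stop("tips missing from range table: ", paste(miss, collapse = ", "))
  keys <- vapply(space$states, paste, "", collapse = "+")
  vapply(tree$tip.label, function(tl) {
    ai <- sort(match(ranges[[tl]], space$areas))
    if (anyNA(ai)) stop("tip ", tl, " uses undeclared areas")
    i <- match(paste(ai, collapse = "+"), keys)
    if (is.na(i)) stop("tip ", tl, " range exceeds max_range_size")
    i
  }, 0L)
}

# Parameter-independent precomputation shared by every likelihood
# evaluation on the same (tree, ranges, space): traversal order, tip
# state indices, the sparsity template of the generator, and the
# cladogenetic pair structure (weights depend on j only).
dec_structure <- function(tree, tip_ranges, space) {
  if (!ape::is.binary(tree)) stop("tree must be bifurcating")
  S <- length(space$states)
  m <- length(space$areas)
  keys <- vapply(space$states, paste, "", collapse = "+")
  sizes <- lengths(space$states)
  exp_i <- exp_j <- exp_mult <- integer(0)
  con_i <- con_j <- integer(0)
  for (i in seq_len(S)) {
    r <- space$states[[i]]
    if (!length(r)) next
    if (length(r) < space$max_range_size)
      for (b in setdiff(seq_len(m), r)) {
        exp_i <- c(exp_i, i)
        exp_j <- c(exp_j, match(paste(sort(c(r, b)), collapse = "+"), keys))
        exp_mult <- c(exp_mult, length(r))
      }
    for (a in r) {
      con_i <- c(con_i, i)
      con_j <- c(con_j, match(paste(setdiff(r, a), collapse = "+"), keys))
    }
  }
  clado_pairs <- lapply(seq_len(S), function(s) {
    if (s == 1) return(NULL)
    r <- space$states[[s]]
    cp <- clado_event_weights(space, r, j = 0)
    cp$jump <- FALSE
    jumps <- setdiff(seq_len(m), r)
    if (length(jumps)) {
      singles <- match(as.character(jumps), keys)
      jp <- data.frame(left = c(rep(s, length(jumps)), singles),
                       right = c(singles, rep(s, length(jumps))),
                       prob = 0, jump = TRUE)
      cp <- rbind(cp, jp)
    }
    cp
  })
  nt <- length(tree$tip.label)
  edge <- tree$edge
  children <- split(seq_len(nrow(edge)), edge[, 1])
  po_edge <- stats::reorder(tree, "postorder")$edge
  # order of *last* appearance as a parent in the postorder edge list:
  # every descendant internal node is processed before its ancestor
  node_order <- rev(unique(rev(po_edge[, 1])))
  list(S = S, n_tips = nt, edge = edge, blen = tree$edge.length,
       children = children, node_order = node_order,
       root = node_order[length(node_order)],
       tipidx = tip_state_indices(tree, tip_ranges, space),
       exp_i = exp_i, exp_j = exp_j, exp_mult = exp_mult,
       con_i = con_i, con_j = con_j,
       clado_pairs = clado_pairs,
       labels = space$labels)
}

# fill the generator from the cached sparsity template
rate_matrix_from_structure <- function(st, d, e) {
  Q <- matrix(0, st$S, st$S, dimnames = list(st$labels, st$labels))
  if (length(st$exp_i)) {
    for (q in seq_along(st$exp_i))
      Q[st$exp_i[q], st$exp_j[q]] <- Q[st$exp_i[q], st$exp_j[q]] +
        st$exp_mult[q] * d
  }
  if (length(st$con_i)) {
    for (q in seq_along(st$con_i))
      Q[st$con_i[q], st$con_j[q]] <- Q[st$con_i[q], st$con_j[q]] + e
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# cladogenetic probabilities from the cached pair structure
clado_probs_from_structure <- function(st, j) {
  lapply(st$clado_pairs, function(cp) {
    if (is.null(cp)) return(NULL)
    wt <- ifelse(cp$jump, j, (3 - j) / 3)
    tot <- sum(wt)
    list(left = cp$left, right = cp$right, prob = wt / tot)
  })
}

# internal pruning engine; returns root lnL and per-node data for reuse
dec_prune <- function(tree, tip_ranges, space, d, e, j, st = NULL) {
  if (is.null(st)) st <- dec_structure(tree, tip_ranges, space)
  S <- st$S
  Q <- rate_matrix_from_structure(st, d, e)
  nt <- st$n_tips
  nn <- length(st$node_order)
  edge <- st$edge
  blen <- st$blen
  ub <- sort(unique(blen))
  Pm <- expm_branches(Q, ub)
  Pedge <- Pm[match(blen, ub)]
  clado <- clado_probs_from_structure(st, j)
  tipidx <- st$tipidx
  L <- matrix(0, nt + nn, S)               # partial likelihoods at nodes
  logsc <- numeric(nt + nn)
  for (i in seq_len(nt)) L[i, tipidx[i]] <- 1
  children <- st$children
  node_order <- st$node_order
  for (v in node_order) {
    ce <- children[[as.character(v)]]
    msgs <- lapply(ce, function(ei) {
      child <- edge[ei, 2]
      as.vector(Pedge[[ei]] %*% L[child, ])
    })
    lv <- numeric(S)
    for (s in 2:S) {
      cw <- clado[[s]]
      lv[s] <- sum(cw$prob * msgs[[1]][cw$left] * msgs[[2]][cw$right])
    }
    sc <- max(lv)
    if (sc <= 0) {
      logsc[v] <- -Inf
      L[v, ] <- 0
    } else {
      L[v, ] <- lv / sc
      kids <- edge[ce, 2]
      logsc[v] <- log(sc) + sum(logsc[kids])
    }
  }
  root <- node_order[length(node_order)]
  prior <- c(0, rep(1 / (S - 1), S - 1))
  rootlik <- sum(prior * L[root, ])
  lnL <- if (rootlik <= 0 || is.infinite(logsc[root])) -Inf else
    log(rootlik) + logsc[root]
  list(lnL = lnL, L = L, logsc = logsc, Pedge = Pedge, clado = clado,
       edge = edge, children = children, node_order = node_order,
       root = root, prior = prior, n_tips = nt)
}

#' DEC / DEC+j log-likelihood of tip ranges on a tree
#'
#' Felsenstein pruning over the range state space: anagenetic change
#' along branches through `exp(Q t)`, cladogenetic change at internal
#' nodes through [clado_event_weights()], and a root prior uniform over
#' non-null states. A data set of probability zero returns `-Inf` rather
#' than raising an error.
#'
#' @param tree bifurcating [ape::phylo] tree with branch lengths.
#' @param ranges a [tip_ranges] object (or named list of area-code
#'   vectors) covering every tip.
#' @param space a [build_state_space()] object.
#' @param d,e,j model parameters (`j = 0` gives plain DEC).
#' @return Log-likelihood (scalar).
#' @export
dec_likelihood <- function(tree, ranges, space, d, e, j = 0) {
  dec_prune(tree, ranges, space, d, e, j)$lnL
}

# marginal ancestral state probabilities at internal nodes
dec_marginals <- function(pr, space) {
  S <- length(space$states)
  edge <- pr$edge
  nt <- pr$n_tips
  O <- matrix(0, nt + length(pr$node_order), S)   # outside likelihoods
  O[pr$root, ] <- pr$prior
  for (v in rev(pr$node_order)) {
    ce <- pr$children[[as.character(v)]]
    kids <- edge[ce, 2]
    msgs <- lapply(ce, function(ei)
      as.vector(pr$Pedge[[ei]] %*% pr$L[edge[ei, 2], ]))
    for (ci in 1:2) {
      child <- kids[ci]
      sib_msg <- msgs[[3 - ci]]
      A <- numeric(S)                       # at top of child's branch
      for (s in 2:S) {
        if (O[v, s] == 0) next
        cw <- pr$clado[[s]]
        own <- if (ci == 1) cw$left else cw$right
        sib <- if (ci == 1) cw$right else cw$left
        contrib <- cw$prob * sib_msg[sib] * O[v, s]
        for (q in seq_along(own)) A[own[q]] <- A[own[q]] + contrib[q]
      }
      O[child, ] <- as.vector(t(pr$Pedge[[ce[ci]]]) %*% A)
      mx <- max(O[child, ])
      if (mx > 0) O[child, ] <- O[child, ] / mx
    }
  }
  nodes <- pr$node_order
  marg <- matrix(0, length(nodes), S,
                 dimnames = list(as.character(nodes), space$labels))
  for (i in seq_along(nodes)) {
    v <- nodes[i]
    raw <- pr$L[v, ] * O[v, ]
    marg[i, ] <- if (sum(raw) > 0) raw / sum(raw) else raw
  }
  marg
}

#' Maximum-likelihood DEC / DEC+j fit
#'
#' Bounded multi-start maximization of the pruning likelihood over
#' `(d, e)` (plain DEC) or `(d, e, j)` (DEC+j), followed by a
#' marginal-ancestral-state pass at the optimum.
#'
#' @inheritParams dec_likelihood
#' @param model `"DEC"` (forces `j = 0`) or `"DECJ"`.
#' @param n_starts number of seeded starting points (default 5).
#' @param seed integer seed for the start grid.
#' @param bounds list with elements `d`, `e` (default `c(1e-6, 5)`) and
#'   `j` (default `c(0, 2.99999)`).
#' @return Object of class `dec_fit`: `params` (d, e, j), `lnL`,
#'   `n_params`, `model`, `node_marginals` (internal nodes x states),
#'   `convergence`, `starts`.
#' @export
dec_fit <- function(tree, ranges, space, model = c("DEC", "DECJ"),
                    n_starts = 5, seed = 1,
                    bounds = list(d = c(1e-6, 5), e = c(1e-6, 5),
                                  j = c(0, 2.99999))) {
  model <- match.arg(model)
  np <- if (model == "DEC") 2L else 3L
  lower <- c(bounds$d[1], bounds$e[1], if (np == 3) bounds$j[1])
  upper <- c(bounds$d[2], bounds$e[2], if (np == 3) bounds$j[2])
  st <- dec_structure(tree, ranges, space)
  nll <- function(par) {
    ll <- dec_prune(tree, ranges, space, par[1], par[2],
                    if (np == 3) par[3] else 0, st = st)$lnL
    if (!is.finite(ll)) 1e10 else -ll
  }
  set.seed(seed)
  # stratified (Latin-style) start grid on log scale for d, e
  strat <- function(lo, hi, k, logscale = TRUE) {
    u <- (sample(k) - runif(k)) / k
    if (logscale) exp(log(lo) + u * (log(hi) - log(lo))) else
      lo + u * (hi - lo)
  }
  starts <- cbind(d = strat(max(lower[1], 1e-4), upper[1], n_starts),
                  e = strat(max(lower[2], 1e-4), upper[2], n_starts))
  if (np == 3) {
    starts <- cbind(starts, j = strat(0.01, 1, n_starts))
    # one extra start hugging j = 0 so the nested DEC optimum is always
    # reachable from the DEC+j fit
    starts <- rbind(starts, c(starts[1, 1:2], 1e-4))
  }
  best <- NULL
  convs <- integer(0)
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[i, ], nll, method = "L-BFGS-B", lower = lower,
            upper = upper, control = list(maxit = 200)),
      error = function(err) NULL)
    if (is.null(fit)) next
    convs <- c(convs, fit$convergence)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("optimizer failed from every start")
  par <- best$par
  d <- par[1]; e <- par[2]; jj <- if (np == 3) par[3] else 0
  pr <- dec_prune(tree, ranges, space, d, e, jj, st = st)
  structure(list(params = c(d = unname(d), e = unname(e), j = unname(jj)),
                 lnL = -best$value,
                 n_params = np,
                 model = model,
                 node_marginals = dec_marginals(pr, space),
                 convergence = best$convergence,
                 converged = best$convergence == 0,
                 starts = starts),
            class = "dec_fit")
}

#' @export
print.dec_fit <- function(x, ...) {
  cat(sprintf("%s fit: lnL = %.4f (%d parameters)\n",
              if (x$model == "DEC") "DEC" else "DEC+j",
              x$lnL, x$n_params))
  cat(sprintf("  d = %.5f  e = %.5f  j = %.5f\n",
              x$params["d"], x$params["e"], x$params["j"]))
  if (!x$converged) cat("  warning: optimizer did not report convergence\n")
  invisible(x)
}

#' @export
coef.dec_fit <- function(object, ...) {
  object$params[seq_len(object$n_params)]
}

#' @export
logLik.dec_fit <- function(object, ...) {
  structure(object$lnL, df = object$n_params, class = "logLik")
}

#' Likelihood-ratio test of DEC+j against DEC
#'
#' The two models are nested and differ by the single founder-event
#' parameter, so `D = 2 (lnL_DEC+j - lnL_DEC)` is referred to a
#' chi-squared distribution with one degree of freedom.
#'
#' @param fit_dec a `dec_fit` with `model = "DEC"`.
#' @param fit_decj a `dec_fit` with `model = "DECJ"` on the same data.
#' @return List of class `dec_lrt`: `D`, `df`, `p_value`.
#' @export
dec_lrt <- function(fit_dec, fit_decj) {
  if (fit_dec$model != "DEC" || fit_decj$model != "DECJ")
    stop("arguments must be a DEC fit and a DEC+j fit")
  D <- 2 * (fit_decj$lnL - fit_dec$lnL)
  if (D < -1e-3)
    stop("DEC+j likelihood below DEC: optimizer failure (D = ",
         format(D), ")")
  D <- max(D, 0)                           # clamp optimizer noise
  structure(list(D = D, df = 1L,
                 p_value = pchisq(D, df = 1, lower.tail = FALSE)),
            class = "dec_lrt")
}

#' @export
print.dec_lrt <- function(x, ...) {
  cat(sprintf("LRT DEC+j vs DEC: D = %.4f, df = %d, p = %.3g\n",
              x$D, x$df, x$p_value))
  invisible(x)
}
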
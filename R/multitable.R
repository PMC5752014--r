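#' RV coefficient between two object configurations
#'
#' Matrix correlation between the row configurations of two tables over
#' the same objects:
#' \deqn{RV = \mathrm{tr}(XX'YY') /
#'   \sqrt{\mathrm{tr}((XX')^2)\,\mathrm{tr}((YY')^2)}.}
#'
#' @param X,Y numeric matrices with identical rows (objects) in the same
#'   order; columns are centered internally.
#' @return Coefficient in `[0, 1]`.
#' @export
rv_coef <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must describe the same objects")
  X <- sweep(X, 2, colMeans(X))
  Y <- sweep(Y, 2, colMeans(Y))
  Wx <- tcrossprod(X); Wy <- tcrossprod(Y)
  nx <- sum(Wx^2); ny <- sum(Wy^2)
  if (nx == 0 || ny == 0) stop("all-zero matrix")
  sum(Wx * Wy) / sqrt(nx * ny)
}

#' Monte-Carlo permutation test of the RV coefficient
#'
#' The rows of `Y` are randomly permuted `n_perm` times; the p-value is
#' the add-one proportion of permuted coefficients at least as large as
#' the observed one.
#'
#' @inheritParams rv_coef
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed.
#' @return Object of class `rv_test`: `rv`, `perm_values`, `p_value`,
#'   `n_perm`.
#' @export
rv_test <- function(X, Y, n_perm = 9999, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  obs <- rv_coef(X, Y)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(as.matrix(X))
  perm <- vapply(seq_len(n_perm), function(i)
    rv_coef(X, as.matrix(Y)[sample(n), , drop = FALSE]), numeric(1))
  structure(list(rv = obs, perm_values = perm,
                 p_value = (sum(perm >= obs) + 1) / (n_perm + 1),
                 n_perm = n_perm),
            class = "rv_test")
}

#' @export
print.rv_test <- function(x, ...) {
  cat(sprintf("RV = %.4f, p = %.4g (%d permutations)\n",
              x$rv, x$p_value, x$n_perm))
  invisible(x)
}

#' Multiple co-inertia analysis
#'
#' Finds, axis by axis, a unit-variance compromise (synthetic) variable
#' `v` and per-table unit loading vectors maximizing the weighted sum of
#' squared covariances between each table's score and `v`. Axis `r` is
#' the leading eigenvector of the summed weighted cross-product operator
#' \eqn{\sum_k w_k X_k X_k'}; before each subsequent axis every table is
#' deflated by regression of its columns on its own previous scores, so
#' successive loadings are orthogonal within tables.
#'
#' @param tables list of >= 2 numeric matrices over the same objects
#'   (rows), each already centered/scaled as its preliminary analysis
#'   dictates (standardized morphometrics, PCoA coordinates as-is).
#'   Columns are re-centered defensively.
#' @param weights `"uniform"` (default: tables enter with their own
#'   total inertias), `"inverse_first_eigenvalue"`, or
#'   `"inverse_total_inertia"`; alternatively a numeric vector of table
#'   weights.
#' @param n_axes number of compromise axes to extract.
#' @return Object of class `mcoa`: `pseudo_eigenvalues`,
#'   `compromise_scores` (unit-variance synthetic variables),
#'   `table_scores`, `table_loadings`, `cov2`, `cos2`, `coinertia`
#'   (tables x axes matrices), `weights`.
#' @export
mcoa <- function(tables, weights = "uniform", n_axes = 2) {
  if (!is.list(tables) || length(tables) < 1)
    stop("'tables' must be a list of matrices")
  K <- length(tables)
  tables <- lapply(tables, as.matrix)
  n <- unique(vapply(tables, nrow, 0L))
  if (length(n) != 1L)
    stop("all tables must have the same objects (rows)")
  if (is.null(names(tables)))
    names(tables) <- paste0("table", seq_len(K))
  Xk <- lapply(tables, function(M) sweep(M, 2, colMeans(M)))
  if (is.character(weights)) {
    weights <- match.arg(weights, c("uniform", "inverse_first_eigenvalue",
                                    "inverse_total_inertia"))
    w <- switch(weights,
      uniform = rep(1, K),
      inverse_first_eigenvalue = vapply(Xk, function(M)
        1 / (eigen(crossprod(M) / n, symmetric = TRUE,
                   only.values = TRUE)$values[1]), 0),
      inverse_total_inertia = vapply(Xk, function(M)
        n / sum(M^2), 0))
  } else {
    if (length(weights) != K || any(weights <= 0))
      stop("numeric weights must be positive, one per table")
    w <- weights
  }
  max_rank <- sum(vapply(Xk, function(M) qr(M)$rank, 0L))
  n_axes_req <- n_axes
  n_axes <- min(n_axes, n - 1L, max_rank)
  lab_ax <- paste0("Axis", seq_len(n_axes))
  pseudo <- numeric(n_axes)
  V <- matrix(NA_real_, n, n_axes,
              dimnames = list(rownames(tables[[1]]), lab_ax))
  cov2 <- cos2 <- coin <- matrix(NA_real_, K, n_axes,
                                 dimnames = list(names(tables), lab_ax))
  scores <- lapply(Xk, function(M)
    matrix(NA_real_, n, n_axes, dimnames = list(rownames(M), lab_ax)))
  loadings <- lapply(Xk, function(M)
    matrix(NA_real_, ncol(M), n_axes, dimnames = list(colnames(M), lab_ax)))
  Dk <- Xk                                  # deflated working copies
  r <- 0L
  while (r < n_axes) {
    r <- r + 1L
    W <- matrix(0, n, n)
    for (k in seq_len(K)) W <- W + w[k] * tcrossprod(Dk[[k]])
    if (r > 1L) {                           # orthogonal compromise axes
      Vp <- V[, seq_len(r - 1L), drop = FALSE] / sqrt(n)
      P <- diag(n) - tcrossprod(Vp)
      W <- P %*% W %*% P
      W <- (W + t(W)) / 2
    }
    eig <- eigen(W, symmetric = TRUE)
    if (eig$values[1] < 1e-12 * n) { r <- r - 1L; break }  # rank exhausted
    v <- eig$vectors[, 1] * sqrt(n)         # unit-variance compromise
    # per-table scores flip with v, so covariance with v is always >= 0;
    # determinism comes from orienting v itself
    lead <- which(abs(v) > 1e-12)[1]
    if (v[lead] < 0) v <- -v
    pseudo[r] <- eig$values[1] / n
    V[, r] <- v
    for (k in seq_len(K)) {
      a <- crossprod(Dk[[k]], v)            # X_k' v
      na <- sqrt(sum(a^2))
      if (na < 1e-12) { cov2[k, r] <- cos2[k, r] <- coin[k, r] <- 0; next }
      u <- a / na
      s <- Dk[[k]] %*% u
      if (sum(s * v) < 0) { u <- -u; s <- -s }
      loadings[[k]][, r] <- u
      scores[[k]][, r] <- s
      cv <- sum(s * v) / n
      cov2[k, r] <- cv^2
      vs <- sum(s^2) / n
      cos2[k, r] <- if (vs > 0) cv^2 / vs else 0   # Cor^2(s, v), Var(v)=1
      coin[k, r] <- vs
      # deflate: remove the component of every column along s
      if (vs > 0)
        Dk[[k]] <- Dk[[k]] - tcrossprod(s / sqrt(sum(s^2))) %*% Dk[[k]]
    }
  }
  if (r < n_axes) {
    warning("rank exhausted after ", r, " axes (", n_axes_req,
            " requested)")
    keep <- seq_len(r)
    pseudo <- pseudo[keep]; V <- V[, keep, drop = FALSE]
    cov2 <- cov2[, keep, drop = FALSE]
    cos2 <- cos2[, keep, drop = FALSE]
    coin <- coin[, keep, drop = FALSE]
    scores <- lapply(scores, function(M) M[, keep, drop = FALSE])
    loadings <- lapply(loadings, function(M) M[, keep, drop = FALSE])
  }
  structure(list(pseudo_eigenvalues = pseudo,
                 compromise_scores = V,
                 table_scores = scores,
                 table_loadings = loadings,
                 cov2 = cov2, cos2 = cos2, coinertia = coin,
                 weights = w, n_objects = n),
            class = "mcoa")
}

#' @export
print.mcoa <- function(x, ...) {
  cat("Multiple co-inertia analysis:", length(x$table_scores),
      "tables,", x$n_objects, "objects,",
      length(x$pseudo_eigenvalues), "axes\n")
  cat("  pseudo-eigenvalues:",
      paste(format(x$pseudo_eigenvalues, digits = 4), collapse = " "), "\n")
  cat("  Cov2 (per table x axis):\n")
  print(round(x$cov2, 4))
  invisible(x)
}

#' @export
summary.mcoa <- function(object, ...) {
  list(pseudo_eigenvalues = object$pseudo_eigenvalues,
       cov2 = object$cov2, cos2 = object$cos2,
       coinertia = object$coinertia)
}

#' @export
plot.mcoa <- function(x, axes = c(1, 2), ...) {
  V <- x$compromise_scores
  if (ncol(V) < max(axes)) stop("not enough axes")
  graphics::plot(V[, axes[1]], V[, axes[2]], pch = 16,
                 xlab = colnames(V)[axes[1]], ylab = colnames(V)[axes[2]],
                 ...)
  for (k in seq_along(x$table_scores)) {
    s <- x$table_scores[[k]]
    sd1 <- sqrt(mean(s[, axes[1]]^2)); sd2 <- sqrt(mean(s[, axes[2]]^2))
    graphics::segments(V[, axes[1]], V[, axes[2]],
                       s[, axes[1]] / max(sd1, 1e-12),
                       s[, axes[2]] / max(sd2, 1e-12),
                       col = k + 1)
  }
  invisible(x)
}
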
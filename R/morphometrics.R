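#' Exclude juvenile specimens below a standard-length cutoff
#'
#' Specimens strictly smaller than `min_sl` are removed to limit
#' allometric bias; the cutoff itself is kept.
#'
#' @param x a [morpho_table].
#' @param min_sl minimum standard length in mm (default 20).
#' @return The filtered `morpho_table`, with attribute `removed_ids`.
#' @export
filter_juveniles <- function(x, min_sl = 20) {
  sl <- sl_of(x)
  keep <- sl >= min_sl
  if (!any(keep)) stop("no specimens left after juvenile filtering")
  out <- morpho_table(unclass(x)[keep, , drop = FALSE],
                      rownames(x)[keep], groups_of(x)[keep],
                      kinds_of(x), attr(x, "hl_column"))
  attr(out, "removed_ids") <- rownames(x)[!keep]
  out
}

#' Impute missing cells by within-group regression on standard length
#'
#' Each missing value is replaced by the fitted value of the simple least
#' squares regression of that variable on SL, computed from the
#' non-missing specimens of the same group. A group with fewer than two
#' observed values for a variable that needs imputation is an error: the
#' procedure defines no fallback.
#'
#' @param x a [morpho_table].
#' @return A `morpho_table` with no missing cells; attribute `imputed`
#'   lists the filled (specimen, variable) pairs.
#' @export
impute_missing <- function(x) {
  vals <- unclass(x)
  grp <- groups_of(x)
  sl <- sl_of(x)
  filled <- list()
  for (j in seq_len(ncol(vals))) {
    miss <- which(is.na(vals[, j]))
    for (i in miss) {
      g <- grp[i]
      obs <- which(grp == g & !is.na(vals[, j]))
      if (length(obs) < 2L)
        stop("cannot impute '", colnames(vals)[j], "' in group '", g,
             "': fewer than 2 observed values")
      xs <- sl[obs]; ys <- vals[obs, j]
      if (stats::var(xs) == 0) {           # vertical SL: fall back to mean
        fit <- mean(ys)
      } else {
        b <- stats::cov(xs, ys) / stats::var(xs)
        a <- mean(ys) - b * mean(xs)
        fit <- a + b * sl[i]
      }
      # imputed counts snap back to the half-integer counting grid
      if (kinds_of(x)[j] == "meristic") fit <- round(2 * fit) / 2
      vals[i, j] <- fit
      filled[[length(filled) + 1L]] <-
        data.frame(id = rownames(vals)[i], variable = colnames(vals)[j],
                   value = vals[i, j])
    }
  }
  out <- morpho_table(vals, rownames(x), grp, kinds_of(x),
                      attr(x, "hl_column"))
  attr(out, "imputed") <-
    if (length(filled)) do.call(rbind, filled) else
      data.frame(id = character(), variable = character(),
                 value = numeric())
  out
}

#' Size-standardize, log-transform, center and scale a morpho table
#'
#' Morphometric variables are divided by their size denominator (SL, or
#' HL for head measurements) and log-transformed; SL itself is
#' log-transformed and retained as a variable; meristic counts enter
#' raw. Every column is then centered to mean zero and scaled to unit
#' variance (population 1/n convention, so the correlation-PCA total
#' inertia equals the column count).
#'
#' @param x an imputed [morpho_table] (no missing cells).
#' @param log_base base of the logarithm (default natural log).
#' @return A plain numeric matrix with attribute `variable_kind`.
#' @export
standardize <- function(x, log_base = exp(1)) {
  vals <- unclass(x)
  if (anyNA(vals)) stop("standardize requires an imputed table")
  kinds <- kinds_of(x)
  sl <- sl_of(x)
  hl_col <- attr(x, "hl_column")
  out <- vals
  for (j in seq_len(ncol(vals))) {
    k <- kinds[j]
    if (k == "SL") {
      out[, j] <- log(sl, base = log_base)
    } else if (k %in% c("morphometric_SL", "morphometric_HL")) {
      denom <- if (k == "morphometric_HL") vals[, hl_col] else sl
      ratio <- vals[, j] / denom
      if (any(ratio <= 0))
        stop("nonpositive morphometric value in '", colnames(vals)[j],
             "': log undefined")
      out[, j] <- log(ratio, base = log_base)
    }                                      # meristic: raw
  }
  ctr <- colMeans(out)
  out <- sweep(out, 2, ctr)
  sds <- sqrt(colMeans(out^2))             # population variance
  zero <- which(sds < 1e-12)
  if (length(zero))
    stop("zero-variance column(s): ",
         paste(colnames(out)[zero], collapse = ", "))
  out <- sweep(out, 2, sds, "/")
  attr(out, "variable_kind") <- kinds
  attr(out, "group_labels") <- groups_of(x)
  out
}

# Between-class inertia of a centered-scaled matrix under uniform row
# weights: sum_k (n_k/n) * ||group mean_k||^2.
between_inertia <- function(X, groups) {
  gm <- rowsum(X, groups) / as.vector(table(groups)[sort(unique(groups))])
  w <- as.vector(table(groups)[rownames(gm)]) / nrow(X)
  sum(w * rowSums(gm^2))
}

#' Between-group analysis with Monte-Carlo permutation test
#'
#' Performs the between-group analysis (BGA) of a centered-scaled
#' matrix: the size-weighted group-mean matrix is eigen-analysed, giving
#' the share of the total (correlation-PCA) inertia that lies between
#' groups, per-axis between-class eigenvalues, group and specimen
#' scores, and variable loadings. Significance of the between-group
#' inertia ratio is assessed by a Monte-Carlo test that permutes group
#' labels.
#'
#' @param X centered-scaled matrix from [standardize()] (or any matrix
#'   with column means 0).
#' @param groups group label per row; defaults to the labels carried by
#'   `X`.
#' @param n_perm number of random permutations (default 9999).
#' @param seed integer seed for the permutation stream.
#' @return An object of class `bga` with elements `ratio` (between /
#'   total inertia), `eigenvalues`, `group_scores`, `specimen_scores`,
#'   `variable_loadings`, `perm_distribution`, `p_value`,
#'   `total_inertia`, `group_sizes`.
#' @export
bga <- function(X, groups = attr(X, "group_labels"), n_perm = 9999,
                seed = NULL) {
  X <- as.matrix(X)
  if (is.null(groups)) stop("group labels required")
  groups <- as.character(groups)
  if (length(groups) != nrow(X)) stop("one group label per row required")
  if (length(unique(groups)) < 2 && n_perm > 0)
    warning("single group: between-group inertia is 0")
  n <- nrow(X)
  total <- sum(X^2) / n
  sizes <- table(groups)
  gm <- rowsum(X, groups) / as.vector(sizes[sort(unique(groups))])
  w <- as.vector(sizes[rownames(gm)]) / n
  B <- crossprod(gm * sqrt(w))             # t(gm) %*% diag(w) %*% gm
  eig <- eigen(B, symmetric = TRUE)
  keep <- eig$values > max(eig$values[1], 0) * 1e-9
  vals <- eig$values[keep]
  vecs <- eig$vectors[, keep, drop = FALSE]
  # deterministic sign: first coordinate of each loading positive
  for (r in seq_len(ncol(vecs))) {
    lead <- which(abs(vecs[, r]) > 1e-12)[1]
    if (!is.na(lead) && vecs[lead, r] < 0) vecs[, r] <- -vecs[, r]
  }
  rownames(vecs) <- colnames(X)
  colnames(vecs) <- paste0("Axis", seq_len(ncol(vecs)))
  ratio <- sum(vals) / total
  perm <- numeric(0)
  p <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    perm <- vapply(seq_len(n_perm), function(i)
      between_inertia(X, sample(groups)) / total, numeric(1))
    p <- (sum(perm >= ratio) + 1) / (n_perm + 1)
  }
  structure(list(ratio = ratio,
                 eigenvalues = vals,
                 group_scores = gm %*% vecs,
                 specimen_scores = X %*% vecs,
                 variable_loadings = vecs,
                 perm_distribution = perm,
                 p_value = p,
                 total_inertia = total,
                 group_sizes = sizes,
                 n_perm = n_perm),
            class = "bga")
}

#' @export
print.bga <- function(x, ...) {
  cat("Between-group analysis\n")
  cat(sprintf("  groups: %d  specimens: %d  variables: %d\n",
              length(x$group_sizes), nrow(x$specimen_scores),
              nrow(x$variable_loadings)))
  cat(sprintf("  between/total inertia: %.4f of %.4g\n",
              x$ratio, x$total_inertia))
  if (length(x$eigenvalues) >= 2)
    cat(sprintf("  axes 1+2 share of between-class inertia: %.2f%%\n",
                100 * sum(x$eigenvalues[1:2]) / sum(x$eigenvalues)))
  if (!is.na(x$p_value))
    cat(sprintf("  permutation test: p = %.4g (%d permutations)\n",
                x$p_value, x$n_perm))
  invisible(x)
}

#' @export
summary.bga <- function(object, ...) {
  ev <- object$eigenvalues
  out <- list(ratio = object$ratio,
              p_value = object$p_value,
              eigenvalues = ev,
              axis_share = ev / sum(ev),
              total_inertia = object$total_inertia)
  class(out) <- "summary.bga"
  out
}

#' @export
print.summary.bga <- function(x, ...) {
  cat("BGA: between/total inertia =", format(x$ratio, digits = 6),
      " p =", format(x$p_value, digits = 4), "\n")
  tab <- rbind(eigenvalue = x$eigenvalues,
               share = x$axis_share,
               cumulative = cumsum(x$axis_share))
  colnames(tab) <- paste0("Axis", seq_along(x$eigenvalues))
  print(round(tab, 4))
  invisible(x)
}

#' @export
plot.bga <- function(x, axes = c(1, 2), ...) {
  s <- x$specimen_scores
  if (ncol(s) < max(axes)) stop("not enough axes")
  graphics::plot(s[, axes[1]], s[, axes[2]],
                 xlab = colnames(s)[axes[1]], ylab = colnames(s)[axes[2]],
                 pch = 16, col = "grey50", ...)
  g <- x$group_scores
  graphics::points(g[, axes[1]], g[, axes[2]], pch = 17, col = "red3")
  graphics::text(g[, axes[1]], g[, axes[2]], rownames(g), pos = 3,
                 cex = 0.7)
  invisible(x)
}
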
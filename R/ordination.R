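new_ordination <- function(eigenvalues, row_scores, col_loadings,
                           total_inertia, correction_constant = 0,
                           method = "pca") {
  structure(list(eigenvalues = eigenvalues,
                 row_scores = row_scores,
                 col_loadings = col_loadings,
                 total_inertia = total_inertia,
                 correction_constant = correction_constant,
                 method = method),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat("Ordination (", x$method, "): ", nrow(x$row_scores), " objects, ",
      length(x$eigenvalues), " axes\n", sep = "")
  cat("  total inertia:", format(x$total_inertia, digits = 6), "\n")
  share <- x$eigenvalues / x$total_inertia
  k <- min(5, length(share))
  cat("  leading axis shares:",
      paste(sprintf("%.3f", share[seq_len(k)]), collapse = " "), "\n")
  if (x$correction_constant > 0)
    cat("  Cailliez constant c =",
        format(x$correction_constant, digits = 6), "\n")
  invisible(x)
}

#' @export
summary.ordination <- function(object, ...) {
  share <- object$eigenvalues / sum(object$eigenvalues)
  data.frame(axis = seq_along(object$eigenvalues),
             eigenvalue = object$eigenvalues,
             share = share,
             cumulative = cumsum(share))
}

# deterministic axis orientation: first nonzero element positive
fix_signs <- function(scores, loadings = NULL) {
  for (r in seq_len(ncol(scores))) {
    ref <- if (is.null(loadings)) scores[, r] else loadings[, r]
    lead <- which(abs(ref) > 1e-12)[1]
    if (!is.na(lead) && ref[lead] < 0) {
      scores[, r] <- -scores[, r]
      if (!is.null(loadings)) loadings[, r] <- -loadings[, r]
    }
  }
  list(scores = scores, loadings = loadings)
}

#' Principal component analysis (1/n inertia convention)
#'
#' Eigen-decomposition of the covariance (or correlation, with
#' `scale = TRUE`) structure under the population 1/n convention, so
#' that a centered-scaled matrix has total inertia equal to its column
#' count.
#'
#' @param X numeric matrix, observations in rows. Already-standardized
#'   matrices (from [standardize()]) should use the defaults.
#' @param center,scale center / scale columns before the decomposition
#'   (population standard deviation).
#' @return An `ordination` object: `eigenvalues`, `row_scores`
#'   (principal coordinates), `col_loadings` (unit eigenvectors),
#'   `total_inertia`.
#' @export
pca <- function(X, center = TRUE, scale = FALSE) {
  X <- as.matrix(X)
  if (center) X <- sweep(X, 2, colMeans(X))
  if (scale) {
    sds <- sqrt(colMeans(X^2))
    if (any(sds < 1e-12))
      stop("zero-variance column(s): ",
           paste(colnames(X)[sds < 1e-12], collapse = ", "))
    X <- sweep(X, 2, sds, "/")
  }
  n <- nrow(X)
  C <- crossprod(X) / n
  eig <- eigen(C, symmetric = TRUE)
  keep <- eig$values > max(eig$values[1], 0) * 1e-9
  vals <- eig$values[keep]
  vecs <- eig$vectors[, keep, drop = FALSE]
  rownames(vecs) <- colnames(X)
  scores <- X %*% vecs
  fixed <- fix_signs(scores, vecs)
  colnames(fixed$scores) <- colnames(fixed$loadings) <-
    paste0("Axis", seq_len(ncol(vecs)))
  rownames(fixed$scores) <- rownames(X)
  new_ordination(vals, fixed$scores, fixed$loadings,
                 total_inertia = sum(diag(C)), method = "pca")
}

# Gower double-centering of -0.5 * D^2
gower_center <- function(D) {
  A <- -0.5 * D^2
  rm <- rowMeans(A); gm <- mean(A)
  sweep(sweep(A, 1, rm), 2, rm) + gm
}

# Smallest additive constant making D Euclidean (largest eigenvalue of
# the 2n x 2n companion problem of Cailliez 1983).
cailliez_constant <- function(D) {
  n <- nrow(D)
  d1 <- gower_center(D)
  d2 <- {
    A <- -0.5 * D
    rm <- rowMeans(A); gm <- mean(A)
    sweep(sweep(A, 1, rm), 2, rm) + gm
  }
  M <- rbind(cbind(matrix(0, n, n), 2 * d1),
             cbind(-diag(n), -4 * d2))
  ev <- eigen(M, only.values = TRUE)$values
  max(Re(ev))
}

#' Principal coordinates analysis with optional Cailliez correction
#'
#' Metric scaling of a dissimilarity matrix. With
#' `correction = "cailliez"` and negative eigenvalues present, the
#' smallest constant `c` is added to every off-diagonal dissimilarity so
#' that the corrected matrix is Euclidean, and the analysis is recomputed
#' on the corrected matrix: pairwise distances between the returned row
#' scores then reproduce `D + c` exactly.
#'
#' @param D labeled symmetric dissimilarity matrix with zero diagonal.
#' @param correction `"none"` or `"cailliez"`.
#' @param tol relative tolerance below which negative eigenvalues are
#'   considered numerical noise.
#' @return An `ordination` object (`col_loadings` is `NULL`);
#'   `correction_constant` holds `c` (0 when the input is already
#'   Euclidean).
#' @export
pcoa <- function(D, correction = c("none", "cailliez"), tol = 1e-8) {
  correction <- match.arg(correction)
  check_distance_matrix(D)
  n <- nrow(D)
  cc <- 0
  G <- gower_center(D)
  ev <- eigen(G, symmetric = TRUE)$values
  if (correction == "cailliez" && min(ev) < -tol * max(abs(ev))) {
    cc <- cailliez_constant(D)
    D <- D + cc
    diag(D) <- 0
    G <- gower_center(D)
  }
  eig <- eigen(G, symmetric = TRUE)
  vals <- eig$values
  # keep positive axes up to rank n-1; truncate numerical noise
  keep <- which(vals > tol * max(abs(vals)))
  keep <- head(keep, n - 1L)
  vals_k <- vals[keep]
  vecs <- eig$vectors[, keep, drop = FALSE]
  scores <- sweep(vecs, 2, sqrt(vals_k), "*")
  scores <- fix_signs(scores)$scores
  rownames(scores) <- rownames(D)
  colnames(scores) <- paste0("Axis", seq_along(keep))
  new_ordination(vals_k, scores, NULL,
                 total_inertia = sum(vals[vals > 0]),
                 correction_constant = cc, method = "pcoa")
}

#' Patristic distance matrix of a tree
#'
#' Sum of branch lengths along the path between every pair of tips.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @return Labeled symmetric matrix in branch-length units.
#' @export
patristic <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  D <- stats::cophenetic(tree)
  D[tree$tip.label, tree$tip.label]
}

#' Great-circle distance matrix of georeferenced points
#'
#' Haversine distances on a sphere of mean radius 6,371,008.8 m.
#'
#' @param points a [geo_points] data frame.
#' @param radius sphere radius in meters.
#' @return Labeled symmetric matrix of distances in meters.
#' @export
geodesic <- function(points, radius = 6371008.8) {
  stopifnot(inherits(points, "geo_points"))
  xy <- cbind(points$lon, points$lat)
  D <- geosphere::distm(xy, fun = function(p1, p2)
    geosphere::distHaversine(p1, p2, r = radius))
  dimnames(D) <- list(points$id, points$id)
  D
}
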
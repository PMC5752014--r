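#' Restrict multi-modal inputs to their common individuals
#'
#' Intersects the identifiers of the morphometric table, the tree (or
#' sequence set), and the coordinate table, and returns all three
#' restricted to the shared individuals in a single common order.
#'
#' @param morpho a [morpho_table].
#' @param phylo an [ape::phylo] tree, a [sequence_set], or a character
#'   vector of ids.
#' @param gps a [geo_points] data frame.
#' @return List of class `common_set`: `morpho`, `phylo`, `gps`, `ids`,
#'   and `dropped` (per-source lists of discarded ids).
#' @export
restrict_common <- function(morpho, phylo, gps) {
  ids_m <- rownames(morpho)
  ids_p <- if (inherits(phylo, "phylo")) phylo$tip.label
           else if (inherits(phylo, "sequence_set")) names(phylo)
           else as.character(phylo)
  ids_g <- gps$id
  common <- intersect(intersect(ids_m, ids_p), ids_g)
  if (!length(common)) stop("no individuals shared by all three inputs")
  common <- ids_m[ids_m %in% common]        # keep morpho row order
  m <- morpho_table(unclass(morpho)[common, , drop = FALSE], common,
                    groups_of(morpho)[match(common, ids_m)],
                    kinds_of(morpho), attr(morpho, "hl_column"))
  p <- if (inherits(phylo, "phylo"))
    ape::keep.tip(phylo, common) else if (inherits(phylo, "sequence_set"))
      sequence_set(common, unclass(phylo)[common],
                   attr(phylo, "group_labels")[match(common, ids_p)])
    else common
  g <- geo_points(common, gps$lat[match(common, ids_g)],
                  gps$lon[match(common, ids_g)])
  structure(list(morpho = m, phylo = p, gps = g, ids = common,
                 dropped = list(morpho = setdiff(ids_m, common),
                                phylo = setdiff(ids_p, common),
                                gps = setdiff(ids_g, common))),
            class = "common_set")
}

#' @export
print.common_set <- function(x, ...) {
  cat("Common individual set: n =", length(x$ids), "\n")
  nd <- vapply(x$dropped, length, 0L)
  if (any(nd > 0))
    cat("  dropped:", paste(names(nd), nd, sep = "=", collapse = ", "),
        "\n")
  invisible(x)
}

#' Integrative multi-table analysis of morphometry, phylogeny and space
#'
#' Runs the full multi-table workflow on a joint individual set:
#' standardized population-mean morphometrics (within-population
#' variability removed, means replicated back to individuals), a
#' Cailliez-corrected PCoA of the patristic distances, a PCoA of
#' great-circle geographic distances, pairwise RV permutation tests
#' between the three representations, and their multiple co-inertia
#' analysis.
#'
#' @param morpho a [morpho_table] (raw; imputed and standardized
#'   internally).
#' @param tree an [ape::phylo] tree covering (at least) the morpho ids.
#' @param gps a [geo_points] data frame.
#' @param min_sl juvenile standard-length cutoff in mm.
#' @param n_axes number of MCOA axes.
#' @param n_perm permutations for each RV test.
#' @param seed integer seed.
#' @param weights MCOA table-weight rule (see [mcoa()]).
#' @return Object of class `integrative_report`: `common`, `tables`
#'   (the three aligned matrices), `rv` (matrix with RV above and
#'   p-values below the diagonal), `rv_tests`, `mcoa`, `table3`
#'   (Inertia / Co-Inertia / Cos2 / Cov2 blocks), `seed`.
#' @export
run_integrative <- function(morpho, tree, gps, min_sl = 20, n_axes = 2,
                            n_perm = 9999, seed = 1,
                            weights = "uniform") {
  cs <- restrict_common(filter_juveniles(morpho, min_sl), tree, gps)
  # morphometric table: population means on the standardized scale,
  # replicated back to individuals so the three tables stay conformable
  Z <- standardize(impute_missing(cs$morpho))
  grp <- groups_of(cs$morpho)
  gm <- rowsum(Z, grp) / as.vector(table(grp)[sort(unique(grp))])
  Xm <- gm[grp, , drop = FALSE]
  rownames(Xm) <- cs$ids
  ord_p <- pcoa(patristic(cs$phylo)[cs$ids, cs$ids],
                correction = "cailliez")
  ord_g <- pcoa(geodesic(cs$gps), correction = "cailliez")
  # each table enters with unit total inertia so the co-inertia /
  # cos2 / cov2 decomposition reads as comparable shares
  unit_inertia <- function(X) {
    X <- sweep(X, 2, colMeans(X))
    X / sqrt(sum(X^2) / nrow(X))
  }
  tables <- list(phylogeny = unit_inertia(ord_p$row_scores),
                 morphology = unit_inertia(Xm),
                 geography = unit_inertia(ord_g$row_scores))
  seeds <- child_seeds(seed, 4L)
  pairs <- combn(names(tables), 2, simplify = FALSE)
  rv_tests <- list()
  K <- length(tables)
  rvmat <- matrix(NA_real_, K, K,
                  dimnames = list(names(tables), names(tables)))
  for (i in seq_along(pairs)) {
    a <- pairs[[i]][1]; b <- pairs[[i]][2]
    tst <- rv_test(tables[[a]], tables[[b]], n_perm = n_perm,
                   seed = seeds[i])
    rv_tests[[paste(a, b, sep = "_vs_")]] <- tst
    rvmat[a, b] <- tst$rv
    rvmat[b, a] <- tst$p_value
  }
  mc <- mcoa(tables, weights = weights, n_axes = n_axes)
  prelim_inertia <- rbind(
    phylogeny = ord_p$eigenvalues[seq_len(n_axes)] / ord_p$total_inertia,
    morphology = {
      pm <- pca(gm, center = TRUE, scale = FALSE)
      pm$eigenvalues[seq_len(n_axes)] / pm$total_inertia
    },
    geography = ord_g$eigenvalues[seq_len(n_axes)] / ord_g$total_inertia)
  colnames(prelim_inertia) <- paste0("Axis", seq_len(n_axes))
  table3 <- rbind(
    data.frame(block = "Inertia", table = rownames(prelim_inertia),
               as.data.frame(prelim_inertia), row.names = NULL),
    data.frame(block = "Co-Inertia", table = rownames(mc$coinertia),
               as.data.frame(mc$coinertia), row.names = NULL),
    data.frame(block = "Cos2", table = rownames(mc$cos2),
               as.data.frame(mc$cos2), row.names = NULL),
    data.frame(block = "Cov2", table = rownames(mc$cov2),
               as.data.frame(mc$cov2), row.names = NULL))
  structure(list(common = cs, tables = tables, rv = rvmat,
                 rv_tests = rv_tests, mcoa = mc, table3 = table3,
                 ordinations = list(phylogeny = ord_p, geography = ord_g),
                 seed = seed),
            class = "integrative_report")
}

#' @export
print.integrative_report <- function(x, ...) {
  cat("Integrative multi-table analysis (n =", length(x$common$ids),
      "individuals)\n")
  cat("RV coefficients (upper) / permutation p-values (lower):\n")
  print(round(x$rv, 4))
  cat("\nMCOA decomposition:\n")
  print(x$table3, digits = 4)
  invisible(x)
}

#' Write the tabular outputs of an integrative report
#' @param report an `integrative_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                   quote = FALSE, col.names = NA)
  wt(round(report$rv, 6), "rv_tests.tsv")
  write.table(report$table3, file.path(dir, "table3_style.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  wt(report$mcoa$compromise_scores, "compromise_scores.tsv")
  manifest <- list(seed = report$seed,
                   n_individuals = length(report$common$ids),
                   pseudo_eigenvalues = report$mcoa$pseudo_eigenvalues)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Relative species abundance per locality
#'
#' Converts a (species, locality, count) collection table into
#' per-locality proportions. An optional readability constant is added
#' to every count before forming proportions (the occurrence + abundance
#' convention used for pie-chart display of rare species).
#'
#' @param x data.frame with columns `species`, `locality`,
#'   `n_specimens`.
#' @param constant nonnegative constant added to each count.
#' @return data.frame with columns `locality`, `species`, `n_specimens`,
#'   `proportion`; attribute `overall` holds each species' share of all
#'   specimens (no constant applied).
#' @export
relative_abundance <- function(x, constant = 0) {
  need <- c("species", "locality", "n_specimens")
  if (!all(need %in% names(x)))
    stop("expected columns species, locality, n_specimens")
  if (any(x$n_specimens < 0)) stop("negative counts")
  if (constant < 0) stop("constant must be nonnegative")
  out <- do.call(rbind, lapply(split(x, x$locality), function(loc) {
    k <- loc$n_specimens + constant
    data.frame(locality = loc$locality, species = loc$species,
               n_specimens = loc$n_specimens,
               proportion = k / sum(k), row.names = NULL)
  }))
  rownames(out) <- NULL
  tot <- tapply(x$n_specimens, x$species, sum)
  attr(out, "overall") <- tot / sum(tot)
  out
}
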
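#' Kimura two-parameter distance between two aligned sequences
#'
#' Sites where either character is not an unambiguous A/C/G/T (gaps,
#' `N`, IUPAC ambiguity codes) are deleted pairwise. With `P` the
#' transition and `Q` the transversion proportion over the retained
#' sites, the distance is
#' \deqn{d = -\tfrac12 \log\{(1 - 2P - Q)\sqrt{1 - 2Q}\}.}
#' When a log argument is nonpositive, or no comparable sites remain,
#' the distance is undefined and `NA` is returned.
#'
#' @param a,b character strings (or single-character vectors) of equal
#'   length.
#' @return Distance in substitutions/site, or `NA_real_` when undefined.
#' @export
k2p <- function(a, b) {
  av <- if (length(a) == 1L) strsplit(toupper(a), "")[[1]] else toupper(a)
  bv <- if (length(b) == 1L) strsplit(toupper(b), "")[[1]] else toupper(b)
  if (length(av) != length(bv)) stop("sequence length mismatch")
  k2p_counts_to_dist(k2p_site_counts(av, bv))
}

# (n_sites, n_transitions, n_transversions) after pairwise deletion
k2p_site_counts <- function(av, bv) {
  ok <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  av <- av[ok]; bv <- bv[ok]
  n <- length(av)
  diff <- av != bv
  purine <- function(x) x == "A" | x == "G"
  ts <- sum(diff & (purine(av) == purine(bv)))
  c(n = n, ts = ts, tv = sum(diff) - ts)
}

k2p_counts_to_dist <- function(cnt) {
  n <- cnt[["n"]]
  if (n == 0L) return(NA_real_)
  P <- cnt[["ts"]] / n
  Q <- cnt[["tv"]] / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1 * sqrt(w2))
}

#' Pairwise K2P distance matrix of an aligned sequence set
#'
#' @param x a [sequence_set].
#' @param warn_undefined warn when any pairwise distance is undefined
#'   (saturated or no comparable sites); such entries are `NA`.
#' @return A labeled symmetric matrix (substitutions/site) with zero
#'   diagonal.
#' @export
k2p_matrix <- function(x, warn_undefined = TRUE) {
  n <- length(x)
  mats <- lapply(unname(x), function(s) strsplit(s, "")[[1]])
  D <- matrix(0, n, n, dimnames = list(names(x), names(x)))
  n_undef <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- k2p_counts_to_dist(k2p_site_counts(mats[[i]], mats[[j]]))
    if (is.na(d)) n_undef <- n_undef + 1L
    D[i, j] <- D[j, i] <- d
  }
  if (n_undef && warn_undefined)
    warning(n_undef, " pairwise K2P distance(s) undefined; returned as NA")
  D
}

#' Long-format export of a distance matrix (for levelplot-style display)
#' @param D labeled symmetric distance matrix.
#' @return data.frame with columns `row`, `col`, `distance`, one row per
#'   unordered pair.
#' @export
dist_long <- function(D) {
  check_distance_matrix(D, allow_na = TRUE)
  idx <- which(upper.tri(D), arr.ind = TRUE)
  data.frame(row = rownames(D)[idx[, 1]],
             col = colnames(D)[idx[, 2]],
             distance = D[idx])
}

#' Within- and between-group distance summaries
#'
#' Pools distances into conspecific (within-label) and heterospecific
#' (between-label) sets, reporting min/max/mean for each plus per
#' label-pair summaries; undefined (`NA`) distances are dropped with a
#' count.
#'
#' @param D labeled symmetric distance matrix.
#' @param labels group/species label per row of `D`.
#' @return A list of class `group_dist_summary`: `within`, `between`
#'   (numeric vectors), `within_stats`, `between_stats`, `per_pair`
#'   (data.frame), `n_undefined`.
#' @export
group_distance_summary <- function(D, labels) {
  check_distance_matrix(D, allow_na = TRUE)
  labels <- as.character(labels)
  if (length(labels) != nrow(D)) stop("one label per individual required")
  idx <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[idx]
  la <- labels[idx[, 1]]; lb <- labels[idx[, 2]]
  n_undef <- sum(is.na(d))
  keep <- !is.na(d)
  d <- d[keep]; la <- la[keep]; lb <- lb[keep]
  same <- la == lb
  stats3 <- function(v) if (!length(v))
    c(min = NA, max = NA, mean = NA) else
    c(min = min(v), max = max(v), mean = mean(v))
  pair <- ifelse(same, la, paste(pmin(la, lb), pmax(la, lb), sep = " vs "))
  per_pair <- do.call(rbind, lapply(split(seq_along(d), pair), function(k)
    data.frame(pair = pair[k[1]], type = if (same[k[1]]) "within" else "between",
               n = length(k), min = min(d[k]), max = max(d[k]),
               mean = mean(d[k]))))
  rownames(per_pair) <- NULL
  structure(list(within = d[same], between = d[!same],
                 within_stats = stats3(d[same]),
                 between_stats = stats3(d[!same]),
                 per_pair = per_pair,
                 n_undefined = n_undef),
            class = "group_dist_summary")
}

#' @export
print.group_dist_summary <- function(x, ...) {
  cat("Group distance summary\n")
  cat(sprintf("  within : n=%d  min=%.4g max=%.4g mean=%.4g\n",
              length(x$within), x$within_stats[1], x$within_stats[2],
              x$within_stats[3]))
  cat(sprintf("  between: n=%d  min=%.4g max=%.4g mean=%.4g\n",
              length(x$between), x$between_stats[1], x$between_stats[2],
              x$between_stats[3]))
  if (x$n_undefined)
    cat("  undefined distances dropped:", x$n_undefined, "\n")
  invisible(x)
}

#' Per-individual barcoding gap
#'
#' For every individual with at least one conspecific, computes the
#' furthest conspecific distance (`max_intra`), the closest
#' heterospecific distance (`min_inter`) and their difference
#' `gap = min_inter - max_intra`; a nonpositive gap flags the absence of
#' a barcoding gap for that individual. Individuals whose label has a
#' single member are reported separately.
#'
#' @inheritParams group_distance_summary
#' @return data.frame of class `gap_records` with columns `id`,
#'   `max_intra`, `min_inter`, `gap`; attribute `singletons` lists
#'   excluded ids.
#' @export
barcode_gap <- function(D, labels) {
  check_distance_matrix(D, allow_na = TRUE)
  labels <- as.character(labels)
  if (length(labels) != nrow(D)) stop("one label per individual required")
  n <- nrow(D)
  rec <- list()
  singletons <- character()
  for (i in seq_len(n)) {
    con <- which(labels == labels[i]); con <- setdiff(con, i)
    het <- which(labels != labels[i])
    if (!length(con)) { singletons <- c(singletons, rownames(D)[i]); next }
    mi <- suppressWarnings(max(D[i, con], na.rm = TRUE))
    mo <- if (length(het))
      suppressWarnings(min(D[i, het], na.rm = TRUE)) else NA_real_
    if (!is.finite(mi)) mi <- NA_real_
    if (!is.null(mo) && !is.finite(mo)) mo <- NA_real_
    rec[[length(rec) + 1L]] <- data.frame(
      id = rownames(D)[i], max_intra = mi, min_inter = mo,
      gap = mo - mi)
  }
  out <- if (length(rec)) do.call(rbind, rec) else
    data.frame(id = character(), max_intra = numeric(),
               min_inter = numeric(), gap = numeric())
  rownames(out) <- NULL
  structure(out, singletons = singletons,
            class = c("gap_records", "data.frame"))
}

#' @export
print.gap_records <- function(x, ...) {
  cat("Barcode gap records:", nrow(x), "individuals;",
      sum(x$gap <= 0, na.rm = TRUE), "without a positive gap\n")
  if (length(attr(x, "singletons")))
    cat("  singleton labels excluded:",
        paste(attr(x, "singletons"), collapse = ", "), "\n")
  NextMethod()
}

# Classify every individual at one threshold. An individual's neighbors
# are all others within distance t. Singletons (no conspecific in the
# data): true negative when alone, false positive otherwise. Others:
# false negative when alone, true positive when all neighbors are
# conspecific, false positive otherwise.
.classify_at <- function(D, labels, t) {
  n <- nrow(D)
  cls <- character(n)
  for (i in seq_len(n)) {
    nb <- which(D[i, ] <= t & seq_len(n) != i & !is.na(D[i, ]))
    has_con <- any(labels == labels[i] & seq_len(n) != i)
    if (!has_con) {
      cls[i] <- if (!length(nb)) "true_neg" else "false_pos"
    } else if (!length(nb)) {
      cls[i] <- "false_neg"
    } else if (all(labels[nb] == labels[i])) {
      cls[i] <- "true_pos"
    } else {
      cls[i] <- "false_pos"
    }
  }
  cls
}

#' Identification-threshold optimization over a distance grid
#'
#' Scans an ascending grid of candidate identification thresholds; at
#' each threshold every individual is classified by its neighborhood
#' (all individuals within the threshold distance), and false positive /
#' false negative identifications are counted. The optimum minimizes the
#' cumulative error (false positives + false negatives); all minimizers
#' are reported, smallest first.
#'
#' @inheritParams group_distance_summary
#' @param grid ascending numeric vector of thresholds
#'   (default `seq(0.001, 0.1, 0.001)`).
#' @return data.frame of class `threshold_table` with columns
#'   `threshold`, `true_pos`, `true_neg`, `false_pos`, `false_neg`,
#'   `cumulative_error`; attribute `optimum` holds the minimizing
#'   threshold(s).
#' @export
optimize_threshold <- function(D, labels, grid = seq(0.001, 0.1, 0.001)) {
  check_distance_matrix(D, allow_na = TRUE)
  labels <- as.character(labels)
  if (!length(grid)) stop("empty threshold grid")
  if (is.unsorted(grid)) stop("grid must be ascending")
  rows <- lapply(grid, function(t) {
    cls <- .classify_at(D, labels, t)
    data.frame(threshold = t,
               true_pos = sum(cls == "true_pos"),
               true_neg = sum(cls == "true_neg"),
               false_pos = sum(cls == "false_pos"),
               false_neg = sum(cls == "false_neg"))
  })
  out <- do.call(rbind, rows)
  out$cumulative_error <- out$false_pos + out$false_neg
  opt <- out$threshold[out$cumulative_error == min(out$cumulative_error)]
  structure(out, optimum = sort(opt),
            class = c("threshold_table", "data.frame"))
}

#' @export
print.threshold_table <- function(x, ...) {
  opt <- attr(x, "optimum")
  cat("Threshold optimization over", nrow(x), "thresholds\n")
  cat(sprintf("  minimum cumulative error %d at threshold %s\n",
              min(x$cumulative_error),
              paste(format(opt), collapse = ", ")))
  invisible(x)
}

#' @export
plot.threshold_table <- function(x, ...) {
  graphics::barplot(t(as.matrix(x[, c("false_pos", "false_neg")])),
                    names.arg = format(x$threshold), las = 2,
                    col = c("grey80", "grey30"),
                    ylab = "count", xlab = "threshold", ...)
  graphics::legend("topright", fill = c("grey80", "grey30"),
                   legend = c("false positive", "false negative"))
  invisible(x)
}
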
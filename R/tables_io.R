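#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef cor cov lm optim pchisq rbinom rexp rnorm runif
#'   sd setNames var cophenetic predict
#' @importFrom utils read.csv write.csv combn head read.delim write.table
#' @importFrom ape read.tree multi2di keep.tip bind.tree
#' @importFrom Matrix expm
#' @importFrom geosphere distHaversine
#' @importFrom jsonlite write_json read_json
NULL

VARIABLE_KINDS <- c("morphometric_SL", "morphometric_HL", "meristic", "SL")

#' Specimen-by-variable morphometric table
#'
#' Container for a specimens x variables table of morphometric
#' measurements (mm) and meristic counts (possibly half-integer, e.g.
#' plates counted to the nearest half plate), with one group
#' (population/morph) label per specimen and one column flagged as the
#' standard length (SL).
#'
#' @param values numeric matrix (specimens x variables), `NA` for missing
#'   cells.
#' @param specimen_ids character vector of unique specimen identifiers.
#' @param group_labels character/factor vector, one label per specimen.
#' @param variable_kind character vector, one of `"morphometric_SL"`,
#'   `"morphometric_HL"`, `"meristic"`, `"SL"` per variable. Exactly one
#'   variable must be flagged `"SL"`.
#' @param hl_column optional name of the head-length column used as the
#'   denominator for `"morphometric_HL"` variables.
#' @return An object of class `morpho_table`: the values matrix with
#'   attributes `group_labels`, `variable_kind` and `hl_column`.
#' @export
morpho_table <- function(values, specimen_ids, group_labels, variable_kind,
                         hl_column = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  p <- ncol(values)
  specimen_ids <- as.character(specimen_ids)
  group_labels <- as.character(group_labels)
  if (length(specimen_ids) != n)
    stop("one specimen id per row required")
  if (anyDuplicated(specimen_ids))
    stop("duplicate specimen ids: ",
         paste(unique(specimen_ids[duplicated(specimen_ids)]), collapse = ", "))
  if (length(group_labels) != n || anyNA(group_labels))
    stop("a group label is required for every specimen")
  if (length(variable_kind) != p)
    stop("one variable kind per column required")
  bad <- setdiff(variable_kind, VARIABLE_KINDS)
  if (length(bad))
    stop("unknown variable kind: ", paste(bad, collapse = ", "))
  if (sum(variable_kind == "SL") != 1L)
    stop("exactly one variable must be flagged 'SL'")
  sl <- values[, variable_kind == "SL"]
  if (anyNA(sl))
    stop("SL missing for specimens: ",
         paste(specimen_ids[is.na(sl)], collapse = ", "))
  mer <- which(variable_kind == "meristic")
  for (j in mer) {
    v <- values[, j]
    v <- v[!is.na(v)]
    if (any(abs(v * 2 - round(v * 2)) > 1e-8))
      stop("meristic column '", colnames(values)[j],
           "' contains values off the 0.5 grid")
  }
  if (any(variable_kind == "morphometric_HL")) {
    if (is.null(hl_column) || !hl_column %in% colnames(values))
      stop("morphometric_HL variables require 'hl_column' naming the HL column")
  }
  rownames(values) <- specimen_ids
  structure(values,
            group_labels = group_labels,
            variable_kind = variable_kind,
            hl_column = hl_column,
            class = c("morpho_table", "matrix", "array"))
}

#' @export
print.morpho_table <- function(x, ...) {
  cat("Morphometric table: ", nrow(x), " specimens x ", ncol(x),
      " variables (", sum(is.na(x)), " missing cells)\n", sep = "")
  kinds <- table(attr(x, "variable_kind"))
  cat("Variable kinds:",
      paste(names(kinds), kinds, sep = "=", collapse = ", "), "\n")
  cat("Groups:", length(unique(attr(x, "group_labels"))), "\n")
  invisible(x)
}

#' Group labels and variable kinds of a morpho_table
#' @param x a `morpho_table`.
#' @return character vector.
#' @export
groups_of <- function(x) attr(x, "group_labels")

#' @rdname groups_of
#' @export
kinds_of <- function(x) attr(x, "variable_kind")

#' Standard-length column of a morpho_table
#' @param x a `morpho_table`.
#' @return numeric vector of SL values (mm).
#' @export
sl_of <- function(x) x[, kinds_of(x) == "SL"]

#' Read a morphometric/meristic CSV table
#'
#' The schema names the id, group and SL columns and gives the kind of
#' every measured variable; empty cells and "NA" (case-insensitive) are
#' parsed as missing.
#'
#' @param path CSV file with a header row.
#' @param schema either a list with elements `id_column`, `group_column`,
#'   `sl_column`, optionally `hl_column`, and `variable_kind` (named
#'   character vector: column name -> kind), or the path to a JSON file
#'   with those fields.
#' @return A [morpho_table].
#' @export
read_morpho_table <- function(path, schema) {
  if (is.character(schema) && length(schema) == 1L)
    schema <- jsonlite::read_json(schema, simplifyVector = TRUE)
  df <- read.csv(path, check.names = FALSE, colClasses = "character",
                 strip.white = TRUE)
  need <- c(schema$id_column, schema$group_column, schema$sl_column,
            names(schema$variable_kind))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("columns absent from ", path, ": ", paste(miss, collapse = ", "))
  vars <- c(schema$sl_column, names(schema$variable_kind))
  kinds <- c("SL", unname(unlist(schema$variable_kind)))
  vals <- sapply(df[vars], function(v) {
    v[v == "" | toupper(v) == "NA"] <- NA
    as.numeric(v)
  })
  vals <- matrix(vals, nrow = nrow(df), dimnames = list(NULL, vars))
  morpho_table(vals,
               specimen_ids = df[[schema$id_column]],
               group_labels = df[[schema$group_column]],
               variable_kind = kinds,
               hl_column = schema$hl_column)
}

#' Write a morpho_table back to CSV (missing cells as "NA")
#' @param x a `morpho_table`.
#' @param path output CSV path.
#' @param id_column,group_column column names used on output.
#' @return `path`, invisibly.
#' @export
write_morpho_table <- function(x, path, id_column = "id",
                               group_column = "group") {
  df <- data.frame(rownames(x), groups_of(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  names(df)[1:2] <- c(id_column, group_column)
  write.csv(df, path, row.names = FALSE, na = "NA", quote = FALSE)
  invisible(path)
}

IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N", "-")

#' Aligned DNA sequence set
#'
#' @param ids unique sequence/specimen identifiers.
#' @param sequences character vector of equal-length IUPAC DNA strings
#'   (gaps `-` allowed).
#' @param group_labels optional species/population label per sequence.
#' @return An object of class `sequence_set` (named character vector with
#'   a `group_labels` attribute).
#' @export
sequence_set <- function(ids, sequences, group_labels = NULL) {
  ids <- as.character(ids)
  sequences <- toupper(as.character(sequences))
  if (length(ids) != length(sequences))
    stop("one id per sequence required")
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  len <- unique(nchar(sequences))
  if (length(len) != 1L)
    stop("ragged alignment: sequence lengths ", paste(len, collapse = ", "))
  chars <- unique(strsplit(paste(sequences, collapse = ""), "")[[1]])
  bad <- setdiff(chars, IUPAC_DNA)
  if (length(bad))
    stop("illegal sequence characters: ", paste(bad, collapse = ", "))
  if (!is.null(group_labels)) {
    group_labels <- as.character(group_labels)
    if (length(group_labels) != length(ids))
      stop("one group label per sequence required")
  }
  structure(setNames(sequences, ids), group_labels = group_labels,
            class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  cat("Sequence set: ", length(x), " aligned sequences of length ",
      if (length(x)) nchar(x[[1]]) else 0, "\n", sep = "")
  invisible(x)
}

#' Read / write an aligned FASTA file
#'
#' Headers may carry a group label after a separator (`id|group` by
#' default); `read_fasta(write_fasta(x))` round-trips exactly.
#'
#' @param path FASTA file.
#' @param group_sep single character separating id and group in headers,
#'   or `NULL` to take the whole header as the id.
#' @return [sequence_set] for `read_fasta`; `path` for `write_fasta`.
#' @export
read_fasta <- function(path, group_sep = "|") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) stop("not a FASTA file: ", path)
  idx <- cumsum(hdr)
  headers <- sub("^>", "", trimws(lines[hdr]))
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(z) paste(z, collapse = ""), "")
  seqs <- gsub("[[:space:]]", "", seqs)
  groups <- NULL
  ids <- headers
  if (!is.null(group_sep) && any(grepl(group_sep, headers, fixed = TRUE))) {
    parts <- strsplit(headers, group_sep, fixed = TRUE)
    ids <- vapply(parts, `[`, "", 1L)
    groups <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, "")
  }
  sequence_set(ids, seqs, groups)
}

#' @rdname read_fasta
#' @param x a [sequence_set].
#' @param width line width for sequence wrapping.
#' @export
write_fasta <- function(x, path, group_sep = "|", width = 70L) {
  ids <- names(x)
  grp <- attr(x, "group_labels")
  hdr <- if (is.null(grp)) ids else
    ifelse(is.na(grp), ids, paste(ids, grp, sep = group_sep))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x)) {
    writeLines(paste0(">", hdr[i]), con)
    s <- x[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a rooted Newick tree
#'
#' Thin validated wrapper around [ape::read.tree()]: tip labels must be
#' unique and branch lengths present and nonnegative.
#'
#' @param path Newick file.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("unreadable Newick file: ", path)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(tree$edge.length < 0))
    stop("negative branch length")
  tree
}

#' Resolve polytomies into a bifurcating tree
#'
#' Multifurcations are broken with zero-length internal branches, so the
#' total tree length and all patristic distances are unchanged. The
#' default mode is deterministic (ladderized in input order); random
#' resolution is available with a seed.
#'
#' @param tree an [ape::phylo] tree.
#' @param mode `"zero_branch_ladder"` (deterministic) or
#'   `"zero_branch_random"`.
#' @param seed integer seed, required for random mode.
#' @return A strictly bifurcating [ape::phylo] tree.
#' @export
resolve_polytomies <- function(tree,
                               mode = c("zero_branch_ladder",
                                        "zero_branch_random"),
                               seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "zero_branch_random") {
    if (is.null(seed)) stop("random resolution requires a seed")
    set.seed(seed)
    out <- ape::multi2di(tree, random = TRUE)
  } else {
    out <- ape::multi2di(tree, random = FALSE)
  }
  out
}

#' Georeferenced specimen coordinates
#'
#' @param ids unique identifiers.
#' @param lat,lon latitude / longitude in decimal degrees.
#' @return A `data.frame` of class `geo_points` with columns `id`, `lat`,
#'   `lon`.
#' @export
geo_points <- function(ids, lat, lon) {
  ids <- as.character(ids)
  lat <- as.numeric(lat); lon <- as.numeric(lon)
  if (anyDuplicated(ids)) stop("duplicate point ids")
  if (length(lat) != length(ids) || length(lon) != length(ids))
    stop("ids, lat, lon must have equal length")
  if (anyNA(lat) || any(lat < -90 | lat > 90))
    stop("latitude out of [-90, 90]")
  if (anyNA(lon) || any(lon < -180 | lon > 180))
    stop("longitude out of [-180, 180]")
  structure(data.frame(id = ids, lat = lat, lon = lon,
                       stringsAsFactors = FALSE),
            class = c("geo_points", "data.frame"))
}

#' Read GPS coordinates from CSV
#' @param path CSV with columns `id`, `lat`, `lon` (header required).
#' @return A [geo_points] data frame.
#' @export
read_geo_points <- function(path) {
  df <- read.csv(path, strip.white = TRUE)
  need <- c("id", "lat", "lon")
  if (!all(need %in% names(df)))
    stop("expected columns id, lat, lon in ", path)
  geo_points(df$id, df$lat, df$lon)
}

#' Tip-to-area range assignments
#'
#' @param ids tree tip identifiers.
#' @param ranges list of character vectors of area codes, one per tip.
#' @param areas declared ordered area universe.
#' @return A named list of class `tip_ranges` with attribute `areas`.
#' @export
tip_ranges <- function(ids, ranges, areas) {
  ids <- as.character(ids)
  areas <- as.character(areas)
  if (anyDuplicated(ids)) stop("duplicate tip ids")
  if (anyDuplicated(areas)) stop("duplicate area codes")
  ranges <- lapply(ranges, as.character)
  if (length(ranges) != length(ids)) stop("one range per tip required")
  for (i in seq_along(ranges)) {
    r <- ranges[[i]]
    if (!length(r)) stop("empty range for tip ", ids[i])
    bad <- setdiff(r, areas)
    if (length(bad))
      stop("tip ", ids[i], " uses undeclared areas: ",
           paste(bad, collapse = ", "))
    ranges[[i]] <- sort(unique(r))
  }
  structure(setNames(ranges, ids), areas = areas, class = "tip_ranges")
}

#' Read tip ranges from TSV
#' @param path TSV with columns `tip_id` and `areas` (comma-separated
#'   area codes).
#' @param areas declared area universe.
#' @return A [tip_ranges] object.
#' @export
read_tip_ranges <- function(path, areas) {
  df <- read.delim(path, strip.white = TRUE)
  if (!all(c("tip_id", "areas") %in% names(df)))
    stop("expected columns tip_id, areas in ", path)
  tip_ranges(df$tip_id, strsplit(as.character(df$areas), ","), areas)
}

#' @rdname read_tip_ranges
#' @param x a [tip_ranges] object.
#' @export
write_tip_ranges <- function(x, path) {
  df <- data.frame(tip_id = names(x),
                   areas = vapply(x, paste, "", collapse = ","))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Shared validator for labeled symmetric distance matrices.
check_distance_matrix <- function(D, allow_na = FALSE) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("distance matrix must be square")
  if (is.null(rownames(D))) stop("distance matrix must be labeled")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8,
                        check.attributes = FALSE)))
    stop("distance matrix must be symmetric")
  if (!allow_na && anyNA(D)) stop("distance matrix has missing entries")
  if (any(diag(D) != 0)) stop("distance matrix diagonal must be zero")
  if (any(D < 0, na.rm = TRUE)) stop("distances must be nonnegative")
  invisible(D)
}
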
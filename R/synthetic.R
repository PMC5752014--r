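# One global seed fans out to independent per-stream child seeds so each
# data modality can be regenerated on its own.
child_seeds <- function(seed, n = 6L) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate a pure-birth (Yule) tree with a fixed number of tips
#'
#' Lineages split at total rate `birth * k`; after the n-th lineage
#' appears, a final exponential stretch separates the last split from
#' the present, so the expected root-to-tip depth is
#' `sum(1 / (birth * k))` for `k = 2..n`. Branch lengths are in
#' expected-substitution units when `birth` is interpreted per unit
#' substitution time.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth per-lineage speciation rate.
#' @param seed integer seed.
#' @return An [ape::phylo] tree with tips `t1..tn`.
#' @export
simulate_tree <- function(n_tips, birth = 1, seed = NULL) {
  if (n_tips < 2) stop("need at least 2 tips")
  if (!is.null(seed)) set.seed(seed)
  # grow a lineage list; each lineage has a birth time
  n_nodes <- 2L * n_tips - 1L
  parent <- integer(n_nodes)
  btime <- numeric(n_nodes)                # time the lineage started
  root <- n_tips + 1L
  next_internal <- root + 1L
  next_tip <- 1L
  # active lineages carry provisional ids; internal ids assigned on split
  active <- c(-1L, -2L)                    # two root children
  prov_parent <- c(root, root)
  prov_start <- c(0, 0)
  t_now <- 0
  edges <- list(); lens <- numeric(0)
  prov <- data.frame(parent = prov_parent, start = prov_start)
  k <- 2L
  while (k < n_tips) {
    t_now <- t_now + rexp(1, birth * k)
    i <- sample.int(k, 1L)
    # lineage i becomes internal node
    node <- next_internal; next_internal <- next_internal + 1L
    edges[[length(edges) + 1L]] <- c(prov$parent[i], node)
    lens <- c(lens, t_now - prov$start[i])
    prov <- rbind(prov[-i, , drop = FALSE],
                  data.frame(parent = c(node, node), start = c(t_now, t_now)))
    k <- k + 1L
  }
  t_end <- t_now + rexp(1, birth * k)
  for (i in seq_len(nrow(prov))) {
    tip <- next_tip; next_tip <- next_tip + 1L
    edges[[length(edges) + 1L]] <- c(prov$parent[i], tip)
    lens <- c(lens, t_end - prov$start[i])
  }
  edge <- do.call(rbind, edges)
  tree <- list(edge = edge, edge.length = lens,
               tip.label = paste0("t", seq_len(n_tips)),
               Nnode = n_tips - 1L)
  class(tree) <- "phylo"
  stats::reorder(tree, "cladewise")
}

# K80 transition-probability matrix for branch length t (expected
# substitutions per site), transition/transversion rate ratio kappa.
# Rates scaled so the total substitution rate is 1.
k80_pmatrix <- function(t, kappa) {
  a <- kappa / (kappa + 2)                  # transition rate
  b <- 1 / (kappa + 2)                      # each transversion rate
  e1 <- exp(-4 * b * t)
  e2 <- exp(-2 * (a + b) * t)
  p_same <- 0.25 + 0.25 * e1 + 0.5 * e2
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e1
  # order A, C, G, T; transitions A<->G, C<->T
  M <- matrix(p_tv, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T")))
  diag(M) <- p_same
  M["A", "G"] <- M["G", "A"] <- M["C", "T"] <- M["T", "C"] <- p_ts
  M
}

#' Simulate aligned sequences under the two-parameter substitution model
#'
#' Sites evolve independently along the tree under the Kimura
#' two-parameter process (equal base frequencies; transition rate
#' `kappa` times each transversion rate), so the K2P distance is the
#' correct estimator for these data by construction.
#'
#' @param tree [ape::phylo] tree with branch lengths in expected
#'   substitutions per site (at `rate = 1`).
#' @param length alignment width in sites.
#' @param kappa transition/transversion rate ratio.
#' @param rate rate multiplier applied to every branch.
#' @param seed integer seed.
#' @param group_labels optional label per tip (recycled to the tip
#'   order).
#' @return A [sequence_set] with one sequence per tip.
#' @export
simulate_sequences <- function(tree, length = 889, kappa = 4, rate = 1,
                               seed = NULL, group_labels = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  nt <- base::length(tree$tip.label)
  nn <- tree$Nnode
  states <- matrix(0L, nt + nn, length)
  root <- nt + 1L
  states[root, ] <- sample.int(4L, length, replace = TRUE)
  edge <- stats::reorder(tree, "cladewise")$edge
  elen <- stats::reorder(tree, "cladewise")$edge.length
  for (i in seq_len(nrow(edge))) {
    par <- edge[i, 1]; child <- edge[i, 2]
    P <- k80_pmatrix(elen[i] * rate, kappa)
    s <- states[par, ]
    new <- s
    for (b in 1:4) {
      at <- which(s == b)
      if (base::length(at))
        new[at] <- sample.int(4L, base::length(at), replace = TRUE,
                              prob = P[b, ])
    }
    states[child, ] <- new
  }
  seqs <- apply(states[seq_len(nt), , drop = FALSE], 1, function(z)
    paste(bases[z], collapse = ""))
  sequence_set(tree$tip.label, seqs, group_labels)
}

#' Simulate a group-structured morphometric table
#'
#' Morphometric variables follow allometric scaling on standard length:
#' `value = slope[pop, var] * SL * exp(noise)` with population-specific
#' slopes and log-normal noise. Meristic counts are Gaussian around
#' population means, rounded to the half-integer grid. Cells (except SL)
#' are set missing completely at random; specimens below the juvenile
#' cutoff can be included to exercise filtering.
#'
#' @param n_pop number of populations.
#' @param n_per_pop specimens per population.
#' @param n_morpho,n_meristic numbers of morphometric / meristic
#'   variables.
#' @param sl_range uniform range of adult standard lengths (mm).
#' @param effect_sd log-scale SD of between-population slope/mean
#'   differences (0 gives identical populations).
#' @param noise_sd log-scale SD of within-population morphometric noise.
#' @param meristic_sd within-population SD of meristic counts.
#' @param missing_rate probability a non-SL cell is missing.
#' @param juvenile_frac fraction of extra specimens drawn below 20 mm SL.
#' @param sl_by_pop draw one standard length per population instead of
#'   per specimen (with zero noise SDs this makes specimens within a
#'   population identical).
#' @param slope,count_mean optional population x variable matrices of
#'   allometric slopes / meristic means overriding the random draw (used
#'   to impose tree-structured divergence between populations).
#' @param seed integer seed.
#' @return A [morpho_table]; attribute `truth` records generating
#'   parameters and the ids of juveniles.
#' @export
simulate_morpho <- function(n_pop = 3, n_per_pop = 10, n_morpho = 8,
                            n_meristic = 4, sl_range = c(30, 120),
                            effect_sd = 0.15, noise_sd = 0.03,
                            meristic_sd = 1, missing_rate = 0.02,
                            juvenile_frac = 0, sl_by_pop = FALSE,
                            slope = NULL, count_mean = NULL,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pops <- sprintf("pop%02d", seq_len(n_pop))
  pop_sl <- runif(n_pop, sl_range[1], sl_range[2])
  if (is.null(slope)) {
    base_slope <- runif(n_morpho, 0.1, 0.8)
    slope <- outer(rep(1, n_pop), base_slope) *
      exp(matrix(rnorm(n_pop * n_morpho, 0, effect_sd), n_pop))
  }
  if (is.null(count_mean)) {
    base_count <- sample(5:30, n_meristic, replace = TRUE)
    count_mean <- outer(rep(1, n_pop), base_count) *
      exp(matrix(rnorm(n_pop * n_meristic, 0, effect_sd), n_pop))
  }
  cmean <- count_mean
  stopifnot(nrow(slope) == n_pop, ncol(slope) == n_morpho,
            nrow(cmean) == n_pop, ncol(cmean) == n_meristic)
  n_juv <- round(n_pop * n_per_pop * juvenile_frac)
  rows <- list(); grp <- character(0)
  mk_row <- function(p, sl) {
    m <- slope[p, ] * sl * exp(rnorm(n_morpho, 0, noise_sd))
    cnt <- round(2 * rnorm(n_meristic, cmean[p, ], meristic_sd)) / 2
    cnt <- pmax(cnt, 0)
    c(sl, m, cnt)
  }
  for (p in seq_len(n_pop)) for (i in seq_len(n_per_pop)) {
    sl <- if (sl_by_pop) pop_sl[p] else runif(1, sl_range[1], sl_range[2])
    rows[[length(rows) + 1L]] <- mk_row(p, sl)
    grp <- c(grp, pops[p])
  }
  juv_ids <- character(0)
  if (n_juv > 0) for (i in seq_len(n_juv)) {
    p <- sample.int(n_pop, 1)
    rows[[length(rows) + 1L]] <- mk_row(p, runif(1, 5, 19.99))
    grp <- c(grp, pops[p])
  }
  vals <- do.call(rbind, rows)
  colnames(vals) <- c("SL", sprintf("M%02d", seq_len(n_morpho)),
                      sprintf("C%02d", seq_len(n_meristic)))
  ids <- sprintf("sp%03d", seq_len(nrow(vals)))
  if (n_juv > 0) juv_ids <- ids[(n_pop * n_per_pop + 1):nrow(vals)]
  if (missing_rate > 0) {
    cells <- which(matrix(runif(nrow(vals) * (ncol(vals) - 1)),
                          nrow(vals)) < missing_rate, arr.ind = TRUE)
    if (nrow(cells)) vals[cbind(cells[, 1], cells[, 2] + 1L)] <- NA
  }
  kinds <- c("SL", rep("morphometric_SL", n_morpho),
             rep("meristic", n_meristic))
  out <- morpho_table(vals, ids, grp, kinds)
  attr(out, "truth") <- list(slope = slope, count_mean = cmean,
                             effect_sd = effect_sd, noise_sd = noise_sd,
                             missing_rate = missing_rate,
                             juvenile_ids = juv_ids)
  out
}

#' Simulate per-basin clustered GPS coordinates
#'
#' Each population is assigned a basin centroid; specimens are jittered
#' around it with Gaussian noise.
#'
#' @param ids specimen ids.
#' @param pops population label per id.
#' @param centroid_lat,centroid_lon optional named vectors of population
#'   centroids (decimal degrees); drawn uniformly in a Guiana-Shield-like
#'   window when absent.
#' @param jitter_sd SD of the coordinate jitter in degrees.
#' @param seed integer seed.
#' @return A [geo_points] data frame; attribute `centroids` records the
#'   generating centroids.
#' @export
simulate_geo <- function(ids, pops, centroid_lat = NULL,
                         centroid_lon = NULL, jitter_sd = 0.05,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  up <- sort(unique(pops))
  if (is.null(centroid_lat))
    centroid_lat <- setNames(runif(length(up), 2, 6), up)
  if (is.null(centroid_lon))
    centroid_lon <- setNames(runif(length(up), -58, -52), up)
  lat <- centroid_lat[pops] + rnorm(length(ids), 0, jitter_sd)
  lon <- centroid_lon[pops] + rnorm(length(ids), 0, jitter_sd)
  out <- geo_points(ids, pmin(pmax(lat, -90), 90),
                    pmin(pmax(lon, -180), 180))
  attr(out, "centroids") <- data.frame(pop = up,
                                       lat = unname(centroid_lat[up]),
                                       lon = unname(centroid_lon[up]))
  out
}

#' Forward simulation of geographic ranges under DEC / DEC+j
#'
#' The root range is drawn from the uniform non-null prior; ranges then
#' evolve by Gillespie simulation of the anagenetic generator along
#' branches, and split at nodes according to [clado_event_weights()].
#' Simulations in which any lineage goes globally extinct (null range)
#' are redrawn, up to `max_tries` attempts.
#'
#' @param tree bifurcating [ape::phylo] tree.
#' @param space a [build_state_space()] object.
#' @param d,e,j generating parameters.
#' @param seed integer seed.
#' @param max_tries redraw budget for extinction-free simulations.
#' @return A [tip_ranges] object; attribute `node_states` holds the true
#'   state index at every node.
#' @export
simulate_ranges <- function(tree, space, d, e, j = 0, seed = NULL,
                            max_tries = 100) {
  if (!is.null(seed)) set.seed(seed)
  if (!ape::is.binary(tree)) stop("tree must be bifurcating")
  Q <- build_rate_matrix(space, d, e)
  S <- length(space$states)
  clado <- vector("list", S)
  for (s in 2:S)
    clado[[s]] <- clado_event_weights(space, space$states[[s]], j)
  nt <- length(tree$tip.label)
  edge <- tree$edge
  elen <- tree$edge.length
  children <- split(seq_len(nrow(edge)), edge[, 1])
  evolve <- function(s0, t) {
    s <- s0; left <- t
    repeat {
      rate <- -Q[s, s]
      if (rate <= 0) return(s)
      w <- rexp(1, rate)
      if (w > left) return(s)
      left <- left - w
      p <- Q[s, ]; p[s] <- 0
      s <- sample.int(S, 1, prob = p)
    }
  }
  for (try in seq_len(max_tries)) {
    states <- integer(nt + tree$Nnode)
    root <- nt + 1L
    states[root] <- sample(2:S, 1)
    ok <- TRUE
    # preorder (ancestors first) = reversed postorder of parent nodes
    ord <- rev(unique(rev(stats::reorder(tree, "postorder")$edge[, 1])))
    for (v in rev(ord)) {
      s <- states[v]
      if (s <= 1) { ok <- FALSE; break }
      cw <- clado[[s]]
      pick <- sample.int(nrow(cw), 1, prob = cw$prob)
      ce <- children[[as.character(v)]]
      starts <- c(cw$left[pick], cw$right[pick])
      for (ci in 1:2) {
        sc <- evolve(starts[ci], elen[ce[ci]])
        if (sc <= 1) { ok <- FALSE; break }
        states[edge[ce[ci], 2]] <- sc
      }
      if (!ok) break
    }
    if (ok) {
      ranges <- lapply(seq_len(nt), function(i)
        space$areas[space$states[[states[i]]]])
      out <- tip_ranges(tree$tip.label, ranges, space$areas)
      attr(out, "node_states") <- states
      attr(out, "tries") <- try
      return(out)
    }
  }
  stop("no extinction-free range history in ", max_tries, " tries; ",
       "extirpation rate too high for this tree")
}

#' Generate a coherent three-species synthetic study
#'
#' Builds one multi-modal dataset with known ground truth: a Yule tree
#' whose tips fall into three well-separated species clades (attained by
#' stretching the two inter-species stem branches), K2P-compatible
#' sequences, an allometric morphometric table with group structure,
#' basin-clustered coordinates, and DEC-simulated tip ranges.
#'
#' @param n_per_species tips per species (default 8).
#' @param seed global seed; child seeds are derived per data stream.
#' @param dir optional directory; when given, writes `morpho.csv`,
#'   `seqs.fasta`, `tree.nwk`, `gps.csv`, `ranges.tsv` and `truth.json`.
#' @param species_depth extra branch length added to each species stem
#'   (substitutions/site) controlling between-species divergence.
#' @param n_sites alignment width.
#' @param dec_params generating `(d, e, j)` for tip ranges.
#' @return List of class `synthetic_study`: `tree`, `sequences`,
#'   `morpho`, `gps`, `ranges`, `space`, `truth`.
#' @export
simulate_study <- function(n_per_species = 8, seed = 42, dir = NULL,
                           species_depth = 0.08, n_sites = 889,
                           dec_params = c(d = 0.3, e = 0.05, j = 0)) {
  seeds <- child_seeds(seed, 6L)
  n_sp <- 3L
  n <- n_sp * n_per_species
  # species subtrees grafted on a 3-taxon backbone
  set.seed(seeds[1])
  # fast within-species branching: intraspecific divergence stays well
  # below the interspecific stem depth, giving a clean barcode gap
  subs <- lapply(seq_len(n_sp), function(i)
    simulate_tree(n_per_species, birth = 100))
  backbone <- ape::read.tree(text = sprintf(
    "((s1:%f,s2:%f):%f,s3:%f);",
    species_depth, species_depth, species_depth / 2, 1.5 * species_depth))
  tree <- backbone
  for (i in seq_len(n_sp)) {
    subs[[i]]$tip.label <- sprintf("sp%d_%02d", i, seq_len(n_per_species))
    tree <- ape::bind.tree(tree, subs[[i]],
                           where = which(tree$tip.label == paste0("s", i)))
  }
  species <- sub("_.*", "", tree$tip.label)
  seqs <- simulate_sequences(tree, length = n_sites, kappa = 4,
                             seed = seeds[2], group_labels = species)
  # population means diverge along the species tree (Brownian-style:
  # the sister pair s1, s2 shares an ancestral deviation, s3 evolves
  # independently), so morphology carries the phylogenetic signal the
  # multi-table analysis is meant to detect
  set.seed(seeds[3])
  bm_effects <- function(n_var, s_shared = 0.15, s_tip = 0.08,
                         s_out = 0.2) {
    anc <- rnorm(n_var, 0, s_shared)
    rbind(anc + rnorm(n_var, 0, s_tip),
          anc + rnorm(n_var, 0, s_tip),
          rnorm(n_var, 0, s_out))
  }
  n_morpho <- 8; n_meristic <- 4
  slope <- outer(rep(1, n_sp), runif(n_morpho, 0.1, 0.8)) *
    exp(bm_effects(n_morpho))
  cmean <- outer(rep(1, n_sp), sample(5:30, n_meristic, replace = TRUE)) *
    exp(bm_effects(n_meristic))
  morpho <- simulate_morpho(n_pop = n_sp, n_per_pop = n_per_species,
                            n_morpho = n_morpho, n_meristic = n_meristic,
                            noise_sd = 0.03, missing_rate = 0.02,
                            slope = slope, count_mean = cmean,
                            seed = seeds[6])
  # align morpho rows to tree tips: population i's block of rows is
  # assigned to the tips of species i, in tip-label order
  ids_by_species <- unlist(lapply(seq_len(n_sp), function(i)
    tree$tip.label[species == paste0("sp", i)]))
  morpho <- morpho_table(unclass(morpho), ids_by_species,
                         sub("_.*", "", ids_by_species), kinds_of(morpho))
  # coastal-basin allopatry: species occupy adjacent basins along a
  # west-to-east gradient, sister species (s1, s2) in neighboring basins,
  # so geography tracks phylogeny as it does in riverine radiations
  gps <- simulate_geo(names(seqs), species,
                      centroid_lat = c(sp1 = 4.2, sp2 = 4.8, sp3 = 3.9),
                      centroid_lon = c(sp1 = -57, sp2 = -55.5, sp3 = -52.5),
                      jitter_sd = 0.05, seed = seeds[4])
  space <- build_state_space(LETTERS[1:5], 5)
  rng <- simulate_ranges(tree, space, dec_params[["d"]],
                         dec_params[["e"]],
                         if (length(dec_params) > 2) dec_params[["j"]] else 0,
                         seed = seeds[5])
  truth <- list(seed = seed, child_seeds = seeds, species = species,
                n_per_species = n_per_species,
                species_depth = species_depth,
                dec_params = as.list(dec_params))
  out <- structure(list(tree = tree, sequences = seqs, morpho = morpho,
                        gps = gps, ranges = rng, space = space,
                        truth = truth),
                   class = "synthetic_study")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ape::write.tree(tree, file.path(dir, "tree.nwk"))
    write_fasta(seqs, file.path(dir, "seqs.fasta"))
    write_morpho_table(morpho, file.path(dir, "morpho.csv"))
    write.csv(gps, file.path(dir, "gps.csv"), row.names = FALSE,
              quote = FALSE)
    write_tip_ranges(rng, file.path(dir, "ranges.tsv"))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic study:", length(x$tree$tip.label), "specimens,",
      length(unique(x$truth$species)), "species\n")
  invisible(x)
}
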
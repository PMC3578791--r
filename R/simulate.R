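# Synthetic trees and alignments with the statistical structure the
# analysis assumes: Yule (pure-birth) trees, a time warp controlling the
# tempo of cladogenesis (and hence the sign of gamma), Jukes-Cantor
# sequence evolution with region-specific rate multipliers, and a
# multi-group fixture of monophyletic clades attached by trunk branches.

#' Simulate a Yule (pure-birth) tree
#'
#' Grows an ultrametric binary tree under a constant birth rate: the
#' duration with `j` lineages is exponential with rate `j * birth_rate`,
#' and the lineage that splits is chosen uniformly. This is the
#' constant-rate null under which the gamma statistic is approximately
#' standard normal.
#'
#' @param n_tips Number of tips (`>= 2`).
#' @param birth_rate Births per lineage per unit time (default 1).
#' @param seed Optional integer seed (`set.seed()` at entry).
#' @return An ultrametric [structured_tree()] with tips `t1..tn`.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  if (n_tips < 2L)
    stop("n_tips must be >= 2", call. = FALSE)
  if (birth_rate <= 0)
    stop("birth_rate must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_tips)
  g <- stats::rexp(n - 1L, rate = (2:n) * birth_rate)
  t_event <- cumsum(c(0, g[-(n - 1L)]))   # time of the j-th split
  T0 <- sum(g)
  # grow forward in time; internal ids n+1 .. 2n-1 in order of creation
  n_edges <- 2L * n - 2L
  edge <- matrix(0L, n_edges, 2L)
  elen <- numeric(n_edges)
  parent <- c(n + 1L, n + 1L)             # active lineages' parent node
  start <- c(0, 0)                        # and their birth times
  n_edge_used <- 0L
  next_node <- n + 2L
  if (n > 2L) {
    for (k in 2:(n - 1L)) {
      i <- sample.int(length(parent), 1L)
      n_edge_used <- n_edge_used + 1L
      edge[n_edge_used, ] <- c(parent[i], next_node)
      elen[n_edge_used] <- t_event[k] - start[i]
      parent <- c(parent[-i], next_node, next_node)
      start <- c(start[-i], t_event[k], t_event[k])
      next_node <- next_node + 1L
    }
  }
  for (i in seq_along(parent)) {
    n_edge_used <- n_edge_used + 1L
    edge[n_edge_used, ] <- c(parent[i], i)
    elen[n_edge_used] <- T0 - start[i]
  }
  tree <- structure(
    list(edge = edge, edge.length = elen, Nnode = n - 1L,
         tip.label = paste0("t", seq_len(n))),
    class = "phylo", order = "cladewise"
  )
  tree <- ape::reorder.phylo(tree, "cladewise")
  structured_tree(tree)
}

#' Warp the node ages of an ultrametric tree
#'
#' Rescales node ages `a` (as fractions of the root age, measured from
#' the present) to `a^beta` and recomputes branch lengths. `beta > 1`
#' pushes branchings toward the present (late cladogenesis, gamma > 0 in
#' expectation); `beta < 1` toward the root (early cladogenesis,
#' gamma < 0); `beta = 1` is the identity. Topology, tip set, and total
#' depth are preserved, and the output remains ultrametric.
#'
#' @param st An ultrametric `structured_tree`.
#' @param beta Positive warp exponent.
#' @return The warped `structured_tree`.
#' @export
warp_tree_times <- function(st, beta) {
  if (beta <= 0)
    stop("beta must be > 0", call. = FALSE)
  tree <- st$tree
  n <- ape::Ntip(tree)
  depth <- node_depths(tree)
  T0 <- max(depth[seq_len(n)])
  h <- (T0 - depth) / T0                  # relative age in [0, 1]
  h[seq_len(n)] <- 0
  h_new <- T0 * h^beta
  out <- tree
  out$edge.length <- h_new[tree$edge[, 1L]] - h_new[tree$edge[, 2L]]
  structured_tree(out, st$groups)
}

# validate region list: list of list(name, span = c(s, e), multiplier)
check_regions <- function(regions, seq_length) {
  if (is.null(regions)) return(invisible(NULL))
  covered <- integer(0)
  for (r in regions) {
    if (is.null(r$span) || length(r$span) != 2L || r$span[1L] > r$span[2L])
      stop("region span must be c(start, end) with start <= end",
           call. = FALSE)
    if (r$span[1L] < 1L || r$span[2L] > seq_length)
      stop("region span outside [1, ", seq_length, "]", call. = FALSE)
    cols <- r$span[1L]:r$span[2L]
    if (length(intersect(covered, cols)))
      stop("region spans overlap", call. = FALSE)
    covered <- c(covered, cols)
    if (is.null(r$multiplier) || r$multiplier < 0)
      stop("region multiplier must be >= 0", call. = FALSE)
  }
  invisible(NULL)
}

#' Evolve sequences along a tree under Jukes-Cantor
#'
#' Simulates a gap-free alignment down the tree: the root sequence is
#' uniform over A/C/G/T and every site evolves independently under the
#' Jukes-Cantor model at rate `base_rate` times the multiplier of the
#' region containing it (1 outside all regions). Branch lengths are in
#' time units, so the expected distance between two tips is
#' `rate * path length`.
#'
#' @param st A `structured_tree` (or `phylo`).
#' @param seq_length Number of alignment columns.
#' @param base_rate Substitutions/site/time outside regions.
#' @param regions Optional list of regions, each a list with `name`,
#'   `span = c(start, end)` (1-based inclusive columns, disjoint), and
#'   `multiplier`.
#' @param group_id Label for the returned alignment.
#' @param seed Optional integer seed.
#' @return A [group_alignment()] with the regions annotated in its
#'   `region_map`.
#' @export
evolve_sequences <- function(st, seq_length, base_rate, regions = NULL,
                             group_id = "sim", seed = NULL) {
  tree <- if (inherits(st, "structured_tree")) st$tree else st
  if (base_rate < 0)
    stop("base_rate must be >= 0", call. = FALSE)
  check_regions(regions, seq_length)
  if (!is.null(seed)) set.seed(seed)
  # split the columns into maximal segments of constant rate
  mult <- rep(1, seq_length)
  for (r in regions) mult[r$span[1L]:r$span[2L]] <- r$multiplier
  breaks <- c(0, which(diff(mult) != 0), seq_length)
  seg_chunks <- vector("list", length(breaks) - 1L)
  for (s in seq_len(length(breaks) - 1L)) {
    cols <- (breaks[s] + 1L):breaks[s + 1L]
    rate <- base_rate * mult[cols[1L]]
    if (rate == 0) {
      base <- sample(c("a", "c", "g", "t"), length(cols), replace = TRUE)
      chunk <- matrix(rep(base, each = ape::Ntip(tree)),
                      nrow = ape::Ntip(tree))
      rownames(chunk) <- tree$tip.label
    } else {
      sim <- phangorn::simSeq(tree, l = length(cols), rate = rate)
      chunk <- as.character(sim)
    }
    seg_chunks[[s]] <- chunk[tree$tip.label, , drop = FALSE]
  }
  m <- do.call(cbind, seg_chunks)
  rows <- toupper(apply(m, 1L, paste, collapse = ""))
  region_map <- NULL
  if (!is.null(regions)) {
    region_map <- lapply(regions, function(r) as.integer(r$span))
    names(region_map) <- vapply(regions, function(r)
      if (is.null(r$name)) "region" else r$name, character(1))
  }
  group_alignment(rows, tree$tip.label, group_id = group_id,
                  region_map = region_map)
}

#' Simulation configuration
#'
#' Collects the knobs of the synthetic-data generator. Defaults emulate
#' the shape of the study data: a ~1800-column full gene with an
#' embedded ~520-column V4-V5-like region evolving 1.4 times faster and
#' a short ~160-column V9-like region at the same elevated rate, and a
#' multi-group layout of monophyletic clades on trunk branches.
#'
#' @param seed Integer master seed.
#' @param n_tips Tips for single-tree simulations (default 50).
#' @param birth_rate Yule birth rate (default 1).
#' @param warp_beta Cladogenesis-tempo exponent (default 1, constant
#'   rate).
#' @param seq_length Alignment columns (default 1800).
#' @param base_rate Substitutions/site/time (default 0.05).
#' @param regions Region list as in [evolve_sequences()]; default
#'   V4V5 = columns 601-1120 at 1.4x and V9 = columns 1630-1789 at 1.4x.
#' @param group_layout Data frame with columns `group_id`, `n_tips`,
#'   `trunk_length`, and optionally `beta` (per-group tempo) and `depth`
#'   (rescaled subtree depth); default five groups of 40/25/15/10/10
#'   tips.
#' @param backbone_length Internal backbone branch length joining
#'   successive groups (default 0.2).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_tips = 50L, birth_rate = 1,
                       warp_beta = 1, seq_length = 1800L,
                       base_rate = 0.05,
                       regions = list(
                         list(name = "V4V5", span = c(601L, 1120L),
                              multiplier = 1.4),
                         list(name = "V9", span = c(1630L, 1789L),
                              multiplier = 1.4)
                       ),
                       group_layout = data.frame(
                         group_id = paste0("G", 1:5),
                         n_tips = c(40L, 25L, 15L, 10L, 10L),
                         trunk_length = c(0.3, 0.5, 0.7, 0.4, 0.6),
                         beta = c(1 / 3, 1, 3, 1, 1)
                       ),
                       backbone_length = 0.2) {
  check_regions(regions, seq_length)
  if (warp_beta <= 0) stop("warp_beta must be > 0", call. = FALSE)
  if (anyDuplicated(group_layout$group_id))
    stop("duplicate group ids in group_layout", call. = FALSE)
  structure(
    list(seed = as.integer(seed), n_tips = as.integer(n_tips),
         birth_rate = birth_rate, warp_beta = warp_beta,
         seq_length = as.integer(seq_length), base_rate = base_rate,
         regions = regions, group_layout = group_layout,
         backbone_length = backbone_length),
    class = "sim_config"
  )
}

#' Build a multi-group tree + alignment fixture
#'
#' Simulates one Yule subtree per group (optionally time-warped and
#' depth-rescaled), relabels its tips `<group>_t<i>`, and attaches the
#' groups by their configured trunk (stem) branches to a ladder
#' backbone, so every group is monophyletic by construction and
#' [trunk_length()] recovers the configured stems exactly. Sequences are
#' then evolved per group along each (unwarped-length) subtree.
#'
#' @param config A [sim_config()] with `>= 2` groups in `group_layout`.
#' @return List with `tree` (a [structured_tree()] with the tip-group
#'   map), `alignments` (named list of [group_alignment()]s), and
#'   `config`.
#' @export
build_supergroup_fixture <- function(config) {
  layout <- config$group_layout
  if (nrow(layout) < 2L)
    stop("group_layout needs at least 2 groups", call. = FALSE)
  set.seed(config$seed)
  subtrees <- vector("list", nrow(layout))
  alignments <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    gid <- layout$group_id[i]
    st <- simulate_yule_tree(layout$n_tips[i], config$birth_rate)
    beta <- if ("beta" %in% names(layout)) layout$beta[i] else 1
    if (beta != 1) st <- warp_tree_times(st, beta)
    if ("depth" %in% names(layout) && !is.na(layout$depth[i])) {
      depth_now <- max(node_depths(st$tree))
      st$tree$edge.length <-
        st$tree$edge.length * layout$depth[i] / depth_now
    }
    st$tree$tip.label <- paste0(gid, "_t", seq_len(ape::Ntip(st$tree)))
    subtrees[[i]] <- st$tree
    alignments[[i]] <- evolve_sequences(
      st, config$seq_length, config$base_rate, config$regions,
      group_id = gid
    )
  }
  names(alignments) <- layout$group_id
  nwk <- vapply(subtrees, function(tr)
    sub(";$", "", ape::write.tree(tr)), character(1))
  stem <- paste0(nwk, ":", format(layout$trunk_length, scientific = FALSE))
  combined <- paste0("(", stem[1L], ",", stem[2L], ")")
  if (nrow(layout) > 2L) {
    for (i in 3:nrow(layout))
      combined <- paste0("(", combined, ":",
                         format(config$backbone_length,
                                scientific = FALSE),
                         ",", stem[i], ")")
  }
  tree <- ape::read.tree(text = paste0(combined, ";"))
  groups <- stats::setNames(
    rep(layout$group_id, layout$n_tips),
    unlist(lapply(subtrees, `[[`, "tip.label"))
  )
  list(tree = structured_tree(tree, groups), alignments = alignments,
       config = config)
}

#' Write a fixture to disk
#'
#' Emits the newick tree, tip-group map TSV, one FASTA per group, and a
#' JSON copy of the configuration.
#'
#' @param fixture Result of [build_supergroup_fixture()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_newick(fixture$tree, file.path(dir, "tree.nwk"),
               file.path(dir, "tip_groups.tsv"))
  for (gid in names(fixture$alignments))
    write_alignment(fixture$alignments[[gid]],
                    file.path(dir, paste0(gid, ".fasta")))
  cfg <- unclass(fixture$config)
  cfg$group_layout <- as.list(fixture$config$group_layout)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
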
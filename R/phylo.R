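# Tree-shape statistics on rooted trees with branch lengths: mean-path-
# length ultrametricization, standardized lineage-through-time curves,
# the Pybus-Harvey gamma statistic with a one-tailed constant-rate test,
# mean phylogenetic distance (MPD), trunk lengths, and intergroup
# distance matrices.

#' Construct a structured tree
#'
#' A rooted `phylo` tree with non-negative branch lengths plus an
#' optional tip-to-group map.
#'
#' @param tree An [ape::read.tree()]-style `phylo` object.
#' @param groups Optional named character vector: `names` are tip labels,
#'   values are group ids. Every mapped tip must be in the tree.
#' @return Object of class `structured_tree`: list with `tree` and
#'   `groups`.
#' @export
structured_tree <- function(tree, groups = NULL) {
  if (!inherits(tree, "phylo"))
    stop("tree must be a 'phylo' object", call. = FALSE)
  if (ape::Ntip(tree) < 2L)
    stop("tree must have at least 2 tips", call. = FALSE)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree must have branch lengths on every edge", call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("negative branch lengths", call. = FALSE)
  # a basal multifurcation is accepted: the file's root is the root
  if (!is.null(groups)) {
    groups <- stats::setNames(as.character(groups), names(groups))
    absent <- setdiff(names(groups), tree$tip.label)
    if (length(absent))
      stop("group-map tip(s) absent from tree: ",
           paste(absent, collapse = ", "), call. = FALSE)
  }
  structure(list(tree = tree, groups = groups),
            class = "structured_tree")
}

#' @export
print.structured_tree <- function(x, ...) {
  cat("Structured tree: ", ape::Ntip(x$tree), " tips",
      if (!is.null(x$groups))
        paste0(", ", length(unique(x$groups)), " groups"),
      "\n", sep = "")
  invisible(x)
}

#' Read a newick tree (with optional tip-to-group map)
#'
#' @param path Newick file with branch lengths (missing lengths are an
#'   error).
#' @param group_map_path Optional TSV with columns `tip_name`,
#'   `group_id`.
#' @return A [structured_tree()].
#' @export
read_newick <- function(path, group_map_path = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree))
    stop("cannot parse newick file: ", path, call. = FALSE)
  if (is.null(tree$edge.length))
    stop("newick file has no branch lengths: ", path, call. = FALSE)
  groups <- NULL
  if (!is.null(group_map_path)) {
    tab <- utils::read.table(group_map_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    groups <- stats::setNames(tab$group_id, tab$tip_name)
  }
  structured_tree(tree, groups)
}

#' Write a structured tree (newick + group map TSV)
#'
#' @param st A `structured_tree`.
#' @param path Newick output path.
#' @param group_map_path Optional TSV output path for the tip-group map.
#' @return `path`, invisibly.
#' @export
write_newick <- function(st, path, group_map_path = NULL) {
  ape::write.tree(st$tree, file = path)
  if (!is.null(group_map_path) && !is.null(st$groups)) {
    utils::write.table(
      data.frame(tip_name = names(st$groups), group_id = st$groups),
      group_map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# Height of every node above the present (tips at their own depth);
# returns list(depth = from-root distances, root = root node id).
node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

#' Transform a tree to ultrametric by mean-path-length smoothing
#'
#' Sets each internal node's height above the present to the mean path
#' length from that node to its descendant tips, processed root-ward;
#' where a child's smoothed height would exceed its parent's, the child
#' is pulled down to the parent (clamping the connecting branch to 0), so
#' all branch lengths stay non-negative. Topology is unchanged and the
#' output has equal root-to-tip path lengths. Only relative node order
#' and times matter for the LTT and gamma analyses downstream, so this
#' deterministic, parameter-free smoothing is used rather than model-
#' based dating.
#'
#' @param st A `structured_tree`.
#' @return An ultrametric `structured_tree` with the same topology and
#'   group map.
#' @export
make_ultrametric <- function(st) {
  tree <- st$tree
  n <- ape::Ntip(tree)
  depth <- node_depths(tree)
  post <- ape::reorder.phylo(tree, "postorder")
  nn <- n + tree$Nnode
  tipsum <- numeric(nn)   # sum of from-root depths of descendant tips
  tipcnt <- integer(nn)
  tipsum[seq_len(n)] <- depth[seq_len(n)]
  tipcnt[seq_len(n)] <- 1L
  for (e in seq_len(nrow(post$edge))) {
    par <- post$edge[e, 1L]; ch <- post$edge[e, 2L]
    tipsum[par] <- tipsum[par] + tipsum[ch]
    tipcnt[par] <- tipcnt[par] + tipcnt[ch]
  }
  h <- numeric(nn)                      # smoothed height above present
  int <- (n + 1L):nn
  h[int] <- tipsum[int] / tipcnt[int] - depth[int]
  h[seq_len(n)] <- 0
  # re-monotonize root-ward: child height may not exceed parent height
  pre <- rev(seq_len(nrow(post$edge)))
  for (e in pre) {
    par <- post$edge[e, 1L]; ch <- post$edge[e, 2L]
    if (h[ch] > h[par]) h[ch] <- h[par]
  }
  out <- tree
  out$edge.length <- h[tree$edge[, 1L]] - h[tree$edge[, 2L]]
  structured_tree(out, st$groups)
}

#' Branching times of an ultrametric tree
#'
#' One time before present per internal node, sorted decreasing (root
#' first, equal to the tree depth). The tree must be ultrametric within
#' a relative tolerance.
#'
#' @param st An ultrametric `structured_tree`.
#' @param tol Relative ultrametricity tolerance (default `1e-6`).
#' @return Numeric vector of node heights, sorted decreasing.
#' @export
branching_times <- function(st, tol = 1e-6) {
  tree <- st$tree
  n <- ape::Ntip(tree)
  depth <- node_depths(tree)
  td <- depth[seq_len(n)]
  T0 <- max(td)
  if (T0 <= 0)
    stop("tree has zero depth", call. = FALSE)
  if (any(abs(td - T0) > tol * T0))
    stop("tree is not ultrametric within tolerance ", tol, call. = FALSE)
  sort(T0 - depth[(n + 1L):(n + tree$Nnode)], decreasing = TRUE)
}

#' Standardized lineage-through-time curve
#'
#' Maps branching times to relative time in `[-1, 0]` (-1 at the root,
#' the origin of the lineage; 0 at present) and lineage counts to
#' percentages of the number at present, so curves from groups of
#' different ages and sizes are comparable. The count starts at 2 at the
#' root and reaches 100% at time 0.
#'
#' @param st An ultrametric `structured_tree` with `>= 2` tips.
#' @return Object of class `ltt_curve`: list with `points` (data.frame
#'   `relative_time`, `lineage_percent`) and `n_tips`.
#' @export
ltt_curve <- function(st) {
  tree <- st$tree
  n <- ape::Ntip(tree)
  bt <- branching_times(st)
  T0 <- bt[1L]
  # lineage count after the event at each branching time; the root node
  # contributes its child count, later nodes add (children - 1)
  kids <- tabulate(tree$edge[, 1L], nbins = n + tree$Nnode)
  nodes <- (n + 1L):(n + tree$Nnode)
  heights <- T0 - node_depths(tree)[nodes]
  ord <- order(heights, decreasing = TRUE)
  inc <- kids[nodes][ord] - 1L
  counts <- 1L + cumsum(inc)            # root: 1 + (k_root - 1) = k_root
  rel <- -heights[ord] / T0
  pts <- data.frame(relative_time = c(rel, 0),
                    lineage_percent = 100 * c(counts, n) / n)
  structure(list(points = pts, n_tips = n), class = "ltt_curve")
}

#' Write an LTT curve as TSV
#' @param curve An `ltt_curve`.
#' @param path Output path (columns relative_time, lineage_percent).
#' @return `path`, invisibly.
#' @export
write_ltt_curve <- function(curve, path) {
  utils::write.table(curve$points, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Pybus-Harvey gamma statistic with one-tailed test
#'
#' Standardized summary of internode intervals of an ultrametric tree:
#' with `g_j` the duration during which the tree holds `j` lineages
#' (`j = 2..n`), `T_i = sum_{k=2..i} k*g_k` and `T = T_n`,
#' `gamma = (mean(T_2..T_{n-1}) - T/2) / (T * sqrt(1/(12(n-2))))`.
#' Under constant-rate pure-birth cladogenesis gamma is approximately
#' standard normal: negative values indicate early cladogenesis (concave
#' LTT), positive values late cladogenesis (convex LTT). The constant-
#' rate null is tested one-tailed in the direction of the observed sign.
#' Polytomies are resolved to binary with zero-length branches (logged);
#' gamma is invariant to the resolution order since the intervals are
#' unchanged.
#'
#' @param st An ultrametric `structured_tree` with `>= 3` tips.
#' @return Object of class `gamma_result`: list with `gamma`, `n_tips`,
#'   `p_one_tailed`, `g` (named internode intervals, `g_2..g_n`), `T`.
#' @export
gamma_statistic <- function(st) {
  tree <- st$tree
  n <- ape::Ntip(tree)
  if (n < 3L)
    stop("gamma statistic needs at least 3 tips", call. = FALSE)
  if (!ape::is.binary(tree)) {
    message("gamma_statistic: resolving polytomies with zero-length ",
            "branches")
    tree <- ape::multi2di(tree, random = FALSE)
  }
  bt <- branching_times(structured_tree(tree, NULL))
  g <- c(-diff(bt), bt[n - 1L])         # durations with 2..n lineages
  names(g) <- paste0("g", 2:n)
  j <- 2:n
  Ti <- unname(cumsum(j * g))
  T_total <- Ti[n - 1L]
  if (T_total <= 0)
    stop("degenerate tree: total weighted time is zero", call. = FALSE)
  gamma <- (mean(Ti[seq_len(n - 2L)]) - T_total / 2) /
    (T_total * sqrt(1 / (12 * (n - 2))))
  structure(
    list(gamma = gamma, n_tips = n,
         p_one_tailed = stats::pnorm(-abs(gamma)),
         g = g, T = T_total),
    class = "gamma_result"
  )
}

#' @export
print.gamma_result <- function(x, ...) {
  cat("gamma = ", formatC(x$gamma, format = "f", digits = 4), " (n = ",
      x$n_tips, ", one-tailed p = ",
      formatC(x$p_one_tailed, format = "g", digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Classify a gamma result against the constant-rate null
#'
#' @param g A `gamma_result`.
#' @param alpha One-tailed significance level (default 0.05).
#' @return `"negative"`, `"zero"`, or `"positive"`.
#' @export
classify_gamma <- function(g, alpha = 0.05) {
  if (g$p_one_tailed >= alpha) "zero"
  else if (g$gamma < 0) "negative"
  else "positive"
}

# tips belonging to one group; error when the map is missing
group_tips <- function(st, group) {
  if (is.null(st$groups))
    stop("tree has no tip-to-group map", call. = FALSE)
  tips <- names(st$groups)[st$groups == group]
  if (length(tips) == 0L)
    stop("no tips mapped to group '", group, "'", call. = FALSE)
  tips
}

#' Mean phylogenetic distance within a group
#'
#' Mean patristic distance (sum of branch lengths along the connecting
#' path) over all unordered tip pairs of one group.
#'
#' @param st A `structured_tree` with a group map.
#' @param group Group id with at least 2 tips.
#' @return Mean patristic distance.
#' @export
mpd <- function(st, group) {
  tips <- group_tips(st, group)
  if (length(tips) < 2L)
    stop("group '", group, "' has fewer than 2 tips", call. = FALSE)
  pd <- ape::cophenetic.phylo(st$tree)[tips, tips]
  mean(pd[upper.tri(pd)])
}

#' Trunk (stem) length of a monophyletic group
#'
#' Length of the branch subtending the group's most recent common
#' ancestor — the evolutionary time between the first appearance of the
#' group and its observed diversification. A single-tip group's trunk is
#' its terminal branch (degenerate clade, flagged via `message()`).
#'
#' @param st A `structured_tree` with a group map.
#' @param group Group id whose tips form a monophyletic clade.
#' @return Stem branch length.
#' @export
trunk_length <- function(st, group) {
  tree <- st$tree
  tips <- group_tips(st, group)
  if (length(tips) == 1L) {
    message("trunk_length: group '", group,
            "' has a single tip; using its terminal branch")
    node <- match(tips, tree$tip.label)
  } else {
    if (length(tips) == ape::Ntip(tree))
      stop("group '", group, "' spans the whole tree: no stem branch",
           call. = FALSE)
    if (!ape::is.monophyletic(tree, tips))
      stop("group '", group, "' is not monophyletic", call. = FALSE)
    node <- ape::getMRCA(tree, tips)
  }
  e <- which(tree$edge[, 2L] == node)
  if (length(e) != 1L)
    stop("group '", group, "' has no stem branch (MRCA is the root)",
         call. = FALSE)
  tree$edge.length[e]
}

#' Mean patristic distances between groups
#'
#' Entry (G, H) is the mean patristic distance over all tip pairs with
#' one tip in G and one in H (trunks included via the connecting path);
#' the per-group minimum off-diagonal entry identifies each group's
#' closest neighbor.
#'
#' @param st A `structured_tree` with a group map covering >= 2 groups.
#' @return List with `d` (symmetric group-by-group matrix, `NA`
#'   diagonal) and `min_intergroup` (named vector of each group's
#'   smallest mean distance to another group).
#' @export
intergroup_distances <- function(st) {
  if (is.null(st$groups))
    stop("tree has no tip-to-group map", call. = FALSE)
  gids <- sort(unique(st$groups))
  if (length(gids) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  pd <- ape::cophenetic.phylo(st$tree)
  d <- matrix(NA_real_, length(gids), length(gids),
              dimnames = list(gids, gids))
  for (i in seq_along(gids)) {
    ti <- names(st$groups)[st$groups == gids[i]]
    for (j in seq_along(gids)) {
      if (i >= j) next
      tj <- names(st$groups)[st$groups == gids[j]]
      d[i, j] <- d[j, i] <- mean(pd[ti, tj, drop = FALSE])
    }
  }
  list(d = d,
       min_intergroup = apply(d, 1L, min, na.rm = TRUE))
}

#' Extract one group's subtree
#'
#' @param st A `structured_tree` with a group map.
#' @param group Group id with >= 2 tips forming a clade (the subtree is
#'   the clade spanned by the group's MRCA).
#' @return A `structured_tree` for the clade.
#' @export
extract_group_tree <- function(st, group) {
  tips <- group_tips(st, group)
  if (length(tips) < 2L)
    stop("group '", group, "' has fewer than 2 tips", call. = FALSE)
  node <- ape::getMRCA(st$tree, tips)
  sub <- ape::extract.clade(st$tree, node)
  structured_tree(sub, st$groups[sub$tip.label])
}
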
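# Independent brute-force oracles used to cross-check the implementation.

# wrap a plain symmetric matrix as a distance_matrix object
as_dm <- function(d) {
  structure(list(names = rownames(d), d = d,
                 sites = matrix(1L, nrow(d), ncol(d))),
            class = "distance_matrix")
}

random_dm <- function(n, max_d = 0.5) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- stats::runif(n * (n - 1) / 2, 0, max_d)
  d <- d + t(d)
  nms <- sprintf("s%02d", seq_len(n))
  dimnames(d) <- list(nms, nms)
  as_dm(d)
}

# Naive furthest-neighbor agglomeration: at every step recompute every
# cluster-pair's complete-linkage distance directly from the (rounded)
# input matrix by scanning all cross pairs. Same grid and tie rule as the
# implementation, but no incremental update.
oracle_complete_linkage <- function(m, precision = 10000L) {
  d <- floor(m$d * precision + 0.5) / precision
  clusters <- lapply(m$names, identity)
  merges <- list()
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        cand <- list(i = i, j = j, h = h, key = key)
        if (is.null(best) || h < best$h ||
            (h == best$h && (key[1] < best$key[1] ||
                             (key[1] == best$key[1] &&
                              key[2] < best$key[2]))))
          best <- cand
      }
    }
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    merges[[length(merges) + 1L]] <- list(height = best$h,
                                          members = merged)
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
  }
  merges
}

# Patristic distance by explicit root-path enumeration on the edge matrix.
oracle_patristic <- function(tree, tip_a, tip_b) {
  path_to_root <- function(node) {
    nodes <- node
    lens <- numeric(0)
    repeat {
      e <- which(tree$edge[, 2] == node)
      if (length(e) == 0L) break
      lens <- c(lens, tree$edge.length[e])
      node <- tree$edge[e, 1]
      nodes <- c(nodes, node)
    }
    list(nodes = nodes, cum = c(0, cumsum(lens)))
  }
  a <- path_to_root(match(tip_a, tree$tip.label))
  b <- path_to_root(match(tip_b, tree$tip.label))
  common <- intersect(a$nodes, b$nodes)
  mrca <- common[which.min(match(common, a$nodes))]
  a$cum[match(mrca, a$nodes)] + b$cum[match(mrca, b$nodes)]
}

# IUPAC-aware primer scan by explicit per-offset, per-letter expansion.
iupac_table <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT",
                 M = "AC", B = "CGT", D = "AGT", H = "ACT", V = "ACG",
                 N = "ACGT")

oracle_primer_scan <- function(seq, primer) {
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(primer, "")[[1]]
  np <- length(p)
  for (off in seq_len(length(s) - np + 1L)) {
    ok <- TRUE
    for (k in seq_len(np)) {
      if (!grepl(s[off + k - 1L], iupac_table[[p[k]]], fixed = TRUE)) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(c(start = off, end = off + np - 1L))
  }
  NULL
}

random_tree <- function(n) {
  simulate_yule_tree(n)$tree
}

round_to_grid_test <- function(d, precision = 10000) {
  floor(d * precision + 0.5) / precision
}

# small aligned fixture with gaps: rows derive from a shared ancestor so
# pairwise divergence stays well below saturation
random_gapped_alignment <- function(n, len, gap_prob = 0.1,
                                    sub_prob = 0.15) {
  anc <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  rows <- vapply(seq_len(n), function(i) {
    chars <- anc
    mut <- stats::runif(len) < sub_prob
    chars[mut] <- sample(c("A", "C", "G", "T"), sum(mut), replace = TRUE)
    gaps <- stats::runif(len) < gap_prob
    chars[gaps] <- "-"
    paste(chars, collapse = "")
  }, character(1))
  group_alignment(rows, sprintf("s%02d", seq_len(n)))
}
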
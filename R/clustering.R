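# Furthest-neighbor (complete-linkage) OTU clustering on a fixed precision
# grid, mirroring mothur's furthest-neighbor routine, plus the per-group
# diversity statistics: Avg, Max, maximum corrected distance, and OTU
# counts across cutoffs.

# Round to the 1/precision grid, half away from zero (mothur-style), so
# e.g. 0.00005 -> 0.0001 at precision 10000.
round_to_grid <- function(d, precision) {
  floor(d * precision + 0.5) / precision
}

#' Furthest-neighbor agglomerative clustering
#'
#' Rounds all pairwise distances to the nearest `1/precision`, then
#' iteratively merges the pair of clusters with the smallest
#' complete-linkage distance (the maximum over cross-pairs). Ties among
#' equal-height candidate merges are broken by the lexicographically
#' smallest member names of the two clusters, which makes the dendrogram
#' reproducible.
#'
#' @param m A [distance_matrix()] (or plain symmetric named matrix) with
#'   at least 2 names and no `NA` entries.
#' @param precision Distance grid resolution (default 10000, i.e. 4
#'   decimals — maximum precision in the mothur sense).
#' @return Object of class `merge_dendrogram`: list with `leaves`,
#'   `merges` (each a list with `height` and `members`, heights
#'   non-decreasing, final merge uniting all leaves), and `precision`.
#' @export
cluster_furthest_neighbor <- function(m, precision = 10000L) {
  d <- if (inherits(m, "distance_matrix")) m$d else as.matrix(m)
  nms <- if (inherits(m, "distance_matrix")) m$names else rownames(d)
  n <- length(nms)
  if (n < 2L)
    stop("need at least 2 sequences to cluster", call. = FALSE)
  if (anyNA(d))
    stop("distance matrix contains undefined (NA) pairs", call. = FALSE)
  work <- round_to_grid(d, precision)
  diag(work) <- Inf
  members <- lapply(nms, identity)          # active cluster -> leaf names
  min_name <- nms                           # lexicographic tie key
  merges <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(members)
    h <- min(work)
    cand <- which(work == h, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    if (nrow(cand) > 1L) {
      key1 <- pmin(min_name[cand[, 1L]], min_name[cand[, 2L]])
      key2 <- pmax(min_name[cand[, 1L]], min_name[cand[, 2L]])
      cand <- cand[order(key1, key2)[1L], , drop = FALSE]
    }
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    new_members <- c(members[[i]], members[[j]])
    merges[[step]] <- list(height = h, members = sort(new_members))
    # complete-linkage (Lance-Williams) update against remaining clusters
    rest <- setdiff(seq_len(k), c(i, j))
    new_row <- pmax(work[i, rest], work[j, rest])
    work <- work[rest, rest, drop = FALSE]
    work <- rbind(cbind(work, new_row), c(new_row, Inf))
    members <- c(members[rest], list(new_members))
    min_name <- c(min_name[rest], min(new_members))
  }
  structure(list(leaves = nms, merges = merges,
                 precision = as.integer(precision)),
            class = "merge_dendrogram")
}

#' @export
print.merge_dendrogram <- function(x, ...) {
  h <- vapply(x$merges, `[[`, numeric(1), "height")
  cat("Furthest-neighbor dendrogram: ", length(x$leaves), " leaves, ",
      length(x$merges), " merges, heights ", format(min(h)), " .. ",
      format(max(h)), "\n", sep = "")
  invisible(x)
}

#' Cut a dendrogram into OTUs at a distance cutoff
#'
#' Applies every merge with height `<=` cutoff (closed interval, compared
#' on the dendrogram's precision grid) and returns the resulting
#' partition. Any two sequences sharing an OTU are guaranteed to have
#' rounded distance at most the cutoff.
#'
#' @param dend A `merge_dendrogram`.
#' @param cutoff Distance cutoff, `>= 0`.
#' @return Object of class `otu_partition`: list with `cutoff` and
#'   `otus` (list of character vectors covering all leaves).
#' @export
partition_at <- function(dend, cutoff) {
  if (cutoff < 0)
    stop("cutoff must be >= 0", call. = FALSE)
  cut_r <- round_to_grid(cutoff, dend$precision) + 1e-9
  assign <- seq_along(dend$leaves)
  names(assign) <- dend$leaves
  nxt <- length(assign) + 1L
  for (mg in dend$merges) {
    if (mg$height > cut_r) break
    assign[mg$members] <- nxt
    nxt <- nxt + 1L
  }
  otus <- split(names(assign), assign)
  otus <- unname(otus[order(vapply(otus, min, character(1)))])
  otus <- lapply(otus, sort)
  structure(list(cutoff = cutoff, otus = otus), class = "otu_partition")
}

#' Number of OTUs at a cutoff
#' @param dend A `merge_dendrogram`.
#' @param cutoff Distance cutoff.
#' @return Integer OTU count.
#' @export
n_otus <- function(dend, cutoff) length(partition_at(dend, cutoff)$otus)

#' Maximum corrected distance
#'
#' The smallest merge height at which a given fraction of the group's
#' sequences (90% by default) falls into a single OTU; 0 when the
#' condition already holds at cutoff 0. This statistic discounts single
#' highly divergent (possibly erroneous) sequences that inflate the raw
#' maximum pairwise distance.
#'
#' @param dend A `merge_dendrogram`.
#' @param fraction Required fraction of sequences in one OTU, in `(0, 1]`;
#'   compared with `>=` on the real value `fraction * n`.
#' @return Distance (on the precision grid).
#' @export
max_corrected_distance <- function(dend, fraction = 0.9) {
  if (fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]", call. = FALSE)
  n <- length(dend$leaves)
  need <- fraction * n
  if (1 >= need) return(0)
  sizes <- rep(1L, n)
  names(sizes) <- dend$leaves
  assign <- seq_len(n)
  names(assign) <- dend$leaves
  heights <- vapply(dend$merges, `[[`, numeric(1), "height")
  largest <- 1L
  k <- 1L
  for (h in unique(heights)) {
    while (k <= length(dend$merges) && heights[k] == h) {
      assign[dend$merges[[k]]$members] <- n + k
      largest <- max(largest, length(dend$merges[[k]]$members))
      k <- k + 1L
    }
    if (largest >= need) return(h)
  }
  heights[length(heights)]   # fraction <= 1 always met at the last merge
}

#' Per-group diversity statistics
#'
#' Computes the statistics of the group report from a distance matrix:
#' sequence count, average and maximum pairwise distance (unrounded),
#' maximum corrected distance, and OTU counts at each cutoff.
#'
#' @param m A [distance_matrix()].
#' @param group_id Group label.
#' @param cutoffs Clustering cutoffs (default `c(0, 0.01, 0.05, 0.10)`).
#' @param precision Clustering grid (default 10000).
#' @param fraction Fraction for the maximum corrected distance
#'   (default 0.9).
#' @return Object of class `group_diversity_stats` (see
#'   [diversity_stats()]).
#' @export
group_diversity <- function(m, group_id = "group",
                            cutoffs = c(0, 0.01, 0.05, 0.10),
                            precision = 10000L, fraction = 0.9) {
  s <- summarize_distances(m)
  dend <- cluster_furthest_neighbor(m, precision = precision)
  counts <- vapply(cutoffs, function(cc) n_otus(dend, cc), integer(1))
  diversity_stats(
    group_id = group_id,
    n_seq = length(m$names),
    avg = s$avg, max = s$max,
    max_corrected = max_corrected_distance(dend, fraction = fraction),
    otu_counts = stats::setNames(counts, format_cutoff(cutoffs))
  )
}

format_cutoff <- function(cutoff) formatC(cutoff, format = "f", digits = 2)

#' Construct group diversity statistics
#'
#' Direct constructor (used both by [group_diversity()] and for working
#' with published OTU-count tables), with the structural invariants
#' enforced: `max_corrected <= max`, OTU counts non-increasing in cutoff
#' and at most `n_seq`.
#'
#' @param group_id Group label.
#' @param n_seq Number of sequences.
#' @param avg,max Average and maximum pairwise distance.
#' @param max_corrected Maximum corrected distance.
#' @param otu_counts Named integer vector, names are cutoffs formatted to
#'   2 decimals (e.g. `"0.00"`, `"0.01"`, `"0.05"`).
#' @param grid_tol Slack allowed on `max_corrected <= max`: the corrected
#'   distance lives on the clustering grid while `max` is unrounded, so
#'   it may exceed `max` by up to half a grid step (default `5e-5`,
#'   matching precision 10000).
#' @return Object of class `group_diversity_stats`.
#' @export
diversity_stats <- function(group_id, n_seq, avg, max, max_corrected,
                            otu_counts, grid_tol = 5e-5) {
  cutoffs <- suppressWarnings(as.numeric(names(otu_counts)))
  if (anyNA(cutoffs))
    stop("otu_counts must be named by numeric cutoffs", call. = FALSE)
  if (is.unsorted(cutoffs, strictly = TRUE))
    stop("otu_counts cutoffs must be strictly increasing", call. = FALSE)
  if (is.unsorted(rev(otu_counts)))
    stop("OTU counts must be non-increasing in cutoff", call. = FALSE)
  if (otu_counts[1L] > n_seq)
    stop("OTU count at the smallest cutoff exceeds n_seq", call. = FALSE)
  if (max_corrected > max + grid_tol)
    stop("max_corrected exceeds max pairwise distance", call. = FALSE)
  structure(
    list(group_id = group_id, n_seq = as.integer(n_seq), avg = avg,
         max = max, max_corrected = max_corrected,
         otu_counts = otu_counts, cutoffs = cutoffs),
    class = "group_diversity_stats"
  )
}

#' @export
print.group_diversity_stats <- function(x, ...) {
  cat("Group '", x$group_id, "': ", x$n_seq, " seqs, Avg ",
      formatC(x$avg, format = "f", digits = 4), ", Max ",
      formatC(x$max, format = "f", digits = 4), ", Max_c ",
      formatC(x$max_corrected, format = "f", digits = 4), "\n  OTUs: ",
      paste(names(x$otu_counts), x$otu_counts, sep = "=",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Clustering pattern: OTU percentages relative to zero distance
#'
#' Expresses OTU counts at each cutoff as a percentage of the count at
#' distance 0, the per-group curve used to compare how fast OTU numbers
#' collapse as the cutoff grows (high percentages at 0.05-0.10 indicate
#' many high-rank lineages).
#'
#' @param stats A `group_diversity_stats`.
#' @param cutoffs Cutoffs to report (default: all in `stats`); each must
#'   be present in `stats$otu_counts`, and cutoff 0 must be present.
#' @return Named numeric vector of percentages.
#' @export
clustering_pattern <- function(stats, cutoffs = stats$cutoffs) {
  keys <- format_cutoff(cutoffs)
  have <- names(stats$otu_counts)
  zero_key <- format_cutoff(0)
  if (!zero_key %in% have)
    stop("OTU count at cutoff 0 is required", call. = FALSE)
  missing <- setdiff(keys, have)
  if (length(missing))
    stop("no OTU count at cutoff(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  n0 <- stats$otu_counts[[zero_key]]
  if (n0 < 1L)
    stop("OTU count at cutoff 0 must be >= 1", call. = FALSE)
  stats::setNames(100 * unname(stats$otu_counts[keys]) / n0, keys)
}

#' Group report table
#'
#' Assembles the per-group statistics into the standard report: one row
#' per group with Seq, Avg, Max, Max_c and OTU counts per cutoff, plus a
#' totals row in which OTU counts are summed across groups (counts are
#' calculated for each group and then added up).
#'
#' @param groups List of `group_diversity_stats` sharing the same
#'   cutoffs.
#' @return `data.frame` with a final `Total` row (distance columns `NA`
#'   there).
#' @export
group_report <- function(groups) {
  if (length(groups) == 0L) {
    return(data.frame(Group = character(0), Seq = integer(0),
                      Avg = numeric(0), Max = numeric(0),
                      Max_c = numeric(0)))
  }
  keys <- names(groups[[1L]]$otu_counts)
  for (g in groups)
    if (!identical(names(g$otu_counts), keys))
      stop("all groups must share the same cutoffs", call. = FALSE)
  df <- data.frame(
    Group = vapply(groups, `[[`, character(1), "group_id"),
    Seq = vapply(groups, `[[`, integer(1), "n_seq"),
    Avg = vapply(groups, `[[`, numeric(1), "avg"),
    Max = vapply(groups, `[[`, numeric(1), "max"),
    Max_c = vapply(groups, `[[`, numeric(1), "max_corrected")
  )
  counts <- t(vapply(groups, function(g) as.integer(g$otu_counts),
                     integer(length(keys))))
  colnames(counts) <- paste0("OTU_", keys)
  df <- cbind(df, as.data.frame(counts))
  total <- data.frame(Group = "Total", Seq = sum(df$Seq), Avg = NA_real_,
                      Max = NA_real_, Max_c = NA_real_)
  total <- cbind(total, as.data.frame(t(colSums(counts))))
  rbind(df, total)
}

#' Write a mothur-style list file
#'
#' One line per cutoff: the cutoff label, the number of OTUs, then one
#' tab-separated field per OTU with comma-joined member names.
#'
#' @param dend A `merge_dendrogram`.
#' @param cutoffs Cutoffs to list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_list_file <- function(dend, cutoffs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cc in cutoffs) {
    part <- partition_at(dend, cc)
    fields <- vapply(part$otus, paste, character(1), collapse = ",")
    writeLines(paste(c(format_cutoff(cc), length(fields), fields),
                     collapse = "\t"), con)
  }
  invisible(path)
}
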
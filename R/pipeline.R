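# End-to-end drivers: per-group diversity (filter -> distances -> OTUs ->
# report), tree structure (ultrametricize -> LTT/gamma/MPD/trunk), and
# region calibration. Report numbers are written with 4 decimals (the
# clustering grid); counts as integers.

format_report_numbers <- function(df, digits = 4L) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]]))
      df[[j]] <- ifelse(is.na(df[[j]]), "",
                        formatC(df[[j]], format = "f", digits = digits))
  }
  df
}

write_report_tsv <- function(df, path, digits = 4L) {
  utils::write.table(format_report_numbers(df, digits), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the per-group diversity analysis
#'
#' For every group alignment: apply the minimum-length filter, compute
#' the Jukes-Cantor distance matrix, cluster by furthest neighbor, and
#' collect the diversity statistics. Produces the group report (one row
#' per group plus a totals row of summed OTU counts) and the
#' clustering-pattern table (OTU percentages relative to distance 0).
#' Groups that fail hard (fewer than 2 sequences after filtering, a
#' saturated pair, no shared sites) are skipped with a logged reason.
#'
#' @param alignments Named list of [group_alignment()]s, or a character
#'   vector of FASTA paths (names become group ids).
#' @param out_dir Optional output directory for `group_report.tsv`,
#'   `clustering_pattern.tsv`, and per-group mothur-style list files.
#' @param cutoffs Clustering cutoffs (default `c(0, 0.01, 0.05, 0.10)`,
#'   sorted unique ascending required).
#' @param precision Clustering grid (default 10000).
#' @param fraction Maximum-corrected-distance fraction (default 0.9).
#' @param min_ungapped Minimum ungapped length retained (default 475).
#' @return List with `report` (data.frame), `patterns` (data.frame of
#'   group, cutoff, percent), `stats` (list of `group_diversity_stats`),
#'   and `skipped` (named character vector of reasons).
#' @export
run_diversity <- function(alignments, out_dir = NULL,
                          cutoffs = c(0, 0.01, 0.05, 0.10),
                          precision = 10000L, fraction = 0.9,
                          min_ungapped = 475L) {
  if (is.character(alignments)) {
    paths <- alignments
    ids <- if (is.null(names(paths)))
      sub("\\.(fa|fasta|fna)$", "", basename(paths)) else names(paths)
    alignments <- Map(read_alignment, paths, ids)
    names(alignments) <- ids
  }
  if (length(alignments) == 0L)
    stop("no group alignments supplied", call. = FALSE)
  if (is.unsorted(cutoffs, strictly = TRUE))
    stop("cutoffs must be sorted ascending and unique", call. = FALSE)
  if (!0 %in% cutoffs)
    stop("cutoffs must include 0 (clustering-pattern reference)",
         call. = FALSE)
  stats_list <- list()
  skipped <- character(0)
  dends <- list()
  for (gid in names(alignments)) {
    aln <- filter_min_length(alignments[[gid]], min_ungapped)
    if (length(aln$rows) < 2L) {
      skipped[gid] <- "fewer than 2 sequences after length filter"
      message("run_diversity: skipping '", gid, "': ", skipped[gid])
      next
    }
    res <- tryCatch({
      m <- distance_matrix(aln)
      dend <- cluster_furthest_neighbor(m, precision = precision)
      list(stats = group_diversity(m, group_id = gid, cutoffs = cutoffs,
                                   precision = precision,
                                   fraction = fraction),
           dend = dend)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      skipped[gid] <- res
      message("run_diversity: skipping '", gid, "': ", res)
      next
    }
    stats_list[[gid]] <- res$stats
    dends[[gid]] <- res$dend
  }
  if (length(stats_list) == 0L)
    stop("all groups failed: ",
         paste(names(skipped), skipped, sep = ": ", collapse = "; "),
         call. = FALSE)
  report <- group_report(stats_list)
  patterns <- do.call(rbind, lapply(stats_list, function(s) {
    pct <- clustering_pattern(s)
    data.frame(group = s$group_id, cutoff = s$cutoffs,
               percent = unname(pct))
  }))
  rownames(patterns) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report_tsv(report, file.path(out_dir, "group_report.tsv"))
    write_report_tsv(patterns,
                     file.path(out_dir, "clustering_pattern.tsv"))
    for (gid in names(dends))
      write_list_file(dends[[gid]], cutoffs,
                      file.path(out_dir, paste0(gid, ".list")))
  }
  list(report = report, patterns = patterns, stats = stats_list,
       skipped = skipped)
}

#' Run the phylogenetic-structure analysis
#'
#' For every group in the tree's tip-group map: extract the group's
#' clade, transform it to ultrametric, and compute the standardized LTT
#' curve and the gamma statistic with its one-tailed constant-rate
#' classification (groups with fewer than 3 tips are excluded from the
#' gamma table with a logged reason). On the full tree, computes each
#' group's MPD, trunk length, and minimum mean intergroup distance.
#'
#' @param st A [structured_tree()] with a tip-group map.
#' @param out_dir Optional output directory for `gamma_report.tsv`,
#'   `structure_report.tsv`, `intergroup_distances.tsv`, and per-group
#'   `ltt_<group>.tsv`.
#' @param alpha One-tailed significance level for the gamma
#'   classification (default 0.05).
#' @return List with `gamma` (data.frame group, n, gamma, p,
#'   classification), `structure` (data.frame group, n, mpd, trunk,
#'   min_intergroup), `intergroup` (matrix), `ltt` (named list of
#'   `ltt_curve`s).
#' @export
run_structure <- function(st, out_dir = NULL, alpha = 0.05) {
  if (is.null(st$groups))
    stop("tree has no tip-to-group map", call. = FALSE)
  gids <- sort(unique(st$groups))
  inter <- intergroup_distances(st)
  ltt <- list()
  gamma_rows <- list()
  struct_rows <- list()
  for (gid in gids) {
    tips <- names(st$groups)[st$groups == gid]
    n <- length(tips)
    g_mpd <- if (n >= 2L) mpd(st, gid) else NA_real_
    g_trunk <- trunk_length(st, gid)
    struct_rows[[gid]] <- data.frame(
      group = gid, n = n, mpd = g_mpd, trunk = g_trunk,
      min_intergroup = unname(inter$min_intergroup[gid]))
    if (n < 3L) {
      message("run_structure: group '", gid, "' has ", n,
              " tip(s); excluded from gamma/LTT")
      next
    }
    sub <- make_ultrametric(extract_group_tree(st, gid))
    ltt[[gid]] <- ltt_curve(sub)
    g <- gamma_statistic(sub)
    gamma_rows[[gid]] <- data.frame(
      group = gid, n = g$n_tips, gamma = g$gamma,
      p = g$p_one_tailed, classification = classify_gamma(g, alpha))
  }
  gamma_df <- if (length(gamma_rows)) do.call(rbind, gamma_rows) else
    data.frame(group = character(0), n = integer(0),
               gamma = numeric(0), p = numeric(0),
               classification = character(0))
  struct_df <- do.call(rbind, struct_rows)
  rownames(gamma_df) <- rownames(struct_df) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report_tsv(gamma_df, file.path(out_dir, "gamma_report.tsv"))
    write_report_tsv(struct_df,
                     file.path(out_dir, "structure_report.tsv"))
    inter_df <- data.frame(group = rownames(inter$d), inter$d,
                           check.names = FALSE)
    write_report_tsv(inter_df,
                     file.path(out_dir, "intergroup_distances.tsv"))
    for (gid in names(ltt))
      write_report_tsv(ltt[[gid]]$points,
                       file.path(out_dir, paste0("ltt_", gid, ".tsv")))
  }
  list(gamma = gamma_df, structure = struct_df, intergroup = inter$d,
       ltt = ltt)
}

#' Run the region calibration
#'
#' For each named region of a full-gene alignment: extract the
#' sub-alignment, compute both distance matrices (saturated pairs set
#' `NA` and dropped from the fit), and regress region distances on
#' full-gene distances.
#'
#' @param full_aln A [group_alignment()] of the full gene with `>= 3`
#'   rows, with regions annotated in its `region_map` (or passed via
#'   `regions`).
#' @param regions Optional named list of column intervals overriding the
#'   alignment's `region_map`.
#' @param out_dir Optional output directory for `region_fits.tsv` plus
#'   per-region pair TSVs and JSON summaries.
#' @return Named list of `region_fit`s.
#' @export
run_region_eval <- function(full_aln, regions = NULL, out_dir = NULL) {
  if (length(full_aln$rows) < 3L)
    stop("need at least 3 sequences (3 pairs) for a region fit",
         call. = FALSE)
  if (is.null(regions)) regions <- full_aln$region_map
  if (is.null(regions) || length(regions) == 0L)
    stop("no regions defined", call. = FALSE)
  full_m <- distance_matrix(full_aln, on_saturation = "na")
  fits <- list()
  for (nm in names(regions)) {
    sub <- extract_region(full_aln, region = regions[[nm]])
    part_m <- distance_matrix(sub, on_saturation = "na")
    fits[[nm]] <- paired_region_fit(full_m, part_m, region_name = nm)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_region_pairs(full_m, part_m,
                         file.path(out_dir, paste0("pairs_", nm, ".tsv")))
      write_region_fit(fits[[nm]],
                       file.path(out_dir, paste0("fit_", nm, ".json")))
    }
  }
  if (!is.null(out_dir)) {
    df <- do.call(rbind, lapply(fits, function(f)
      data.frame(region = f$region_name, m = f$m,
                 intercept = f$intercept, R = f$R,
                 n_pairs = f$n_pairs)))
    rownames(df) <- NULL
    write_report_tsv(df, file.path(out_dir, "region_fits.tsv"))
  }
  fits
}
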
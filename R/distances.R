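# Jukes-Cantor pairwise distances with pairwise deletion of gaps and
# ambiguity codes, and the per-group Avg/Max summaries.

#' Observed proportion of differing sites between two aligned rows
#'
#' Compares two equal-length aligned sequences under pairwise deletion:
#' only columns where both characters are unambiguous bases (A, C, G, T)
#' are counted; gaps and ambiguity codes in either row exclude the column.
#'
#' @param a,b Aligned sequence strings of equal length.
#' @return List with `p` (mismatch proportion among comparable sites)
#'   and `sites` (number of comparable sites).
#' @export
p_distance <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("sequences differ in length (", nchar(a), " vs ", nchar(b), ")",
         call. = FALSE)
  x <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
  y <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
  bases <- c("A", "C", "G", "T")
  ok <- x %in% bases & y %in% bases
  sites <- sum(ok)
  if (sites == 0L)
    stop("no comparable sites between the two sequences", call. = FALSE)
  list(p = sum(x[ok] != y[ok]) / sites, sites = sites)
}

#' Jukes-Cantor correction of an observed mismatch proportion
#'
#' `d = -(3/4) * log(1 - 4p/3)`, the expected substitutions per site
#' under the one-parameter substitution model. Defined for `p < 0.75`;
#' at or beyond saturation the distance is undefined and an error is
#' raised (silent clamping would corrupt maximum-distance statistics).
#'
#' @param p Mismatch proportion(s) in `[0, 0.75)`.
#' @return Corrected distance(s), substitutions/site.
#' @export
jukes_cantor <- function(p) {
  if (any(p < 0))
    stop("mismatch proportion below 0", call. = FALSE)
  if (any(p >= 0.75))
    stop("saturated pair: p = ", format(max(p)),
         " >= 0.75, Jukes-Cantor distance undefined", call. = FALSE)
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise Jukes-Cantor distance matrix for a group alignment
#'
#' Applies [p_distance()] + [jukes_cantor()] to every unordered pair.
#' Saturated pairs (`p >= 0.75`) and pairs with no comparable sites are
#' an error naming the pair by default; with `on_saturation = "na"` they
#' become `NA` entries (counted via `message()`), which the region
#' calibration uses to drop such pairs.
#'
#' @param aln A [group_alignment()] with at least 2 rows.
#' @param on_saturation `"error"` (default) or `"na"`.
#' @return Object of class `distance_matrix`: list with `names`, `d`
#'   (symmetric numeric matrix, substitutions/site), and `sites`
#'   (symmetric integer matrix of comparable-site counts).
#' @export
distance_matrix <- function(aln, on_saturation = c("error", "na")) {
  on_saturation <- match.arg(on_saturation)
  n <- length(aln$rows)
  if (n < 2L)
    stop("need at least 2 sequences for a distance matrix", call. = FALSE)
  m <- aln_matrix(aln)
  code <- match(m, c("A", "C", "G", "T"))        # NA for gap/ambiguity
  dim(code) <- dim(m)
  d <- matrix(0, n, n, dimnames = list(aln$names, aln$names))
  sites <- matrix(0L, n, n, dimnames = list(aln$names, aln$names))
  n_dropped <- 0L
  for (i in seq_len(n - 1L)) {
    xi <- code[i, ]
    for (j in (i + 1L):n) {
      yj <- code[j, ]
      ok <- !is.na(xi) & !is.na(yj)
      ns <- sum(ok)
      if (ns == 0L) {
        if (on_saturation == "error")
          stop("no comparable sites between '", aln$names[i], "' and '",
               aln$names[j], "'", call. = FALSE)
        d[i, j] <- d[j, i] <- NA_real_
        n_dropped <- n_dropped + 1L
        next
      }
      p <- sum(xi[ok] != yj[ok]) / ns
      sites[i, j] <- sites[j, i] <- ns
      if (p >= 0.75) {
        if (on_saturation == "error")
          stop("saturated pair '", aln$names[i], "' vs '", aln$names[j],
               "' (p = ", format(p), " >= 0.75)", call. = FALSE)
        d[i, j] <- d[j, i] <- NA_real_
        n_dropped <- n_dropped + 1L
        next
      }
      d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * p / 3)
    }
  }
  if (n_dropped > 0L)
    message("distance_matrix: ", n_dropped,
            " pair(s) undefined (saturated or no shared sites), set NA")
  structure(list(names = aln$names, d = d, sites = sites),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("Jukes-Cantor distance matrix: ", length(x$names),
      " sequences\n", sep = "")
  invisible(x)
}

#' Average and maximum pairwise distance within a group
#'
#' `avg` is the mean over the `n(n-1)/2` unordered pairs; `max` the
#' largest pair value — the Avg and Max statistics reported per group.
#'
#' @param m A `distance_matrix` (or plain symmetric matrix) with >= 2
#'   names; `NA` pairs are excluded.
#' @return List with `avg` and `max`.
#' @export
summarize_distances <- function(m) {
  d <- if (inherits(m, "distance_matrix")) m$d else as.matrix(m)
  if (nrow(d) < 2L)
    stop("need at least 2 sequences", call. = FALSE)
  v <- d[upper.tri(d)]
  v <- v[!is.na(v)]
  if (length(v) == 0L)
    stop("no defined pairwise distances", call. = FALSE)
  list(avg = mean(v), max = max(v))
}

#' Write a distance matrix as square TSV
#' @param m A `distance_matrix`.
#' @param path Output path (names in header row and first column).
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(m, path) {
  df <- data.frame(name = m$names, m$d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a distance matrix as a three-column pair list
#' @param m A `distance_matrix`.
#' @param path Output path (columns name1, name2, distance).
#' @return `path`, invisibly.
#' @export
write_pair_list <- function(m, path) {
  idx <- which(upper.tri(m$d), arr.ind = TRUE)
  df <- data.frame(name1 = m$names[idx[, 1L]],
                   name2 = m$names[idx[, 2L]],
                   distance = m$d[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
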
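# Calibration of a partial-gene region against full-gene distances:
# ordinary least squares of partial on full pairwise distances, with the
# Pearson correlation, over matched sequence pairs.

#' Regression of partial-region distances on full-gene distances
#'
#' Over all unordered sequence pairs shared by the two matrices, fits
#' `partial = intercept + m * full` by ordinary least squares and reports
#' the slope `m`, intercept, Pearson correlation `R`, and the number of
#' pairs used. A slope above 1 means the region is more variable than the
#' full gene and overestimates genetic distances by that factor (about
#' 1.4 for V4-V5 on 18S rDNA). Pairs where either matrix is undefined
#' (`NA`, e.g. saturated) are dropped and counted via `message()`.
#'
#' @param full [distance_matrix()] from the full-length gene.
#' @param partial [distance_matrix()] from the extracted region; must
#'   cover the identical set of sequence names.
#' @param region_name Label carried into the result.
#' @return Object of class `region_fit`: list with `region_name`, `m`,
#'   `intercept`, `R`, `n_pairs`.
#' @export
paired_region_fit <- function(full, partial, region_name = "region") {
  fn <- full$names
  pn <- partial$names
  if (!setequal(fn, pn))
    stop("full and partial matrices cover different sequences: ",
         paste(union(setdiff(fn, pn), setdiff(pn, fn)), collapse = ", "),
         call. = FALSE)
  ord <- match(fn, pn)
  dp <- partial$d[ord, ord]
  df <- full$d
  ut <- upper.tri(df)
  x <- df[ut]
  y <- dp[ut]
  drop <- is.na(x) | is.na(y)
  if (any(drop))
    message("paired_region_fit: dropped ", sum(drop),
            " undefined pair(s)")
  x <- x[!drop]; y <- y[!drop]
  if (length(x) < 3L)
    stop("need at least 3 defined pairs to fit (have ", length(x), ")",
         call. = FALSE)
  if (stats::var(x) == 0)
    stop("degenerate fit: zero variance in full-gene distances",
         call. = FALSE)
  fit <- stats::lm.fit(cbind(1, x), y)
  structure(
    list(region_name = region_name,
         m = unname(fit$coefficients[2L]),
         intercept = unname(fit$coefficients[1L]),
         R = stats::cor(x, y),
         n_pairs = length(x)),
    class = "region_fit"
  )
}

#' @export
print.region_fit <- function(x, ...) {
  cat("Region fit '", x$region_name, "': m = ",
      formatC(x$m, format = "f", digits = 4), ", intercept = ",
      formatC(x$intercept, format = "f", digits = 4), ", R = ",
      formatC(x$R, format = "f", digits = 4), " (", x$n_pairs,
      " pairs)\n", sep = "")
  invisible(x)
}

#' Write per-pair distances for external plotting
#'
#' @param full,partial Matched [distance_matrix()] objects.
#' @param path Output TSV path (columns name1, name2, full_d, partial_d).
#' @return `path`, invisibly.
#' @export
write_region_pairs <- function(full, partial, path) {
  ord <- match(full$names, partial$names)
  dp <- partial$d[ord, ord]
  idx <- which(upper.tri(full$d), arr.ind = TRUE)
  df <- data.frame(name1 = full$names[idx[, 1L]],
                   name2 = full$names[idx[, 2L]],
                   full_d = full$d[idx],
                   partial_d = dp[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a region fit as JSON
#' @param fit A `region_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_region_fit <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
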
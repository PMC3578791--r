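# Aligned 18S rDNA sequences for one taxonomic group, plus primer-based
# region extraction and the minimum-length filter applied before distance
# computation.

IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

#' Construct a group alignment
#'
#' Bundles the aligned sequences of one taxonomic group: equal-length rows
#' over IUPAC nucleotide codes plus `-` gaps, unique sequence names, and an
#' optional map of named column intervals (1-based, inclusive) marking
#' regions such as V4-V5.
#'
#' @param rows Character vector of aligned sequences (equal lengths).
#' @param names Character vector of unique sequence identifiers.
#' @param group_id Free-text group label (e.g. `"Dinophyceae"`).
#' @param region_map Optional named list of length-2 integer vectors
#'   `c(start, end)`, 1-based inclusive alignment columns.
#' @return An object of class `group_alignment`.
#' @export
group_alignment <- function(rows, names, group_id = "group",
                            region_map = NULL) {
  rows <- toupper(as.character(rows))
  rows <- chartr("U", "T", rows)
  names <- as.character(names)
  if (length(rows) != length(names))
    stop("rows and names differ in length", call. = FALSE)
  if (length(rows) == 0L)
    stop("alignment has no sequences", call. = FALSE)
  widths <- nchar(rows)
  if (length(unique(widths)) > 1L)
    stop("alignment rows have unequal lengths: ",
         paste(sort(unique(widths)), collapse = ", "), call. = FALSE)
  if (widths[1L] < 1L)
    stop("alignment has zero columns", call. = FALSE)
  if (anyDuplicated(names))
    stop("duplicate sequence names: ",
         paste(unique(names[duplicated(names)]), collapse = ", "),
         call. = FALSE)
  bad <- grepl(paste0("[^", paste(names(IUPAC_CODES), collapse = ""), "-]"),
               rows)
  if (any(bad))
    stop("non-IUPAC characters in sequences: ",
         paste(names[bad], collapse = ", "), call. = FALSE)
  if (!is.null(region_map)) {
    if (is.null(names(region_map)) || any(!nzchar(names(region_map))))
      stop("region_map intervals must be named", call. = FALSE)
    for (nm in names(region_map)) {
      iv <- as.integer(region_map[[nm]])
      if (length(iv) != 2L || anyNA(iv) || iv[1L] > iv[2L] ||
          iv[1L] < 1L || iv[2L] > widths[1L])
        stop("region '", nm, "' outside [1, ", widths[1L],
             "] or start > end", call. = FALSE)
      region_map[[nm]] <- iv
    }
  }
  structure(
    list(group_id = as.character(group_id)[1L], names = names,
         rows = rows, region_map = region_map),
    class = "group_alignment"
  )
}

#' @export
print.group_alignment <- function(x, ...) {
  cat("Group alignment '", x$group_id, "': ", length(x$rows),
      " sequences x ", nchar(x$rows[1L]), " columns\n", sep = "")
  if (!is.null(x$region_map))
    for (nm in names(x$region_map))
      cat("  region ", nm, ": ", x$region_map[[nm]][1L], "-",
          x$region_map[[nm]][2L], "\n", sep = "")
  invisible(x)
}

#' Number of alignment columns
#' @param aln A `group_alignment`.
#' @return Integer column count.
#' @export
aln_width <- function(aln) nchar(aln$rows[1L])

#' Alignment as a character matrix (rows = sequences)
#' @param aln A `group_alignment`.
#' @return Character matrix with row names.
#' @export
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
  rownames(m) <- aln$names
  m
}

#' Read a multi-FASTA alignment
#'
#' Reads a (possibly line-wrapped) multi-FASTA file into a
#' [group_alignment()]. Rows are uppercased and `U` is mapped to `T`;
#' unequal row lengths, duplicate names, and empty files are errors.
#'
#' @param path Path to a FASTA file.
#' @param group_id Group label to attach.
#' @return A `group_alignment`.
#' @export
read_alignment <- function(path, group_id = basename(path)) {
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("cannot read FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L)
    stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  group_alignment(as.character(set), ids, group_id = group_id)
}

#' Write an alignment to FASTA
#'
#' Writes `-`-gapped FASTA wrapped at 80 columns.
#'
#' @param aln A `group_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  set <- Biostrings::BStringSet(aln$rows)
  names(set) <- aln$names
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Define a degenerate primer
#'
#' @param name Primer name (e.g. `"TAReuk454FWD1"`).
#' @param iupac Primer sequence over IUPAC codes; degeneracies allowed.
#' @param reference_span Optional 1-based inclusive positions on a
#'   reference sequence (documentation only).
#' @return An object of class `primer_spec`.
#' @export
primer_spec <- function(name, iupac, reference_span = NULL) {
  iupac <- chartr("U", "T", toupper(as.character(iupac)[1L]))
  if (!nzchar(iupac))
    stop("primer sequence is empty", call. = FALSE)
  letters <- strsplit(iupac, "", fixed = TRUE)[[1L]]
  bad <- setdiff(letters, names(IUPAC_CODES))
  if (length(bad))
    stop("invalid IUPAC letters in primer '", name, "': ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  structure(list(name = as.character(name)[1L], iupac = iupac,
                 reference_span = reference_span),
            class = "primer_spec")
}

#' Locate a primer on an ungapped sequence
#'
#' Finds the first exact IUPAC-compatible match of a degenerate primer
#' (each degeneracy matches any of its expansions; no mismatches).
#'
#' @param seq Ungapped nucleotide string.
#' @param primer A [primer_spec()] (or plain IUPAC string).
#' @return Integer `c(start, end)` (1-based, inclusive), or `NULL` when
#'   the primer does not occur.
#' @export
locate_primer <- function(seq, primer) {
  if (!inherits(primer, "primer_spec"))
    primer <- primer_spec("primer", primer)
  seq <- chartr("U", "T", toupper(seq))
  if (grepl("-", seq, fixed = TRUE))
    stop("locate_primer expects an ungapped sequence", call. = FALSE)
  hits <- Biostrings::matchPattern(
    Biostrings::DNAString(primer$iupac), Biostrings::DNAString(seq),
    fixed = "subject"
  )
  if (length(hits) == 0L) return(NULL)
  c(start = Biostrings::start(hits)[1L], end = Biostrings::end(hits)[1L])
}

# Map an ungapped position on one alignment row back to its column.
ungapped_to_column <- function(row, pos) {
  cols <- which(strsplit(row, "", fixed = TRUE)[[1L]] != "-")
  if (pos < 1L || pos > length(cols))
    stop("ungapped position ", pos, " outside sequence of length ",
         length(cols), call. = FALSE)
  cols[pos]
}

#' Extract a sub-alignment by columns or primer pair
#'
#' Cuts an alignment down to a region given either as an explicit column
#' interval or as a forward/reverse primer pair located on a designated
#' ungapped reference row and mapped back to alignment columns. With
#' `drop_primers` the primer-matching columns themselves are excluded,
#' as is conventional when the amplified insert is analysed.
#'
#' @param aln A `group_alignment`.
#' @param region Length-2 integer `c(start, end)` of alignment columns
#'   (1-based inclusive), or a region name present in `aln$region_map`.
#' @param primers List with elements `fwd` and `rev` ([primer_spec()]s);
#'   used when `region` is missing.
#' @param reference Name of the row on which primers are located.
#' @param drop_primers Exclude the primer-matching columns (default TRUE).
#' @return A `group_alignment` restricted to the selected columns.
#' @export
extract_region <- function(aln, region = NULL, primers = NULL,
                           reference = NULL, drop_primers = TRUE) {
  w <- aln_width(aln)
  if (!is.null(region)) {
    if (is.character(region)) {
      if (is.null(aln$region_map[[region]]))
        stop("region '", region, "' not annotated on alignment",
             call. = FALSE)
      region <- aln$region_map[[region]]
    }
    iv <- as.integer(region)
    if (length(iv) != 2L || anyNA(iv) || iv[1L] > iv[2L])
      stop("invalid region interval [", paste(region, collapse = ", "),
           "]: need start <= end", call. = FALSE)
    if (iv[1L] < 1L || iv[2L] > w)
      stop("region [", iv[1L], ", ", iv[2L], "] outside alignment of ",
           w, " columns", call. = FALSE)
  } else {
    if (is.null(primers) || is.null(primers$fwd) || is.null(primers$rev))
      stop("supply either a column interval or fwd/rev primers",
           call. = FALSE)
    if (is.null(reference)) reference <- aln$names[1L]
    ridx <- match(reference, aln$names)
    if (is.na(ridx))
      stop("reference row '", reference, "' not in alignment",
           call. = FALSE)
    ref <- gsub("-", "", aln$rows[ridx], fixed = TRUE)
    f <- locate_primer(ref, primers$fwd)
    r <- locate_primer(ref, primers$rev)
    if (is.null(f) || is.null(r))
      stop("primer not found on reference row '", reference, "'",
           call. = FALSE)
    if (drop_primers) {
      u1 <- f[["end"]] + 1L
      u2 <- r[["start"]] - 1L
    } else {
      u1 <- f[["start"]]
      u2 <- r[["end"]]
    }
    if (u1 > u2)
      stop("primer-delimited region is empty on reference '",
           reference, "'", call. = FALSE)
    iv <- c(ungapped_to_column(aln$rows[ridx], u1),
            ungapped_to_column(aln$rows[ridx], u2))
  }
  rows <- substr(aln$rows, iv[1L], iv[2L])
  group_alignment(rows, aln$names, group_id = aln$group_id)
}

#' Drop sequences shorter than a minimum ungapped length
#'
#' Removes rows whose ungapped length (non-`-` characters) is below
#' `min_ungapped`, preserving the order of survivors; the study filter
#' eliminates sequences shorter than 475 bp before distances are
#' computed. The number removed is reported via `message()`.
#'
#' @param aln A `group_alignment`.
#' @param min_ungapped Minimum ungapped length retained (default 475).
#' @return Filtered `group_alignment`; may have zero rows, in which case
#'   a zero-row marker list is returned.
#' @export
filter_min_length <- function(aln, min_ungapped = 475L) {
  ungapped <- nchar(gsub("-", "", aln$rows, fixed = TRUE))
  keep <- ungapped >= min_ungapped
  n_removed <- sum(!keep)
  if (n_removed > 0L)
    message("filter_min_length: removed ", n_removed, " of ",
            length(keep), " sequences (< ", min_ungapped, " bp) from '",
            aln$group_id, "'")
  if (!any(keep)) {
    return(structure(
      list(group_id = aln$group_id, names = character(0),
           rows = character(0), region_map = aln$region_map),
      class = "group_alignment"
    ))
  }
  out <- group_alignment(aln$rows[keep], aln$names[keep],
                         group_id = aln$group_id)
  out$region_map <- aln$region_map
  out
}

#' Write a region annotation table
#'
#' @param aln A `group_alignment` with a `region_map`.
#' @param path Output TSV path (columns group_id, region_name, start, end).
#' @return `path`, invisibly.
#' @export
write_region_table <- function(aln, path) {
  rm <- aln$region_map
  df <- data.frame(
    group_id = aln$group_id,
    region_name = if (is.null(rm)) character(0) else names(rm),
    start = if (is.null(rm)) integer(0) else
      vapply(rm, `[`, integer(1), 1L),
    end = if (is.null(rm)) integer(0) else
      vapply(rm, `[`, integer(1), 2L)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
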
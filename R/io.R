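## Readers/writers for the external formats the pipeline touches.
## Coordinates are 0-based half-open everywhere, as in BED.

#' Read a BED file of genomic intervals
#'
#' Reads BED3 (or BED4 when a name/label column is present) with strict
#' validation: non-integer coordinates, `start >= end`, or short lines raise
#' a format error naming the offending line. Comment, `track` and `browser`
#' lines are skipped.
#'
#' @param path Path to a tab-separated BED file.
#' @param expected_columns Minimum number of columns each record must have
#'   (3 or 4).
#' @return A data frame with columns `chrom`, `start`, `end` and, when a
#'   fourth column is present, `label`.
#' @export
read_bed <- function(path, expected_columns = 3L) {
  if (!file.exists(path)) param_error(sprintf("file not found: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < expected_columns)
  if (length(bad))
    format_error(sprintf("expected at least %d columns, found %d",
                         expected_columns, nf[bad[1]]),
                 line = idx[bad[1]], path = path)
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start_c <- vapply(fields, `[[`, character(1), 2L)
  end_c <- vapply(fields, `[[`, character(1), 3L)
  start <- suppressWarnings(as.numeric(start_c))
  end <- suppressWarnings(as.numeric(end_c))
  bad <- which(is.na(start) | is.na(end) |
                 start != floor(start) | end != floor(end))
  if (length(bad))
    format_error(sprintf("non-integer coordinates '%s'/'%s'",
                         start_c[bad[1]], end_c[bad[1]]),
                 line = idx[bad[1]], path = path)
  bad <- which(start < 0 | start >= end)
  if (length(bad))
    format_error(sprintf("invalid interval [%d, %d): need 0 <= start < end",
                         as.integer(start[bad[1]]), as.integer(end[bad[1]])),
                 line = idx[bad[1]], path = path)
  bad <- which(!nzchar(chrom))
  if (length(bad))
    format_error("empty chromosome name", line = idx[bad[1]], path = path)
  out <- data.frame(chrom = chrom, start = as.integer(start),
                    end = as.integer(end), stringsAsFactors = FALSE)
  if (any(nf >= 4L))
    out$label <- vapply(fields, function(f)
      if (length(f) >= 4L) f[[4L]] else NA_character_, character(1))
  out
}

#' Write intervals as BED
#'
#' Emits BED3, or BED4 when a `label` (or `state`/`name`) column is present.
#'
#' @param x Data frame with `chrom`, `start`, `end` and optionally a label
#'   column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  label_col <- intersect(c("label", "state", "name"), names(x))
  cols <- x[, c("chrom", "start", "end"), drop = FALSE]
  if (length(label_col)) cols$label <- x[[label_col[1]]]
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Named character vector mapping the header token (before the
#'   first whitespace) to the uppercase sequence.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) param_error(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !startsWith(first, ">"))
    format_error("missing FASTA header line", line = 1L, path = path)
  dss <- Biostrings::readDNAStringSet(path)
  keys <- sub("\\s.*$", "", names(dss))
  if (anyDuplicated(keys))
    format_error(sprintf("duplicate FASTA header '%s'",
                         keys[anyDuplicated(keys)]), path = path)
  if (any(Biostrings::width(dss) == 0L))
    format_error(sprintf("empty sequence for '%s'",
                         keys[which(Biostrings::width(dss) == 0L)[1]]),
                 path = path)
  stats::setNames(toupper(as.character(dss)), keys)
}

#' Write sequences as FASTA (60-column wrap)
#'
#' @param genome Named character vector (chrom -> sequence).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  if (is.null(names(genome))) param_error("`genome` must be named")
  dss <- Biostrings::DNAStringSet(unlist(genome))
  names(dss) <- names(genome)
  Biostrings::writeXStringSet(dss, path, width = 60L)
  invisible(path)
}

#' Construct and validate a peak count table
#'
#' The container for peak-level accessibility counts: peak intervals, a
#' non-negative integer peak-by-sample count matrix, and a sample-to-
#' condition mapping.
#'
#' @param peaks Data frame of peak intervals (`chrom`, `start`, `end`,
#'   optional `name`).
#' @param counts Non-negative integer matrix, `nrow(peaks)` x samples, with
#'   column names matching `names(condition_of)`.
#' @param condition_of Named character vector mapping sample -> condition.
#' @return An object of class `peak_count_table`.
#' @export
peak_count_table <- function(peaks, counts, condition_of) {
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(peaks))
    param_error("count matrix rows must match peaks")
  if (is.null(colnames(counts)) || is.null(names(condition_of)) ||
      !setequal(colnames(counts), names(condition_of)))
    param_error("count matrix columns must match names(condition_of)")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    param_error("counts must be non-negative integers without NA")
  storage.mode(counts) <- "integer"
  condition_of <- condition_of[colnames(counts)]
  if (is.null(peaks$name))
    peaks$name <- paste0("peak_", seq_len(nrow(peaks)))
  structure(list(peaks = peaks, counts = counts,
                 condition_of = condition_of),
            class = "peak_count_table")
}

#' @export
print.peak_count_table <- function(x, ...) {
  cat(sprintf("peak_count_table: %d peaks x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", names(table(x$condition_of)),
                            table(x$condition_of)), collapse = ", ")))
  invisible(x)
}

#' Read a peak count table from TSV
#'
#' Expects a header row `peak_id  chrom  start  end  <sample1> ...` as
#' written by [write_count_table()]. Counts must be non-negative integers;
#' `NA` or negative cells raise a format error.
#'
#' @param path Path to the TSV file.
#' @param condition_of Named character vector mapping sample -> condition.
#' @return A [peak_count_table()].
#' @export
read_count_table <- function(path, condition_of) {
  if (!file.exists(path)) param_error(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  meta <- c("peak_id", "chrom", "start", "end")
  if (!all(meta %in% names(df)))
    format_error(sprintf("missing columns: %s",
                         paste(setdiff(meta, names(df)), collapse = ", ")),
                 path = path)
  samples <- setdiff(names(df), meta)
  if (length(samples) == 0L) format_error("no sample columns", path = path)
  counts <- as.matrix(df[, samples, drop = FALSE])
  if (anyNA(counts))
    format_error(sprintf("NA count at row %d", which(rowSums(is.na(counts)) > 0)[1]),
                 path = path)
  if (any(counts < 0) || any(counts != round(counts)))
    format_error(sprintf("negative or non-integer count at row %d",
                         which(rowSums(counts < 0 | counts != round(counts)) > 0)[1]),
                 path = path)
  peaks <- data.frame(chrom = df$chrom, start = as.integer(df$start),
                      end = as.integer(df$end), name = df$peak_id,
                      stringsAsFactors = FALSE)
  peak_count_table(peaks, counts, condition_of)
}

#' Write a peak count table as TSV
#'
#' @param table A [peak_count_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "peak_count_table"))
  df <- cbind(data.frame(peak_id = table$peaks$name,
                         chrom = table$peaks$chrom,
                         start = table$peaks$start,
                         end = table$peaks$end,
                         stringsAsFactors = FALSE),
              as.data.frame(table$counts))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED12 gene model
#'
#' Parses the 12-column BED gene-model format: thickStart/thickEnd delimit
#' the CDS and the block fields give exon structure. Used by
#' [annotate_feature()].
#'
#' @param path Path to a BED12 file.
#' @return Data frame with one row per transcript: `chrom`, `start`, `end`,
#'   `name`, `strand`, `thick_start`, `thick_end`, and list-columns
#'   `block_starts` (relative to `start`) and `block_sizes`.
#' @export
read_bed12 <- function(path) {
  raw <- read_bed(path, expected_columns = 12L)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  parse_ints <- function(s) as.integer(strsplit(sub(",$", "", s), ",")[[1]])
  out <- raw[, c("chrom", "start", "end")]
  out$name <- vapply(fields, `[[`, character(1), 4L)
  out$strand <- vapply(fields, `[[`, character(1), 6L)
  if (!all(out$strand %in% c("+", "-")))
    format_error("strand must be '+' or '-'", path = path)
  out$thick_start <- as.integer(vapply(fields, `[[`, character(1), 7L))
  out$thick_end <- as.integer(vapply(fields, `[[`, character(1), 8L))
  n_blocks <- as.integer(vapply(fields, `[[`, character(1), 10L))
  out$block_sizes <- lapply(fields, function(f) parse_ints(f[[11L]]))
  out$block_starts <- lapply(fields, function(f) parse_ints(f[[12L]]))
  ok <- mapply(function(n, bs, bst) length(bs) == n && length(bst) == n,
               n_blocks, out$block_sizes, out$block_starts)
  if (!all(ok))
    format_error("block count does not match block lists", path = path)
  out
}
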
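#' Read alignments in the LAST tabular (TAB) dialect
#'
#' Parses the 12-column tabular format emitted by `lastal -f TAB`: score,
#' then name/start/alnSize/strand/seqSize for the reference and for the
#' read, then the blocks string `"n[,d:i,n]*"` encoding gapless segments of
#' `n` aligned columns separated by gaps of `d` reference-skipping and `i`
#' read-skipping bases. Lines beginning `#` are comments. Coordinates are
#' kept 0-based as in the file; for a `-`-strand read they refer to the
#' reverse-complemented read, as the dialect specifies.
#'
#' @param path Path to the alignment file.
#' @return An [AlignmentSet-class] (without read bases).
#' @seealso [attachReadSequences()], [selectBestAlignments()],
#'   [writeLastTab()]
#' @export
readLastTab <- function(path) {
  .parseTab(path, allow_bases = FALSE)
}

#' Read/write the internal alignment TSV
#'
#' The internal dialect is identical to LAST TAB plus an optional 13th
#' column holding the strand-corrected read bases, which lets oracle
#' alignments from the read simulator round-trip through files.
#'
#' @param path File path.
#' @return `readAlignmentTsv()`: an [AlignmentSet-class].
#' @export
readAlignmentTsv <- function(path) {
  .parseTab(path, allow_bases = TRUE)
}

.parseTab <- function(path, allow_bases = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(AlignmentSet(data.frame(
      score = integer(), ref_id = character(), ref_start = integer(),
      ref_aln_size = integer(), ref_strand = character(),
      ref_seq_size = integer(), read_id = character(),
      read_start = integer(), read_aln_size = integer(),
      read_strand = character(), read_seq_size = integer(),
      blocks = character())))
  fields <- strsplit(lines, "\\s+")
  nf <- lengths(fields)
  wanted <- if (allow_bases) c(12L, 13L) else 12L
  bad <- which(!nf %in% wanted)
  if (length(bad))
    stop("parse error at line ", lineno[bad[1]], ": expected ",
         paste(wanted, collapse = " or "), " fields, found ", nf[bad[1]])
  m <- matrix(unlist(lapply(fields, `[`, 1:12)), ncol = 12L, byrow = TRUE)
  numCols <- c(1L, 3L, 4L, 6L, 8L, 9L, 11L)
  nums <- suppressWarnings(matrix(as.integer(m[, numCols]),
                                  ncol = length(numCols)))
  if (anyNA(nums)) {
    badrow <- which(apply(is.na(nums), 1L, any))[1]
    stop("parse error at line ", lineno[badrow],
         ": non-numeric value in a numeric field")
  }
  df <- data.frame(score = nums[, 1], ref_id = m[, 2], ref_start = nums[, 2],
                   ref_aln_size = nums[, 3], ref_strand = m[, 5],
                   ref_seq_size = nums[, 4], read_id = m[, 7],
                   read_start = nums[, 5], read_aln_size = nums[, 6],
                   read_strand = m[, 10], read_seq_size = nums[, 7],
                   blocks = m[, 12])
  if (allow_bases)
    df$read_bases <- vapply(fields, function(f)
      if (length(f) == 13L) f[13] else NA_character_, "")
  AlignmentSet(df)
}

#' Write alignments in the LAST TAB / internal TSV dialect
#'
#' @param x An [AlignmentSet-class].
#' @param path Output path.
#' @param read_bases If `TRUE`, append the 13th read-bases column (internal
#'   dialect); requires bases to be attached.
#' @return The path, invisibly.
#' @export
writeLastTab <- function(x, path, read_bases = FALSE) {
  df <- alignmentRecords(x)
  cols <- df[, .ALN_COLS]
  if (read_bases) {
    if (anyNA(df$read_bases))
      stop("read bases not attached; run attachReadSequences() first")
    cols$read_bases <- df$read_bases
  }
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Attach read bases to alignment records from FASTQ
#'
#' Joins alignments to their reads and stores, per record, the aligned slice
#' of the read in reference orientation: for a `-`-strand record the raw
#' read is reverse-complemented before slicing (LAST TAB read coordinates
#' count on that strand), so `read_bases` compares position-by-position with
#' the reference in pileups.
#'
#' @param x An [AlignmentSet-class].
#' @param reads Path to a FASTQ file, or a named character vector of read
#'   sequences keyed by read id.
#' @return The [AlignmentSet-class] with `read_bases` filled in.
#' @export
attachReadSequences <- function(x, reads) {
  df <- alignmentRecords(x)
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- .readFastqSequences(reads)
  stopifnot(is.character(reads), !is.null(names(reads)))
  missing <- setdiff(unique(df$read_id), names(reads))
  if (length(missing))
    stop("read id(s) missing from FASTQ: ",
         paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) ", ...")
  raw <- unname(reads[df$read_id])
  minus <- df$read_strand == "-"
  if (any(minus)) raw[minus] <- revComp(raw[minus])
  df$read_bases <- substring(raw, df$read_start + 1L,
                             df$read_start + df$read_aln_size)
  AlignmentSet(df)
}

.readFastqSequences <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  # FASTQ headers may carry descriptions after the id
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Select the best-scoring alignment per read
#'
#' Keeps, for each read, the alignment with the maximum score; when several
#' alignments tie at the maximum, a single one is chosen by one uniform draw
#' from a generator seeded with `seed`. Reads are processed in sorted
#' read-id order and reads with a unique best alignment consume no random
#' numbers, so results are reproducible and the seed only influences actual
#' ties.
#'
#' @param x An [AlignmentSet-class].
#' @param seed Integer seed for tie-breaking.
#' @return An [AlignmentSet-class] with exactly one record per distinct
#'   read id, in sorted read-id order.
#' @export
selectBestAlignments <- function(x, seed = 1) {
  df <- alignmentRecords(x)
  if (!nrow(df)) return(AlignmentSet(df))
  if (!anyDuplicated(df$read_id))  # unique best per read: seed irrelevant
    return(AlignmentSet(df[order(df$read_id), , drop = FALSE]))
  groups <- split(seq_len(nrow(df)), df$read_id)  # sorted by read_id
  keep <- integer(length(groups))
  withSeed(seed, {
    for (j in seq_along(groups)) {
      idx <- groups[[j]]
      if (length(idx) == 1L) { keep[j] <- idx; next }
      sc <- df$score[idx]
      cand <- idx[sc == max(sc)]
      keep[j] <- if (length(cand) == 1L) cand
      else cand[floor(stats::runif(1) * length(cand)) + 1L]
    }
  })
  AlignmentSet(df[keep, , drop = FALSE])
}
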
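#' @import methods
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement
#' @importFrom BiocGenerics start
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' Reference sequence set (genome contigs plus integration constructs)
#'
#' A named collection of DNA sequences used as the mapping target for the
#' differential SNP caller and as the substrate for the REMI simulator. The
#' set deliberately mixes chromosomal contigs with plasmid/construct
#' sequences, mirroring how mutant-strain reads are mapped against the host
#' genome together with the integrated expression and REMI plasmids, so that
#' construct-borne mutations (such as a variant inside a secretion-signal
#' coding sequence) are called through the same machinery as genomic ones.
#'
#' @slot sequences A [Biostrings::DNAStringSet] with unique, non-empty names.
#' @slot role Character vector parallel to `sequences`; each element is
#'   `"genome_contig"` or `"construct"`.
#'
#' @seealso [ReferenceSet()], [generateGenome()], [plantSNV()]
#' @export
setClass("ReferenceSet",
  representation(sequences = "DNAStringSet", role = "character"))

setValidity("ReferenceSet", function(object) {
  msg <- character()
  ids <- names(object@sequences)
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
    msg <- c(msg, "all sequences must be named")
  if (anyDuplicated(ids))
    msg <- c(msg, "sequence ids must be unique")
  if (length(object@role) != length(object@sequences))
    msg <- c(msg, "'role' must be parallel to 'sequences'")
  if (!all(object@role %in% c("genome_contig", "construct")))
    msg <- c(msg, "roles must be 'genome_contig' or 'construct'")
  if (any(Biostrings::width(object@sequences) == 0L))
    msg <- c(msg, "sequences must be non-empty")
  bad <- Biostrings::alphabetFrequency(object@sequences, baseOnly = TRUE)
  if (length(object@sequences) && any(bad[, "other"] > 0L))
    msg <- c(msg, "sequences must be over the ACGT(N) alphabet")
  if (length(msg)) msg else TRUE
})

#' Construct a ReferenceSet
#'
#' @param sequences A named [Biostrings::DNAStringSet] or named character
#'   vector of DNA sequences.
#' @param role Character vector of roles (`"genome_contig"` or
#'   `"construct"`), recycled if of length 1.
#' @return A [ReferenceSet-class] object.
#' @examples
#' rs <- ReferenceSet(c(chr1 = "ACGTACGTACGT"), role = "genome_contig")
#' refLengths(rs)
#' @export
ReferenceSet <- function(sequences, role = "genome_contig") {
  if (!is(sequences, "DNAStringSet"))
    sequences <- DNAStringSet(sequences)
  role <- rep_len(role, length(sequences))
  new("ReferenceSet", sequences = sequences, role = role)
}

#' @describeIn ReferenceSet-class Number of sequences in the set.
#' @param x,object A `ReferenceSet`.
#' @export
setMethod("length", "ReferenceSet", function(x) length(x@sequences))

#' @describeIn ReferenceSet-class Sequence ids.
#' @export
setMethod("names", "ReferenceSet", function(x) names(x@sequences))

setMethod("show", "ReferenceSet", function(object) {
  cat(sprintf("ReferenceSet with %d sequence(s), %d bp total\n",
              length(object), sum(Biostrings::width(object@sequences))))
  n <- min(length(object), 6L)
  for (i in seq_len(n))
    cat(sprintf("  %-20s %8d bp  [%s]\n", names(object)[i],
                Biostrings::width(object@sequences)[i], object@role[i]))
  if (length(object) > n) cat("  ...\n")
})

#' Extract sequences or roles from a ReferenceSet
#'
#' `refSequences()` returns the underlying `DNAStringSet` (optionally
#' subset), `refRoles()` the named role vector, and `refLengths()` the named
#' sequence widths.
#'
#' @param x A [ReferenceSet-class].
#' @param ids Optional character vector of sequence ids to subset to.
#' @return A `DNAStringSet`, named character vector, or named integer vector.
#' @export
refSequences <- function(x, ids = NULL) {
  stopifnot(is(x, "ReferenceSet"))
  if (is.null(ids)) x@sequences else {
    missing <- setdiff(ids, names(x))
    if (length(missing))
      stop("unknown sequence id(s): ", paste(missing, collapse = ", "))
    x@sequences[ids]
  }
}

#' @rdname refSequences
#' @export
refRoles <- function(x) {
  stopifnot(is(x, "ReferenceSet"))
  stats::setNames(x@role, names(x))
}

#' @rdname refSequences
#' @export
refLengths <- function(x) {
  stopifnot(is(x, "ReferenceSet"))
  stats::setNames(Biostrings::width(x@sequences), names(x))
}

#' Alignment set in the LAST tabular dialect
#'
#' Holds scored placements of reads on references, one row per alignment.
#' Coordinates are 0-based half-open; the reference strand is always `+` and
#' strand is carried on the read side, matching the 12-column tabular output
#' of the `lastal` aligner (`-f TAB`). The `blocks` column keeps the gapless
#' segment structure as the dialect's `"n[,d:i,n]*"` string, where `d:i`
#' denotes `d` reference-skipping and `i` read-skipping bases. `read_bases`,
#' when attached from FASTQ, is the aligned slice of the read already
#' reverse-complemented to reference orientation.
#'
#' @slot records A `data.frame` with columns `score`, `ref_id`, `ref_start`,
#'   `ref_aln_size`, `ref_strand`, `ref_seq_size`, `read_id`, `read_start`,
#'   `read_aln_size`, `read_strand`, `read_seq_size`, `blocks`, and
#'   optionally `read_bases`.
#'
#' @seealso [readLastTab()], [attachReadSequences()], [selectBestAlignments()]
#' @export
setClass("AlignmentSet", representation(records = "data.frame"))

.ALN_COLS <- c("score", "ref_id", "ref_start", "ref_aln_size", "ref_strand",
               "ref_seq_size", "read_id", "read_start", "read_aln_size",
               "read_strand", "read_seq_size", "blocks")

setValidity("AlignmentSet", function(object) {
  df <- object@records
  msg <- character()
  if (!all(.ALN_COLS %in% names(df)))
    return(paste("missing column(s):",
                 paste(setdiff(.ALN_COLS, names(df)), collapse = ", ")))
  if (nrow(df)) {
    if (!all(df$ref_strand == "+"))
      msg <- c(msg, "reference strand must be '+'")
    if (!all(df$read_strand %in% c("+", "-")))
      msg <- c(msg, "read strand must be '+' or '-'")
    sizes <- blockSizes(df$blocks)
    if (any(sizes$ref != df$ref_aln_size))
      msg <- c(msg, "blocks inconsistent with ref_aln_size")
    if (any(sizes$read != df$read_aln_size))
      msg <- c(msg, "blocks inconsistent with read_aln_size")
    if (any(df$ref_start + df$ref_aln_size > df$ref_seq_size))
      msg <- c(msg, "alignment extends beyond reference end")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AlignmentSet from a record data.frame
#'
#' @param records A `data.frame` with the twelve LAST TAB columns (see
#'   [AlignmentSet-class]) and optionally `read_bases`.
#' @return An [AlignmentSet-class].
#' @export
AlignmentSet <- function(records) {
  if (!"read_bases" %in% names(records))
    records$read_bases <- rep(NA_character_, nrow(records))
  records <- records[, c(.ALN_COLS, "read_bases")]
  rownames(records) <- NULL
  new("AlignmentSet", records = records)
}

#' @describeIn AlignmentSet-class Number of alignment records.
#' @param x,object An `AlignmentSet`.
#' @export
setMethod("length", "AlignmentSet", function(x) nrow(x@records))

setMethod("show", "AlignmentSet", function(object) {
  df <- object@records
  cat(sprintf("AlignmentSet with %d record(s), %d distinct read(s)%s\n",
              nrow(df), length(unique(df$read_id)),
              if (nrow(df) && !anyNA(df$read_bases)) ", read bases attached"
              else ""))
  if (nrow(df))
    print(utils::head(df[, c("score", "ref_id", "ref_start", "read_id",
                             "read_strand", "blocks")], 5L))
})

#' Extract the alignment record table
#'
#' @param x An [AlignmentSet-class].
#' @return The underlying `data.frame` of alignment records.
#' @export
alignmentRecords <- function(x) {
  stopifnot(is(x, "AlignmentSet"))
  x@records
}

#' Result of an in-silico plasmid rescue
#'
#' Captures the outcome of digesting an insertion-mutant sequence with a
#' plasmid-safe enzyme mixture, circularizing the fragment that carries the
#' integrated plasmid, and splitting off the genomic flanks that identify
#' the disrupted locus.
#'
#' @slot fragment_start,fragment_end 0-based half-open interval of the
#'   rescued fragment on the mutant sequence.
#' @slot rescue_sequence The self-ligated (circular) rescue sequence.
#' @slot upstream_flank,downstream_flank Genomic DNA flanking the insert,
#'   in genome orientation.
#' @slot mapped_locus A one-row `data.frame` (`ref_id`, `start`, `end`,
#'   `strand`, `status`) once [locateFlank()] has been applied, else
#'   a zero-row frame.
#' @slot flags Character vector of warnings (e.g. `"empty_flank"`).
#' @export
setClass("RescueResult",
  representation(fragment_start = "integer", fragment_end = "integer",
                 rescue_sequence = "character",
                 upstream_flank = "character", downstream_flank = "character",
                 mapped_locus = "data.frame", flags = "character"))

setMethod("show", "RescueResult", function(object) {
  cat(sprintf("RescueResult: fragment [%d,%d) (%d bp), flanks %d/%d bp\n",
              object@fragment_start, object@fragment_end,
              object@fragment_end - object@fragment_start,
              nchar(object@upstream_flank), nchar(object@downstream_flank)))
  if (nrow(object@mapped_locus))
    cat(sprintf("  locus: %s\n",
        paste(unlist(object@mapped_locus[1, ]), collapse = " ")))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

#' Flank sequences of a rescue result
#'
#' @param x A [RescueResult-class].
#' @return Named character vector with elements `upstream` and `downstream`.
#' @export
rescueFlanks <- function(x) {
  stopifnot(is(x, "RescueResult"))
  c(upstream = x@upstream_flank, downstream = x@downstream_flank)
}

#' @rdname rescueFlanks
#' @export
rescueFlags <- function(x) {
  stopifnot(is(x, "RescueResult"))
  x@flags
}
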
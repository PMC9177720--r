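#' Restriction enzyme definitions
#'
#' Loads an enzyme table (name, IUPAC recognition sequence, top-strand cut
#' offset). The table shipped with the package covers the two linearization
#' enzymes used to open the REMI plasmid (BamHI, KpnI) and the eight-enzyme
#' mixture used to fragment genomic DNA before self-ligation during plasmid
#' rescue (AflII, EcoRI, EcoRV, HpaI, MluI, NheI, SpeI, XhoI); recognition
#' sequences and cut offsets follow standard enzyme reference data. The cut
#' is modeled as a single blunt top-strand coordinate at
#' `site_start + cut_offset`; sticky-end chemistry is abstracted away because
#' only the sequence-level outcome feeds the downstream analysis.
#'
#' @param path Path to a tab-separated enzyme table with columns `name`,
#'   `recognition`, `cut_offset`. Defaults to the shipped table.
#' @param names Optional character vector restricting (and ordering) the
#'   enzymes returned.
#' @return A `data.frame` with columns `name`, `recognition`, `cut_offset`.
#' @examples
#' loadEnzymes(names = c("BamHI", "EcoRI"))
#' @export
loadEnzymes <- function(path = system.file("extdata", "enzymes.tsv",
                                           package = "REMIscreen"),
                        names = NULL) {
  enz <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "recognition", "cut_offset") %in% colnames(enz)))
  enz$recognition <- toupper(enz$recognition)
  .checkEnzymes(enz)
  if (!is.null(names)) {
    missing <- setdiff(names, enz$name)
    if (length(missing))
      stop("enzyme(s) not in table: ", paste(missing, collapse = ", "))
    enz <- enz[match(names, enz$name), , drop = FALSE]
  }
  rownames(enz) <- NULL
  enz
}

#' The eight-enzyme digestion mixture used for plasmid rescue
#'
#' @return A `data.frame` of the eight digestion enzymes (AflII, EcoRI,
#'   EcoRV, HpaI, MluI, NheI, SpeI, XhoI).
#' @export
digestionEnzymes <- function() {
  loadEnzymes(names = c("AflII", "EcoRI", "EcoRV", "HpaI", "MluI", "NheI",
                        "SpeI", "XhoI"))
}

.IUPAC <- Biostrings::IUPAC_CODE_MAP

.checkEnzymes <- function(enz) {
  for (i in seq_len(nrow(enz))) {
    rec <- enz$recognition[i]
    if (nchar(rec) < 4L)
      stop("enzyme ", enz$name[i], ": recognition shorter than 4 bp")
    letters <- strsplit(rec, "")[[1]]
    bad <- setdiff(letters, names(.IUPAC))
    if (length(bad))
      stop("enzyme ", enz$name[i], ": invalid IUPAC letter(s) ",
           paste(bad, collapse = ""))
    off <- enz$cut_offset[i]
    if (off < 0L || off > nchar(rec))
      stop("enzyme ", enz$name[i], ": cut_offset outside recognition site")
  }
  invisible(enz)
}

.isPalindromic <- function(recognition) {
  as.character(reverseComplement(DNAString(recognition))) == recognition
}

#' Locate restriction recognition sites
#'
#' Scans a sequence for all matches of an enzyme's IUPAC recognition pattern.
#' Both strands are considered; for palindromic sites the two strands
#' coincide and each site is reported once. Positions are 0-based top-strand
#' starts. For circular molecules the scan wraps across the origin, so a
#' site spanning the sequence end is found — this is what makes the
#' "absent from the plasmid" safety check on the circular REMI plasmid exact.
#'
#' @param seq A DNA string (character or `DNAString`) over ACGT.
#' @param enzyme A one-row `data.frame` from [loadEnzymes()] (or any list
#'   with `name`, `recognition`, `cut_offset`).
#' @param circular Treat `seq` as circular?
#' @return Sorted integer vector of 0-based site start positions. The
#'   attribute `"strand"` gives the matched strand per site.
#' @examples
#' bam <- loadEnzymes(names = "BamHI")
#' findSites("AAGGATCCTT", bam)          # 2
#' findSites("TCCAAAGGA", bam, circular = TRUE)  # wraps: site at 6
#' @export
findSites <- function(seq, enzyme, circular = FALSE) {
  seq <- as.character(seq)
  rec <- enzyme$recognition[1]
  .checkEnzymes(as.data.frame(enzyme)[1, , drop = FALSE])
  k <- nchar(rec)
  n <- nchar(seq)
  if (!circular && k > n)
    return(structure(integer(), strand = character()))
  if (circular && k > n)
    stop("recognition site longer than the circular molecule")
  subject <- if (circular && n >= 2L)
    paste0(seq, substr(seq, 1L, min(k - 1L, n))) else seq
  hit0 <- function(pattern) {
    m <- Biostrings::matchPattern(DNAString(pattern), DNAString(subject),
                                  fixed = FALSE)
    BiocGenerics::start(m) - 1L
  }
  fwd <- hit0(rec)
  if (.isPalindromic(rec)) {
    pos <- fwd
    strand <- rep("+", length(pos))
  } else {
    rev <- hit0(as.character(reverseComplement(DNAString(rec))))
    pos <- c(fwd, rev)
    strand <- rep(c("+", "-"), c(length(fwd), length(rev)))
  }
  if (circular) {
    keep <- pos < n
    pos <- pos[keep] %% n
    strand <- strand[keep]
  }
  o <- order(pos)
  structure(as.integer(pos[o]), strand = strand[o])
}

# 0-based cut coordinates (top strand) for one enzyme on a sequence.  For a
# bottom-strand match of a non-palindromic site the offset mirrors so the cut
# falls at the equivalent position on the top strand.
.cutPositions <- function(seq, enzyme, circular) {
  sites <- findSites(seq, enzyme, circular = circular)
  if (!length(sites)) return(integer())
  strand <- attr(sites, "strand")
  k <- nchar(enzyme$recognition[1])
  off <- ifelse(strand == "+", enzyme$cut_offset[1], k - enzyme$cut_offset[1])
  cuts <- as.integer(sites) + as.integer(off)
  n <- nchar(as.character(seq))
  if (circular) cuts <- cuts %% n else cuts <- cuts[cuts >= 0L & cuts <= n]
  sort(unique(cuts))
}

#' Linearize a circular plasmid at a unique restriction site
#'
#' Requires exactly one recognition site for the enzyme on the circular
#' molecule (as when the REMI plasmid is opened with BamHI or KpnI before
#' electroporation). The output is the full-length sequence opened at the
#' cut coordinate; because the cut site is unique, any rotation of the input
#' yields the identical linear molecule.
#'
#' @param plasmid Circular DNA (character or `DNAString`).
#' @param enzyme One-row enzyme `data.frame`.
#' @return Linear DNA as a character string, same length as the input.
#' @export
linearizePlasmid <- function(plasmid, enzyme) {
  plasmid <- as.character(plasmid)
  sites <- findSites(plasmid, enzyme, circular = TRUE)
  if (length(sites) != 1L)
    stop("linearization with ", enzyme$name[1], " requires exactly 1 site, ",
         "found ", length(sites))
  cut <- .cutPositions(plasmid, enzyme, circular = TRUE)[1]
  n <- nchar(plasmid)
  if (cut == 0L) plasmid
  else paste0(substr(plasmid, cut + 1L, n), substr(plasmid, 1L, cut))
}

#' Check that no enzyme of a digestion set cuts a plasmid
#'
#' The plasmid-rescue protocol digests mutant genomic DNA with enzymes that
#' must all be absent from the integrated plasmid, so the insert plus its
#' genomic flanks survives as one fragment. This validates that property by
#' a circular scan of every enzyme.
#'
#' @param plasmid Circular plasmid sequence.
#' @param enzymes Enzyme `data.frame` (multiple rows).
#' @return A list with `pass` (logical) and `violations` (a `data.frame` of
#'   enzyme name and 0-based site position for every offending site).
#' @export
validateDigestionSet <- function(plasmid, enzymes) {
  viol <- list()
  for (i in seq_len(nrow(enzymes))) {
    sites <- findSites(plasmid, enzymes[i, , drop = FALSE], circular = TRUE)
    if (length(sites))
      viol[[length(viol) + 1L]] <- data.frame(
        name = enzymes$name[i], position = as.integer(sites))
  }
  violations <- if (length(viol)) do.call(rbind, viol)
  else data.frame(name = character(), position = integer())
  list(pass = nrow(violations) == 0L, violations = violations)
}

#' Integrate a linearized insert into a genome sequence
#'
#' Models NHEJ-mediated random integration of a linearized plasmid: the
#' insert (or its reverse complement, for `orientation = "reverse"`) is
#' spliced in before the 0-based `position`, conserving every genomic base.
#'
#' @param genome Genomic DNA (character or `DNAString`).
#' @param insert Linearized insert DNA.
#' @param position 0-based insertion point, `0 <= position <= nchar(genome)`;
#'   insertion occurs before this base.
#' @param orientation `"forward"` or `"reverse"`.
#' @param target_ref_id Optional id recorded in the returned event.
#' @param linearizing_enzyme Optional enzyme name recorded in the event.
#' @return A list with `sequence` (the mutant DNA) and `event` (a one-row
#'   `data.frame` describing the insertion).
#' @export
integrateInsert <- function(genome, insert, position,
                            orientation = c("forward", "reverse"),
                            target_ref_id = "genome",
                            linearizing_enzyme = NA_character_) {
  genome <- as.character(genome); insert <- as.character(insert)
  orientation <- match.arg(orientation)
  n <- nchar(genome)
  if (!nchar(insert)) stop("insert sequence must be non-empty")
  if (position < 0L || position > n)
    stop("insertion position ", position, " outside [0, ", n, "]")
  block <- if (orientation == "reverse") revComp(insert) else insert
  mutant <- paste0(substr(genome, 1L, position), block,
                   substr(genome, position + 1L, n))
  list(sequence = mutant,
       event = data.frame(target_ref_id = target_ref_id,
                          insertion_position = as.integer(position),
                          orientation = orientation,
                          insert_length = nchar(insert),
                          linearizing_enzyme = linearizing_enzyme))
}

#' Digest a sequence with a set of restriction enzymes
#'
#' Cut coordinates are the union over all enzymes of site start plus cut
#' offset, deduplicated and sorted. A linear molecule with `k` cuts yields
#' `k + 1` fragments; a circular one with `k >= 1` cuts yields `k` linear
#' fragments (an uncut circle is returned whole). Fragment concatenation in
#' order reconstructs the input (up to rotation for circular molecules).
#'
#' @param seq DNA sequence.
#' @param enzymes Enzyme `data.frame`.
#' @param circular Is the molecule circular?
#' @return A `data.frame` with columns `start`, `end` (0-based half-open on
#'   the input; circular fragments may wrap so `end` can exceed the length)
#'   and `sequence`.
#' @export
digestSequence <- function(seq, enzymes, circular = FALSE) {
  seq <- as.character(seq)
  n <- nchar(seq)
  cuts <- sort(unique(unlist(lapply(seq_len(nrow(enzymes)), function(i)
    .cutPositions(seq, enzymes[i, , drop = FALSE], circular = circular)))))
  if (circular) {
    if (!length(cuts))
      return(data.frame(start = 0L, end = n, sequence = seq))
    doubled <- paste0(seq, seq)
    start <- cuts
    end <- c(cuts[-1], cuts[1] + n)
    data.frame(start = start, end = end,
               sequence = substring(doubled, start + 1L, end))
  } else {
    bounds <- unique(c(0L, cuts, n))
    start <- bounds[-length(bounds)]
    end <- bounds[-1]
    data.frame(start = start, end = end,
               sequence = substring(seq, start + 1L, end))
  }
}

#' Rescue the integrated plasmid and its genomic flanks
#'
#' Simulates the plasmid-rescue genotyping step: the mutant sequence is
#' digested with the plasmid-safe enzyme mixture, the unique fragment
#' containing the insert is selected and circularized by self-ligation, and
#' the genomic DNA on either side of the insert is split into upstream and
#' downstream flanks (in genome orientation) which identify the disrupted
#' locus via [locateFlank()].
#'
#' @param mutant Mutant (insertion-bearing) linear DNA.
#' @param insert The full inserted plasmid sequence as integrated (i.e. the
#'   linearized plasmid); it doubles as the marker that identifies the
#'   plasmid-bearing fragment.
#' @param enzymes Digestion enzyme `data.frame` (e.g. [digestionEnzymes()]).
#' @return A [RescueResult-class].
#' @export
rescuePlasmid <- function(mutant, insert, enzymes) {
  mutant <- as.character(mutant); insert <- as.character(insert)
  hitFwd <- .allOccurrences(mutant, insert)
  hitRev <- .allOccurrences(mutant, revComp(insert))
  hits <- sort(unique(c(hitFwd, hitRev)))  # palindromic inserts hit twice
  if (!length(hits))
    stop("rescue error: insert marker not found in mutant sequence")
  if (length(hits) > 1L)
    stop("rescue error: insert marker occurs ", length(hits), " times")
  ins_start <- hits[1]
  ins_end <- ins_start + nchar(insert)

  frags <- digestSequence(mutant, enzymes, circular = FALSE)
  containing <- which(frags$start <= ins_start & frags$end >= ins_end)
  if (!length(containing)) {
    inside <- enzymes$name[vapply(seq_len(nrow(enzymes)), function(i) {
      any(.cutPositions(mutant, enzymes[i, , drop = FALSE], FALSE) > ins_start &
          .cutPositions(mutant, enzymes[i, , drop = FALSE], FALSE) < ins_end)
    }, logical(1))]
    stop("protocol violation: insert split across fragments by enzyme(s) ",
         paste(inside, collapse = ", "))
  }
  fr <- frags[containing[1], ]
  upstream <- substr(mutant, fr$start + 1L, ins_start)
  downstream <- substr(mutant, ins_end + 1L, fr$end)
  flags <- character()
  if (!nchar(upstream) || !nchar(downstream))
    flags <- c(flags, "empty_flank")
  # Self-ligation: the fragment joined end-to-start into a circle.
  new("RescueResult",
      fragment_start = as.integer(fr$start), fragment_end = as.integer(fr$end),
      rescue_sequence = fr$sequence,
      upstream_flank = upstream, downstream_flank = downstream,
      mapped_locus = data.frame(ref_id = character(), start = integer(),
                                end = integer(), strand = character(),
                                status = character()),
      flags = flags)
}

.allOccurrences <- function(subject, pattern) {
  if (!nchar(pattern) || nchar(pattern) > nchar(subject)) return(integer())
  m <- Biostrings::matchPattern(DNAString(pattern), DNAString(subject))
  BiocGenerics::start(m) - 1L
}

#' Map a rescued flank back to the genome
#'
#' Exact substring search of a flank (both strands) against the genome
#' contigs of a reference set, mimicking how the Sanger-sequenced flank of a
#' rescued plasmid identifies the plasmid-integration locus. Flanks shorter
#' than `min_length` are reported unmapped; multiple hits (e.g. a flank
#' drawn from a repeated segment) are reported ambiguous with the hit count.
#'
#' @param flank Flank DNA (character).
#' @param refset A [ReferenceSet-class]; only `genome_contig` entries are
#'   searched.
#' @param min_length Minimum flank length considered mappable (bp).
#' @return A one-row `data.frame` with `ref_id`, `start`, `end` (0-based
#'   half-open), `strand`, `status` (`"unique"`, `"unmapped"` or
#'   `"ambiguous"`) and `n_hits`.
#' @export
locateFlank <- function(flank, refset, min_length = 20L) {
  stopifnot(is(refset, "ReferenceSet"))
  flank <- as.character(flank)
  empty <- data.frame(ref_id = NA_character_, start = NA_integer_,
                      end = NA_integer_, strand = NA_character_,
                      status = "unmapped", n_hits = 0L)
  if (nchar(flank) < min_length) return(empty)
  contigs <- names(refset)[refRoles(refset) == "genome_contig"]
  hits <- list()
  for (id in contigs) {
    subject <- as.character(refSequences(refset, id)[[1]])
    for (str in c("+", "-")) {
      pat <- if (str == "+") flank else revComp(flank)
      pos <- .allOccurrences(subject, pat)
      if (length(pos))
        hits[[length(hits) + 1L]] <- data.frame(
          ref_id = id, start = as.integer(pos),
          end = as.integer(pos + nchar(flank)), strand = str)
    }
  }
  if (!length(hits)) return(empty)
  hits <- do.call(rbind, hits)
  if (nrow(hits) == 1L)
    cbind(hits, status = "unique", n_hits = 1L)
  else
    data.frame(ref_id = NA_character_, start = NA_integer_,
               end = NA_integer_, strand = NA_character_,
               status = "ambiguous", n_hits = nrow(hits))
}

#' Full in-silico REMI genotyping round trip
#'
#' Convenience wrapper: rescue the plasmid from a mutant and map both flanks,
#' preferring the longer flank and falling back to the other if the first is
#' unmappable. Returns the rescue result with `mapped_locus` filled in.
#'
#' @inheritParams rescuePlasmid
#' @param refset [ReferenceSet-class] holding the uninserted genome.
#' @param min_length Passed to [locateFlank()].
#' @return A [RescueResult-class] with `mapped_locus` populated.
#' @export
identifyLocus <- function(mutant, insert, enzymes, refset, min_length = 20L) {
  res <- rescuePlasmid(mutant, insert, enzymes)
  flanks <- rescueFlanks(res)
  ord <- order(nchar(flanks), decreasing = TRUE)
  locus <- NULL
  for (fl in flanks[ord]) {
    locus <- locateFlank(fl, refset, min_length = min_length)
    if (locus$status == "unique") break
  }
  res@mapped_locus <- locus
  res
}
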
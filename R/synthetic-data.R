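#' Generate a random genome contig
#'
#' Draws an i.i.d. nucleotide sequence at a target GC content, the base
#' substrate for the simulated host genome. For sequences of at least 10 kb
#' the empirical GC fraction lands within about 3 percentage points of the
#' target.
#'
#' @param length Sequence length in bp (>= 1000).
#' @param gc_fraction Target GC content in `[0, 1]`.
#' @param seed Integer seed; identical arguments and seed give identical
#'   output.
#' @param id Sequence id for the returned entry.
#' @return A [ReferenceSet-class] with a single `genome_contig` entry.
#' @examples
#' rs <- generateGenome(2000, gc_fraction = 0.41, seed = 1)
#' refLengths(rs)
#' @export
generateGenome <- function(length, gc_fraction = 0.5, seed = 1,
                           id = "chr1") {
  if (length < 1000)
    stop("genome length must be at least 1000 bp, got ", length)
  stopifnot(gc_fraction >= 0, gc_fraction <= 1)
  seq <- withSeed(seed, .randomDna(length, gc_fraction))
  ReferenceSet(stats::setNames(DNAStringSet(seq), id),
               role = "genome_contig")
}

.randomDna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a plasmid satisfying restriction-site constraints
#'
#' Builds a random circular plasmid that carries exactly one recognition
#' site for each `must_have_single` enzyme (so it can be linearized
#' unambiguously, as the REMI plasmid is with BamHI or KpnI) and no site at
#' all — scanned circularly — for any `must_lack` enzyme (so the rescue
#' digestion mixture cannot cut it). Generation is by rejection/repair
#' sampling: required sites are planted at non-overlapping positions and
#' every stray site is destroyed by point mutation until the constraints
#' hold, within an iteration budget.
#'
#' @param size Plasmid size in bp.
#' @param must_have_single Enzyme `data.frame` whose sites must occur
#'   exactly once; recognition sequences must be concrete (ACGT).
#' @param must_lack Enzyme `data.frame` whose sites must be absent.
#' @param seed Integer seed.
#' @param max_iter Repair iteration budget.
#' @return The circular plasmid as a character string of length `size`.
#' @examples
#' enz <- loadEnzymes()
#' p <- generatePlasmid(3000, must_have_single = enz[enz$name == "BamHI", ],
#'                      must_lack = enz[enz$name == "EcoRI", ], seed = 3)
#' length(findSites(p, enz[enz$name == "BamHI", ], circular = TRUE))
#' @export
generatePlasmid <- function(size, must_have_single = NULL, must_lack = NULL,
                            seed = 1, max_iter = 500L) {
  have <- if (is.null(must_have_single))
    loadEnzymes()[0, ] else must_have_single
  lack <- if (is.null(must_lack)) loadEnzymes()[0, ] else must_lack
  if (length(intersect(have$recognition, lack$recognition)))
    stop("must_have_single and must_lack share a recognition sequence")
  if (nrow(have) && any(grepl("[^ACGT]", have$recognition)))
    stop("must_have_single recognition sequences must be concrete ACGT")
  # A required site that itself contains (on either strand) the site of a
  # forbidden enzyme can never be planted; fail fast naming the enzyme.
  for (i in seq_len(nrow(lack))) {
    for (j in seq_len(nrow(have))) {
      if (length(findSites(have$recognition[j], lack[i, , drop = FALSE])))
        stop("unsatisfiable constraints: ", lack$name[i],
             " site inside the required ", have$name[j], " site")
    }
  }
  if (nrow(have) && size < nrow(have) * (max(nchar(have$recognition)) + 2L) * 2L)
    stop("plasmid size too small for the required sites")

  withSeed(seed, {
    seq <- .randomDna(size)
    # Plant required sites at spread-out positions away from the origin so
    # they cannot overlap each other or wrap.
    planted <- data.frame(start = integer(), end = integer())
    if (nrow(have)) {
      slots <- floor(size * (seq_len(nrow(have)) - 0.5) / (nrow(have) + 0.5))
      for (j in seq_len(nrow(have))) {
        rec <- have$recognition[j]
        substr(seq, slots[j] + 1L, slots[j] + nchar(rec)) <- rec
        planted <- rbind(planted, data.frame(
          start = slots[j], end = slots[j] + nchar(rec)))
      }
    }
    allEnz <- rbind(have, lack)
    for (iter in seq_len(max_iter)) {
      bad <- NULL
      for (i in seq_len(nrow(allEnz))) {
        e <- allEnz[i, , drop = FALSE]
        sites <- as.integer(findSites(seq, e, circular = TRUE))
        wanted <- if (e$name %in% have$name)
          sites[vapply(sites, function(s)
            any(planted$start == s), logical(1))] else integer()
        extra <- setdiff(sites, wanted)
        if (e$name %in% have$name && length(wanted) != 1L)
          stop("generation failure: required ", e$name,
               " site destroyed during repair")
        if (length(extra)) { bad <- list(enzyme = e, site = extra[1]); break }
      }
      if (is.null(bad)) return(seq)
      # Destroy the stray site: mutate one of its bases lying outside every
      # planted interval.
      k <- nchar(bad$enzyme$recognition)
      cand <- (bad$site + seq_len(k) - 1L) %% size
      ok <- !vapply(cand, function(p)
        any(p >= planted$start & p < planted$end), logical(1))
      if (!any(ok))
        stop("generation failure: cannot repair ", bad$enzyme$name,
             " site overlapping a required site")
      p <- sample(cand[ok], 1L)
      cur <- substr(seq, p + 1L, p + 1L)
      substr(seq, p + 1L, p + 1L) <- sample(setdiff(c("A", "C", "G", "T"),
                                                    cur), 1L)
    }
    stop("generation failure: constraints unsatisfied after ", max_iter,
         " repair iterations")
  })
}

#' Plant a single-nucleotide variant in a reference set
#'
#' Returns a modified copy of the reference set in which exactly one base
#' differs, together with a ground-truth record. Used to emulate a
#' near-clonal point mutation in a mutant strain (the host keeps the
#' unmodified set).
#'
#' @param refset A [ReferenceSet-class].
#' @param sequence_id Id of the sequence to edit.
#' @param position 0-based position of the variant.
#' @param alt_base Alternative base; must differ from the reference base.
#' @param purity Mutant allele purity in `(0, 1]`: the expected fraction of
#'   mutant-strain reads carrying the alternative base (1 = clonal).
#' @return A list with `refset` (the edited copy) and `truth` (a one-row
#'   `data.frame`: `sequence_id`, `position`, `ref_base`, `alt_base`,
#'   `purity`).
#' @export
plantSNV <- function(refset, sequence_id, position, alt_base, purity = 1.0) {
  stopifnot(is(refset, "ReferenceSet"))
  if (purity <= 0 || purity > 1) stop("purity must be in (0, 1]")
  seqs <- refSequences(refset)
  if (!sequence_id %in% names(seqs))
    stop("unknown sequence id: ", sequence_id)
  len <- refLengths(refset)[[sequence_id]]
  if (position < 0L || position >= len)
    stop("position ", position, " outside [0, ", len, ")")
  s <- as.character(seqs[[sequence_id]])
  ref_base <- substr(s, position + 1L, position + 1L)
  if (identical(ref_base, toupper(alt_base)))
    stop("alt base equals the reference base (", ref_base, ") at ", position)
  substr(s, position + 1L, position + 1L) <- toupper(alt_base)
  seqs[[sequence_id]] <- DNAString(s)
  out <- new("ReferenceSet", sequences = seqs, role = refset@role)
  list(refset = out,
       truth = data.frame(sequence_id = sequence_id,
                          position = as.integer(position),
                          ref_base = ref_base, alt_base = toupper(alt_base),
                          purity = purity))
}

#' Simulate single-end sequencing reads with oracle alignments
#'
#' Draws uniformly placed, fixed-length single-end reads from every sequence
#' of the reference set, applies i.i.d. substitution errors, and returns the
#' reads together with their true placements as oracle alignment records
#' (score = matches minus mismatches, one ungapped block). Minus-strand
#' reads are reverse-complemented in the FASTQ output and their oracle
#' record carries the `-` read strand. If `ground_truth` rows (from
#' [plantSNV()]) have `purity < 1`, reads covering the variant revert to
#' the host base with probability `1 - purity`, so the expected fraction of
#' variant-carrying reads equals the purity.
#'
#' @param refset [ReferenceSet-class] to sequence (for a mutant strain, the
#'   edited copy from [plantSNV()]).
#' @param mean_coverage Mean per-base coverage (> 0).
#' @param read_length Read length in bp; must not exceed the shortest
#'   reference sequence.
#' @param error_rate Per-base substitution error rate in `[0, 0.1]`.
#' @param ground_truth Optional `data.frame` of planted variants.
#' @param seed Integer seed.
#' @param id_prefix Prefix for read ids.
#' @return A list with `reads` (a `data.frame`: `read_id`, `sequence` in
#'   sequencing orientation, `quality`), `alignments` (an
#'   [AlignmentSet-class] of oracle records with `read_bases` attached in
#'   reference orientation) and `origins` (a `data.frame` of true origins
#'   and per-read mismatch counts).
#' @export
simulateReads <- function(refset, mean_coverage = 30, read_length = 150L,
                          error_rate = 0, ground_truth = NULL, seed = 1,
                          id_prefix = "r") {
  stopifnot(is(refset, "ReferenceSet"))
  if (mean_coverage <= 0) stop("mean_coverage must be positive")
  if (error_rate < 0 || error_rate > 0.1)
    stop("error_rate must be in [0, 0.1]")
  lens <- refLengths(refset)
  if (read_length > min(lens))
    stop("read_length exceeds the shortest reference sequence")
  L <- as.integer(read_length)
  withSeed(seed, {
    perRef <- lapply(names(lens), function(id) {
      n <- max(1L, as.integer(round(mean_coverage * lens[[id]] / L)))
      start <- sample.int(lens[[id]] - L + 1L, n, replace = TRUE) - 1L
      strand <- sample(c("+", "-"), n, replace = TRUE)
      refchr <- as.character(refSequences(refset, id)[[1]])
      origin <- substring(refchr, start + 1L, start + L)
      reads <- origin
      # allele purity: revert the planted alt base on a purity-determined
      # subset of covering reads (a reverted base mismatches the mutant
      # reference, so it counts toward the oracle score)
      flips <- integer()
      gt <- ground_truth[ground_truth$sequence_id == id &
                           ground_truth$purity < 1, , drop = FALSE]
      for (g in seq_len(NROW(gt))) {
        pos <- gt$position[g]
        cov <- which(start <= pos & pos < start + L)
        flip <- cov[stats::runif(length(cov)) > gt$purity[g]]
        for (i in flip)
          substr(reads[i], pos - start[i] + 1L, pos - start[i] + 1L) <-
            gt$ref_base[g]
        flips <- c(flips, (flip - 1L) * L + (pos - start[flip] + 1L))
      }
      list(id = id, start = start, strand = strand, reads = reads,
           origin = origin, flips = flips)
    })
    start <- unlist(lapply(perRef, `[[`, "start"))
    strand <- unlist(lapply(perRef, `[[`, "strand"))
    reads <- unlist(lapply(perRef, `[[`, "reads"))
    nPer <- vapply(perRef, function(p) length(p$start), 0L)
    refid <- rep(vapply(perRef, `[[`, "", "id"), nPer)
    flips <- unlist(Map(function(p, off) p$flips + off,
                        perRef, c(0L, cumsum(nPer * L))[seq_along(perRef)]))
    n <- length(reads)
    total <- n * L
    # i.i.d. substitution errors over the flattened base stream
    hit <- integer()
    if (error_rate > 0) {
      k <- stats::rbinom(1L, total, error_rate)
      if (k > 0L) {
        big <- paste(reads, collapse = "")
        hit <- sort(sample.int(total, k))
        cur <- substring(big, hit, hit)
        alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
        pick <- ceiling(stats::runif(k) * 3)
        newc <- substr(alt[cur], pick, pick)
        segs <- substring(big, c(1L, hit + 1L), c(hit - 1L, total))
        big <- paste0(paste0(segs[seq_len(k)], newc, collapse = ""),
                      segs[k + 1L])
        off <- (seq_len(n) - 1L) * L
        reads <- substring(big, off + 1L, off + L)
      }
    }
    # mismatches vs the reference can only sit at modified coordinates
    mism <- integer(n)
    modified <- sort(unique(c(hit, flips)))
    if (length(modified)) {
      bigNew <- paste(reads, collapse = "")
      bigOri <- paste(unlist(lapply(perRef, `[[`, "origin")), collapse = "")
      diff <- substring(bigNew, modified, modified) !=
        substring(bigOri, modified, modified)
      mism <- tabulate((modified[diff] - 1L) %/% L + 1L, nbins = n)
    }
    read_id <- sprintf("%s%06d", id_prefix, seq_len(n))
    minus <- strand == "-"
    fastq_seq <- reads
    if (any(minus)) fastq_seq[minus] <- revComp(reads[minus])
    aln <- AlignmentSet(data.frame(
      score = L - 2L * mism, ref_id = refid, ref_start = start,
      ref_aln_size = L, ref_strand = "+",
      ref_seq_size = as.integer(lens[refid]),
      read_id = read_id, read_start = 0L, read_aln_size = L,
      read_strand = strand, read_seq_size = L,
      blocks = as.character(L), read_bases = reads))
    list(reads = data.frame(read_id = read_id, sequence = fastq_seq,
                            quality = strrep("?", L)),
         alignments = aln,
         origins = data.frame(read_id = read_id, sequence_id = refid,
                              start = start, strand = strand,
                              n_errors = mism))
  })
}

#' Write references, reads and ground truth to standard text formats
#'
#' `writeReferenceFasta()` writes a [ReferenceSet-class] as FASTA;
#' `writeReadsFastq()` writes simulated reads as Sanger/Phred+33 FASTQ with
#' a constant Q30 placeholder quality; `writeGroundTruthTsv()` writes a
#' planted-variant table as TSV.
#'
#' @param refset A [ReferenceSet-class].
#' @param reads The `reads` `data.frame` from [simulateReads()].
#' @param truth A ground-truth `data.frame` from [plantSNV()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
writeReferenceFasta <- function(refset, path) {
  stopifnot(is(refset, "ReferenceSet"))
  Biostrings::writeXStringSet(refSequences(refset), path)
  invisible(path)
}

#' @rdname writeReferenceFasta
#' @export
writeReadsFastq <- function(reads, path) {
  x <- DNAStringSet(stats::setNames(reads$sequence, reads$read_id))
  q <- Biostrings::PhredQuality(reads$quality)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' @rdname writeReferenceFasta
#' @export
writeGroundTruthTsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
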
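# Shared fixture builders and independent brute-force oracles.

# Small genome + construct reference set with a planted construct variant.
makeSmallStudySet <- function(genome_bp = 6000, plasmid_bp = 1200,
                              snv_pos = 400L, seed = 101) {
  enz <- loadEnzymes()
  g <- generateGenome(genome_bp, gc_fraction = 0.41, seed = seed)
  p <- generatePlasmid(plasmid_bp,
                       must_have_single = enz[enz$name %in% c("BamHI", "KpnI"), ],
                       must_lack = digestionEnzymes(), seed = seed + 1)
  rs <- ReferenceSet(
    c(refSequences(g), Biostrings::DNAStringSet(c(construct = p))),
    role = c("genome_contig", "construct"))
  ref_base <- substr(p, snv_pos + 1L, snv_pos + 1L)
  alt <- switch(ref_base, A = "G", C = "T", G = "A", T = "C")
  planted <- plantSNV(rs, "construct", snv_pos, alt)
  list(host = rs, mutant = planted$refset, truth = planted$truth,
       plasmid = p, enzymes = enz)
}

# Brute-force IUPAC site scan (independent of findSites): slide a window
# over the (optionally rotated) sequence and compare letter sets.
bruteForceSites <- function(seq, recognition, circular = FALSE) {
  iupac <- Biostrings::IUPAC_CODE_MAP
  matches1 <- function(s, pat) {
    sc <- strsplit(s, "")[[1]]
    pc <- strsplit(pat, "")[[1]]
    all(mapply(function(a, b) grepl(a, iupac[[b]], fixed = TRUE), sc, pc))
  }
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  pats <- unique(c(recognition, rc(recognition)))
  n <- nchar(seq)
  k <- nchar(recognition)
  subject <- if (circular) paste0(seq, substr(seq, 1, k - 1)) else seq
  hits <- integer()
  for (i in seq_len(nchar(subject) - k + 1)) {
    w <- substr(subject, i, i + k - 1)
    if (any(vapply(pats, function(p) matches1(w, p), logical(1))))
      hits <- c(hits, i - 1L)
  }
  sort(unique(hits %% n))
}

# Brute-force per-position base tally from alignment records (ungapped
# records only), independent of buildPileup.
bruteForcePileup <- function(aln, refset) {
  df <- alignmentRecords(aln)
  tallies <- list()
  for (i in seq_len(nrow(df))) {
    bases <- strsplit(df$read_bases[i], "")[[1]]
    for (k in seq_along(bases)) {
      key <- paste(df$ref_id[i], df$ref_start[i] + k - 1L)
      if (is.null(tallies[[key]]))
        tallies[[key]] <- c(A = 0L, C = 0L, G = 0L, T = 0L)
      if (bases[k] %in% c("A", "C", "G", "T"))
        tallies[[key]][bases[k]] <- tallies[[key]][bases[k]] + 1L
    }
  }
  tallies
}

randomPlateFixture <- function(multipliers, seed = 1, blank = 0.05) {
  set.seed(seed)
  strains <- names(multipliers)
  host_signal <- 0.8
  wells <- c(sprintf("%s%d", rep(LETTERS[1:8], each = 12), rep(1:12, 8)))
  n <- length(strains)
  data.frame(
    plate_id = "P1",
    well = wells[seq_len(n + 3)],
    strain_id = c(strains, "host", "host", "blank"),
    role = c(rep("sample", n), "host_control", "host_control", "blank"),
    signal = c(blank + host_signal * unname(multipliers),
               blank + host_signal, blank + host_signal, blank))
}
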
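test_that("findSites locates IUPAC sites on both strands and across the origin", {
  bam <- loadEnzymes(names = "BamHI")
  expect_identical(as.integer(findSites("GGATCCA", bam)), 0L)
  expect_identical(as.integer(findSites("AAGGATCCTT", bam)), 2L)
  # circular: site spanning the origin
  expect_identical(as.integer(findSites("TCCAGGA", bam, circular = TRUE)),
                   4L)
  expect_length(findSites("TCCAGGA", bam, circular = FALSE), 0L)
  # non-palindromic recognition is found via the bottom strand too
  asym <- data.frame(name = "BspMI", recognition = "ACCTGC", cut_offset = 4L)
  hits <- findSites("AAGCAGGTAA", asym)  # revcomp of ACCTGC = GCAGGT
  expect_identical(as.integer(hits), 2L)
  expect_identical(attr(hits, "strand"), "-")
  # degenerate IUPAC letters
  deg <- data.frame(name = "XcmI", recognition = "CCANNNNNNNNNTGG",
                    cut_offset = 8L)
  expect_identical(as.integer(findSites("ACCATTTTTTTTTTGGA", deg)), 1L)
  expect_error(findSites("ACGT", data.frame(name = "bad",
    recognition = "AC?T", cut_offset = 1L)), "IUPAC")
})

test_that("findSites agrees with a brute-force sliding-window scan", {
  set.seed(77)
  enz <- loadEnzymes()
  for (rep in 1:4) {
    s <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
               collapse = "")
    e <- enz[sample(nrow(enz), 1), , drop = FALSE]
    for (circ in c(FALSE, TRUE))
      expect_identical(as.integer(findSites(s, e, circular = circ)),
                       bruteForceSites(s, e$recognition, circular = circ))
  }
})

test_that("linearizePlasmid opens at the unique cut and is rotation-invariant", {
  enz <- loadEnzymes()
  bam <- enz[enz$name == "BamHI", ]
  p <- generatePlasmid(1500, must_have_single = bam,
                       must_lack = digestionEnzymes(), seed = 6)
  lin <- linearizePlasmid(p, bam)
  expect_identical(nchar(lin), nchar(p))
  expect_identical(sort(strsplit(lin, "")[[1]]), sort(strsplit(p, "")[[1]]))
  # any rotation of the circle yields the identical linear molecule
  for (shift in c(17, 500, 1499)) {
    rot <- paste0(substr(p, shift + 1, nchar(p)), substr(p, 1, shift))
    expect_identical(linearizePlasmid(rot, bam), lin)
  }
  # 0 or >= 2 sites fail with the site count
  expect_error(linearizePlasmid(p, enz[enz$name == "EcoRI", ]), "found 0")
  two <- paste0(p, "GGATCC")
  expect_error(linearizePlasmid(two, bam), "found 2")
})

test_that("validateDigestionSet reports violating enzymes with positions", {
  enz <- loadEnzymes()
  p <- generatePlasmid(1500, must_have_single = enz[enz$name == "BamHI", ],
                       must_lack = digestionEnzymes(), seed = 8)
  rep <- validateDigestionSet(p, digestionEnzymes())
  expect_true(rep$pass)
  expect_identical(nrow(rep$violations), 0L)

  bad <- paste0(substr(p, 1, 700), "GAATTC", substr(p, 707, nchar(p)))
  repBad <- validateDigestionSet(bad, digestionEnzymes())
  expect_false(repBad$pass)
  expect_identical(repBad$violations$name, "EcoRI")
  expect_identical(repBad$violations$position, 700L)
  # the report agrees with findSites for every enzyme
  for (i in seq_len(nrow(digestionEnzymes()))) {
    e <- digestionEnzymes()[i, , drop = FALSE]
    expect_identical(
      repBad$violations$position[repBad$violations$name == e$name],
      as.integer(findSites(bad, e, circular = TRUE)))
  }
})

test_that("integrateInsert conserves genome bases and inverts cleanly", {
  g <- paste(rep(c("A", "C", "G", "T"), 250), collapse = "")
  ins <- strrep("GATTACA", 40)
  fwd <- integrateInsert(g, ins, 300, "forward")
  expect_identical(nchar(fwd$sequence), nchar(g) + nchar(ins))
  expect_identical(substr(fwd$sequence, 301, 300 + nchar(ins)), ins)
  # removal restores the original genome
  restored <- paste0(substr(fwd$sequence, 1, 300),
                     substr(fwd$sequence, 301 + nchar(ins),
                            nchar(fwd$sequence)))
  expect_identical(restored, g)
  # reverse orientation inserts the reverse complement
  rev <- integrateInsert(g, ins, 300, "reverse")
  expect_identical(substr(rev$sequence, 301, 300 + nchar(ins)),
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(ins))))
  # insertion at position 0 puts the insert first
  at0 <- integrateInsert(g, ins, 0, "forward")
  expect_identical(substr(at0$sequence, 1, nchar(ins)), ins)
  expect_error(integrateInsert(g, ins, nchar(g) + 1, "forward"), "outside")
})

test_that("digestSequence fragments and conserves linear and circular molecules", {
  # linear, planted cuts at 30 and 60 of a 100 bp molecule
  s <- strrep("A", 29)
  seq100 <- paste0(s, "GAATTC", strrep("A", 24), "GAATTC", strrep("A", 35))
  eco <- loadEnzymes(names = "EcoRI")  # cuts G^AATTC: sites 29, 59 -> cuts 30, 60
  fr <- digestSequence(seq100, eco, circular = FALSE)
  expect_identical(fr$end - fr$start, c(30L, 30L, 40L))
  expect_identical(paste(fr$sequence, collapse = ""), seq100)

  # circular with one cut: a single full-length linear fragment
  circ <- paste0(strrep("C", 50), "GAATTC", strrep("T", 44))
  frc <- digestSequence(circ, eco, circular = TRUE)
  expect_identical(nrow(frc), 1L)
  expect_identical(nchar(frc$sequence), 100L)
  # uncut circle comes back whole
  frq <- digestSequence(strrep("ACGG", 25), eco, circular = TRUE)
  expect_identical(frq$sequence, strrep("ACGG", 25))
})

test_that("digestion conservation holds on random sequences and enzyme draws", {
  set.seed(123)
  enz <- loadEnzymes()
  for (rep in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(500:2000, 1),
                      replace = TRUE), collapse = "")
    pick <- enz[sample(nrow(enz), sample(1:4, 1)), , drop = FALSE]
    circ <- sample(c(TRUE, FALSE), 1)
    fr <- digestSequence(s, pick, circular = circ)
    expect_identical(sum(nchar(fr$sequence)), nchar(s))
    if (!circ)
      expect_identical(paste(fr$sequence, collapse = ""), s)
    else {
      # concatenation reconstructs some rotation of the input
      cat2 <- paste(fr$sequence, collapse = "")
      expect_true(grepl(cat2, paste0(s, s), fixed = TRUE))
    }
  }
})

test_that("rescuePlasmid recovers flanks delimited by the nearest cut sites", {
  enz <- loadEnzymes()
  set.seed(42)
  g <- paste(sample(c("A", "C", "G", "T"), 6000, replace = TRUE),
             collapse = "")
  p <- generatePlasmid(1000, must_have_single = enz[enz$name == "BamHI", ],
                       must_lack = digestionEnzymes(), seed = 9)
  ins <- linearizePlasmid(p, enz[enz$name == "BamHI", ])
  pos <- 3000L
  mut <- integrateInsert(g, ins, pos, "forward")
  res <- rescuePlasmid(mut$sequence, ins, digestionEnzymes())
  # expected flanks from the digestion cut map of the uninserted genome
  cuts <- sort(unique(unlist(lapply(seq_len(nrow(digestionEnzymes())),
    function(i) {
      e <- digestionEnzymes()[i, , drop = FALSE]
      as.integer(findSites(g, e)) + e$cut_offset
    }))))
  up_cut <- max(c(0L, cuts[cuts <= pos]))
  down_cut <- min(c(nchar(g), cuts[cuts > pos]))
  expect_identical(nchar(rescueFlanks(res)[["upstream"]]), pos - up_cut)
  expect_identical(nchar(rescueFlanks(res)[["downstream"]]),
                   down_cut - pos)
  expect_identical(rescueFlanks(res)[["upstream"]],
                   substr(g, up_cut + 1, pos))
  # the rescue circle contains the full insert
  expect_true(grepl(ins, res@rescue_sequence, fixed = TRUE))
})

test_that("rescuePlasmid flags degenerate flanks and rejects protocol violations", {
  enz <- loadEnzymes()
  eco <- enz[enz$name == "EcoRI", ]
  # an enzyme cutting at the site's 3' boundary, so a cut can coincide with
  # the insertion point without the insertion destroying the site
  te <- data.frame(name = "TestI", recognition = "GAATTC", cut_offset = 6L)
  g <- paste0(strrep("A", 500), "GAATTC", strrep("T", 500))
  ins <- strrep("GGATCCC", 30)
  mut <- integrateInsert(g, ins, 506L, "forward")  # cut lands at ins_start
  res <- rescuePlasmid(mut$sequence, ins, te)
  expect_true("empty_flank" %in% rescueFlags(res))
  expect_identical(nchar(rescueFlanks(res)[["upstream"]]), 0L)
  expect_gt(nchar(rescueFlanks(res)[["downstream"]]), 0L)

  # an enzyme cutting inside the insert splits the marker across fragments
  insBad <- paste0(strrep("C", 100), "GAATTC", strrep("G", 100))
  mutBad <- integrateInsert(strrep("A", 1000), insBad, 400L, "forward")
  expect_error(rescuePlasmid(mutBad$sequence, insBad, eco),
               "protocol violation.*EcoRI")
  expect_error(rescuePlasmid(strrep("A", 500), ins, eco), "not found")
})

test_that("locateFlank maps unique flanks and reports short or repeated ones", {
  set.seed(7)
  g <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
             collapse = "")
  rs <- ReferenceSet(c(chr1 = g))
  fl <- substr(g, 2001, 2500)
  hit <- locateFlank(fl, rs)
  expect_identical(hit$status, "unique")
  expect_identical(hit$start, 2000L)
  expect_identical(hit$end, 2500L)
  expect_identical(hit$strand, "+")
  # the reverse complement maps to the same interval on the minus strand
  rcfl <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fl)))
  hitRC <- locateFlank(rcfl, rs)
  expect_identical(hitRC$strand, "-")
  expect_identical(hitRC$start, 2000L)
  # short flank: unmapped
  expect_identical(locateFlank(substr(g, 1, 10), rs)$status, "unmapped")
  # flank from a duplicated segment: ambiguous with hit count
  dup <- paste0(g, substr(g, 1001, 1100), strrep("A", 30))
  amb <- locateFlank(substr(g, 1001, 1100), ReferenceSet(c(chr1 = dup)))
  expect_identical(amb$status, "ambiguous")
  expect_identical(amb$n_hits, 2L)
  # constructs are never searched
  rs2 <- ReferenceSet(c(chr1 = g, plas = fl),
                      role = c("genome_contig", "construct"))
  expect_identical(locateFlank(fl, rs2)$n_hits, 1L)
})

test_that("integrate-rescue-locate round trip identifies the planted locus", {
  enz <- loadEnzymes()
  g <- generateGenome(20000, 0.41, seed = 300)
  gseq <- as.character(refSequences(g)[[1]])
  p <- generatePlasmid(1500,
    must_have_single = enz[enz$name %in% c("BamHI", "KpnI"), ],
    must_lack = digestionEnzymes(), seed = 301)
  ins <- linearizePlasmid(p, enz[enz$name == "KpnI", ])
  set.seed(302)
  positions <- sample(0:20000, 25)
  recovered <- 0L; eligible <- 0L
  for (pos in positions) {
    orient <- sample(c("forward", "reverse"), 1)
    mut <- integrateInsert(gseq, ins, pos, orient)
    res <- tryCatch(identifyLocus(mut$sequence, ins, digestionEnzymes(), g),
                    error = function(e) NULL)
    if (is.null(res)) next
    fl <- nchar(rescueFlanks(res))
    if (max(fl) >= 20) {
      eligible <- eligible + 1L
      locus <- res@mapped_locus
      if (identical(locus$status, "unique") &&
          (identical(locus$start, as.integer(pos)) ||
             identical(locus$end, as.integer(pos))))
        recovered <- recovered + 1L
    }
  }
  expect_gte(eligible, 18L)
  expect_identical(recovered, eligible)
})
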
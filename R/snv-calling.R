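#' Parameters for pileup-based SNP classification
#'
#' Bundles the thresholds of the two-tier SNP classifier: positions must be
#' covered by at least `min_depth` selected alignments to be evaluated; the
#' aggregate of non-reference bases must exceed the reference count
#' (strictly, by default) for a variant to be reported; and a variant
#' fraction of at least `plausible_fraction` of the covering alignments
#' upgrades a *potential* SNP to a *plausible* SNP.
#'
#' @param min_depth Minimum alignment depth for evaluation (default 10).
#' @param plausible_fraction Variant fraction at or above which a site is
#'   classified plausible (default 0.90); must be in `(0.5, 1]`.
#' @param strict_majority Must the variant count strictly exceed the
#'   reference count? (default `TRUE`).
#' @return A validated list of class `snv_params`.
#' @export
snvParams <- function(min_depth = 10L, plausible_fraction = 0.90,
                      strict_majority = TRUE) {
  stopifnot(min_depth >= 1, plausible_fraction > 0.5,
            plausible_fraction <= 1, is.logical(strict_majority))
  structure(list(min_depth = as.integer(min_depth),
                 plausible_fraction = plausible_fraction,
                 strict_majority = strict_majority),
            class = "snv_params")
}

.BASES <- c("A", "C", "G", "T")

#' Build a pileup from best-selected alignments
#'
#' Tallies, for every reference position covered by at least one matched
#' alignment column, the strand-corrected read base of each selected
#' alignment. Gap columns contribute nothing; `N` read bases are dropped
#' from counts and depth. Input records must carry `read_bases` (see
#' [attachReadSequences()]) and be best-selected (one record per read).
#'
#' @param x An [AlignmentSet-class] with read bases attached.
#' @param refset The [ReferenceSet-class] the alignments refer to.
#' @return A `data.frame` with columns `ref_id`, `position` (0-based),
#'   `ref_base`, `A`, `C`, `G`, `T`, `depth`, one row per covered position,
#'   sorted by (`ref_id`, `position`). The attribute `"ref_ids"` records the
#'   full reference universe for downstream consistency checks.
#' @export
buildPileup <- function(x, refset) {
  stopifnot(is(refset, "ReferenceSet"))
  df <- alignmentRecords(x)
  if (nrow(df) && anyNA(df$read_bases))
    stop("records without read_bases; run attachReadSequences() first")
  unknown <- setdiff(unique(df$ref_id), names(refset))
  if (length(unknown))
    stop("alignment ref_id(s) not in reference set: ",
         paste(unknown, collapse = ", "))
  lens <- refLengths(refset)
  out <- vector("list", length(lens))
  for (ri in seq_along(lens)) {
    id <- names(lens)[ri]
    sub <- df[df$ref_id == id, , drop = FALSE]
    if (!nrow(sub)) next
    len <- lens[[id]]
    simple <- !grepl("[,:]", sub$blocks)
    lut <- integer(128L)
    lut[utf8ToInt("ACGT")] <- 1:4
    pos <- list(); cod <- list()
    if (any(simple)) {
      s <- sub[simple, , drop = FALSE]
      if (length(unique(s$ref_aln_size)) == 1L) {
        L <- s$ref_aln_size[1]
        pos[[1]] <- rep(s$ref_start, each = L) +
          rep.int(0:(L - 1L), nrow(s))
      } else {
        pos[[1]] <- unlist(Map(function(st, w) st + 0:(w - 1L),
                               s$ref_start, s$ref_aln_size))
      }
      cod[[1]] <- lut[utf8ToInt(paste(s$read_bases, collapse = ""))]
    }
    if (any(!simple)) {
      s <- sub[!simple, , drop = FALSE]
      pieces <- lapply(seq_len(nrow(s)), function(i) {
        seg <- parseBlocks(s$blocks[i])
        rcur <- s$ref_start[i]; qcur <- 0L
        rp <- integer(); qp <- integer()
        for (k in seq_len(nrow(seg))) {
          m <- seg[k, "match"]
          if (m > 0L) {
            rp <- c(rp, rcur + 0:(m - 1L))
            qp <- c(qp, qcur + 0:(m - 1L))
            rcur <- rcur + m; qcur <- qcur + m
          }
          rcur <- rcur + seg[k, "ref_gap"]
          qcur <- qcur + seg[k, "read_gap"]
        }
        codes <- lut[utf8ToInt(s$read_bases[i])]
        list(pos = rp, cod = codes[qp + 1L])
      })
      pos[[length(pos) + 1L]] <- unlist(lapply(pieces, `[[`, "pos"))
      cod[[length(cod) + 1L]] <- unlist(lapply(pieces, `[[`, "cod"))
    }
    pos <- unlist(pos)
    code <- unlist(cod)
    ok <- code > 0L  # drop N and any non-ACGT
    pos <- pos[ok]; code <- code[ok]
    if (!length(pos)) next
    tab <- tabulate(pos * 4L + code, nbins = 4L * len)
    counts <- matrix(tab, ncol = 4L, byrow = TRUE,
                     dimnames = list(NULL, .BASES))
    depth <- as.integer(rowSums(counts))
    covered <- which(depth > 0L)
    refchars <- strsplit(as.character(refSequences(refset, id)[[1]]),
                         "")[[1]]
    out[[ri]] <- data.frame(ref_id = id, position = covered - 1L,
                            ref_base = refchars[covered],
                            counts[covered, , drop = FALSE],
                            depth = depth[covered])
  }
  out <- out[!vapply(out, is.null, logical(1))]
  res <- if (length(out)) do.call(rbind, out)
  else data.frame(ref_id = character(), position = integer(),
                  ref_base = character(), A = integer(), C = integer(),
                  G = integer(), T = integer(), depth = integer())
  rownames(res) <- NULL
  attr(res, "ref_ids") <- names(refset)
  res
}

#' Classify pileup columns into the two-tier SNP categories
#'
#' Applies the classification rules per position: a position covered by
#' fewer than `min_depth` alignments is `not_evaluated`; otherwise, with
#' `V` the aggregate count of non-reference bases and `R` the reference
#' count, a position is `no_variant` unless `V > R` (majority rule;
#' `V >= R` when `strict_majority` is off), `plausible` when additionally
#' `V / depth >= plausible_fraction`, and `potential` otherwise. The
#' reported variant base is the most frequent non-reference base, ties
#' broken alphabetically; the variant fraction is `V / depth`.
#'
#' @param pileup A pileup `data.frame` from [buildPileup()] (columns
#'   `ref_base`, `A`, `C`, `G`, `T`, `depth`), or a single column given as
#'   named counts.
#' @param params A [snvParams()] list.
#' @return The pileup with columns `category`, `variant_base`,
#'   `variant_fraction` appended (`NA` for categories without a variant).
#' @examples
#' col <- data.frame(ref_id = "chr1", position = 99L, ref_base = "A",
#'                   A = 1L, C = 0L, G = 9L, T = 0L, depth = 10L)
#' classifyPileup(col)$category  # "plausible"
#' @export
classifyPileup <- function(pileup, params = snvParams()) {
  stopifnot(inherits(params, "snv_params"))
  counts <- as.matrix(pileup[, .BASES, drop = FALSE])
  depth <- pileup$depth
  stopifnot(all(rowSums(counts) == depth))
  refIdx <- match(pileup$ref_base, .BASES)
  stopifnot(!anyNA(refIdx))
  n <- nrow(pileup)
  R <- counts[cbind(seq_len(n), refIdx)]
  V <- depth - R
  nonref <- counts
  nonref[cbind(seq_len(n), refIdx)] <- -1L
  topAlt <- .BASES[max.col(nonref, ties.method = "first")]
  frac <- ifelse(depth > 0, V / depth, NA_real_)
  majority <- if (params$strict_majority) V > R else V >= R
  category <- rep("no_variant", n)
  category[majority & frac >= params$plausible_fraction] <- "plausible"
  category[majority & frac < params$plausible_fraction] <- "potential"
  category[depth < params$min_depth] <- "not_evaluated"
  hasVar <- category %in% c("potential", "plausible")
  pileup$category <- category
  pileup$variant_base <- ifelse(hasVar, topAlt, NA_character_)
  pileup$variant_fraction <- ifelse(hasVar, frac, NA_real_)
  pileup
}

#' Classify a single pileup column
#'
#' Convenience wrapper around [classifyPileup()] for one position given as
#' base counts.
#'
#' @param counts Named integer vector of base counts (names among A, C, G,
#'   T; absent bases count 0).
#' @param ref_base The reference base at the position.
#' @param params A [snvParams()] list.
#' @return A list with `category`, `variant_base`, `variant_fraction` and
#'   `depth`.
#' @examples
#' classifySite(c(A = 1, G = 9), ref_base = "A")$category
#' @export
classifySite <- function(counts, ref_base, params = snvParams()) {
  full <- stats::setNames(rep(0L, 4L), .BASES)
  stopifnot(all(names(counts) %in% .BASES))
  full[names(counts)] <- as.integer(counts)
  col <- data.frame(ref_base = ref_base, A = full["A"], C = full["C"],
                    G = full["G"], T = full["T"], depth = sum(full))
  cl <- classifyPileup(col, params)
  list(category = cl$category, variant_base = cl$variant_base,
       variant_fraction = cl$variant_fraction, depth = cl$depth)
}

#' Differential SNP extraction between a mutant and its host strain
#'
#' Emits a call for every position classified `plausible` in the mutant and
#' *not* classified `potential` or `plausible` in the host — i.e. the host
#' position is `no_variant` or was never evaluated (low or no coverage).
#' Host positions below the evaluation depth pass the exclusion filter but
#' are flagged, since an uncovered host cannot actively exclude a shared
#' variant. Both pileups must derive from the same reference universe.
#'
#' @param mutant_pileup,host_pileup Pileups from [buildPileup()] for the
#'   mutant and host strain reads.
#' @param params A [snvParams()] list, applied to both strains.
#' @return A `data.frame` sorted by (`ref_id`, `position`) with columns
#'   `ref_id`, `position`, `ref_base`, `alt_base`, `mutant_fraction`,
#'   `mutant_depth`, `host_category`, `host_depth`, `low_host_coverage`.
#' @export
callDifferentialSnvs <- function(mutant_pileup, host_pileup,
                                 params = snvParams()) {
  mu <- attr(mutant_pileup, "ref_ids")
  hu <- attr(host_pileup, "ref_ids")
  if (!is.null(mu) && !is.null(hu) && !setequal(mu, hu))
    stop("reference mismatch: pileups derive from different reference sets")
  extra <- setdiff(unique(mutant_pileup$ref_id), unique(c(hu, host_pileup$ref_id)))
  if (is.null(hu) && length(extra) && nrow(host_pileup))
    stop("reference mismatch: ref_id(s) absent from host input: ",
         paste(extra, collapse = ", "))
  mcl <- classifyPileup(mutant_pileup, params)
  hcl <- classifyPileup(host_pileup, params)
  m <- mcl[mcl$category == "plausible", , drop = FALSE]
  if (!nrow(m)) {
    out <- data.frame(ref_id = character(), position = integer(),
                      ref_base = character(), alt_base = character(),
                      mutant_fraction = numeric(), mutant_depth = integer(),
                      host_category = character(), host_depth = integer(),
                      low_host_coverage = logical())
    return(out)
  }
  key <- function(d) paste(d$ref_id, d$position)
  hi <- match(key(m), key(hcl))
  host_category <- ifelse(is.na(hi), "not_evaluated", hcl$category[hi])
  host_depth <- ifelse(is.na(hi), 0L, hcl$depth[hi])
  keep <- host_category %in% c("not_evaluated", "no_variant")
  out <- data.frame(ref_id = m$ref_id, position = m$position,
                    ref_base = m$ref_base, alt_base = m$variant_base,
                    mutant_fraction = m$variant_fraction,
                    mutant_depth = m$depth,
                    host_category = host_category,
                    host_depth = as.integer(host_depth),
                    low_host_coverage = host_depth < params$min_depth)
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$ref_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the complete differential SNP pipeline on simulated reads
#'
#' Chains best-alignment selection, pileup construction, per-site
#' classification and mutant-vs-host differential extraction, starting from
#' alignment sets with attached read bases (e.g. the oracle alignments from
#' [simulateReads()], or parsed aligner output joined to FASTQ).
#'
#' @param mutant_aln,host_aln [AlignmentSet-class] objects with read bases.
#' @param refset The shared [ReferenceSet-class].
#' @param params A [snvParams()] list.
#' @param seed Seed for best-alignment tie-breaking.
#' @return The call table of [callDifferentialSnvs()].
#' @export
snvPipeline <- function(mutant_aln, host_aln, refset, params = snvParams(),
                        seed = 1) {
  mp <- buildPileup(selectBestAlignments(mutant_aln, seed = seed), refset)
  hp <- buildPileup(selectBestAlignments(host_aln, seed = seed), refset)
  callDifferentialSnvs(mp, hp, params)
}

#' Write a differential SNP call table
#'
#' Writes calls as TSV with 1-based positions for human readability
#' (internal coordinates are 0-based), or as a minimal VCF-like rendering.
#'
#' @param calls Call table from [callDifferentialSnvs()].
#' @param path Output path.
#' @param format `"tsv"` or `"vcf"`.
#' @return The path, invisibly.
#' @export
writeSnvCalls <- function(calls, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- calls
    out$position <- out$position + 1L
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
    if (nrow(calls))
      writeLines(sprintf(
        "%s\t%d\t.\t%s\t%s\t.\t%s\tAF=%.4f;DP=%d;HOST=%s",
        calls$ref_id, calls$position + 1L, calls$ref_base, calls$alt_base,
        ifelse(calls$low_host_coverage, "LowHostCov", "PASS"),
        calls$mutant_fraction, calls$mutant_depth, calls$host_category), con)
  }
  invisible(path)
}
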
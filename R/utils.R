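# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so generators are deterministic without
# clobbering the session RNG.
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Reverse complement of plain character DNA, vectorized.
revComp <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

# Parse a LAST TAB blocks string "n[,d:i,n]*" into a matrix with columns
# match, ref_gap, read_gap (one row per segment; pure-match segments have
# zero gaps, gap segments have zero match).
parseBlocks <- function(blocks) {
  stopifnot(length(blocks) == 1L)
  toks <- strsplit(blocks, ",", fixed = TRUE)[[1]]
  out <- matrix(0L, nrow = length(toks), ncol = 3L,
                dimnames = list(NULL, c("match", "ref_gap", "read_gap")))
  gap <- grepl(":", toks, fixed = TRUE)
  if (any(!gap)) {
    v <- suppressWarnings(as.integer(toks[!gap]))
    if (anyNA(v)) stop("malformed blocks string: ", blocks)
    out[!gap, "match"] <- v
  }
  if (any(gap)) {
    parts <- strsplit(toks[gap], ":", fixed = TRUE)
    if (any(lengths(parts) != 2L)) stop("malformed blocks string: ", blocks)
    m <- suppressWarnings(matrix(as.integer(unlist(parts)), ncol = 2L,
                                 byrow = TRUE))
    if (anyNA(m)) stop("malformed blocks string: ", blocks)
    out[gap, c("ref_gap", "read_gap")] <- m
  }
  out
}

# Total reference- and read-consumed lengths for a vector of blocks strings.
# Single ungapped blocks (the overwhelmingly common case) take a vectorized
# fast path.
blockSizes <- function(blocks) {
  ref <- read <- integer(length(blocks))
  simple <- !grepl("[,:]", blocks)
  if (any(simple)) {
    v <- suppressWarnings(as.integer(blocks[simple]))
    if (anyNA(v))
      stop("malformed blocks string: ", blocks[simple][which(is.na(v))[1]])
    ref[simple] <- v
    read[simple] <- v
  }
  if (any(!simple)) {
    sizes <- vapply(blocks[!simple], function(b) {
      seg <- parseBlocks(b)
      c(sum(seg[, "match"]) + sum(seg[, "ref_gap"]),
        sum(seg[, "match"]) + sum(seg[, "read_gap"]))
    }, numeric(2), USE.NAMES = FALSE)
    ref[!simple] <- sizes[1, ]
    read[!simple] <- sizes[2, ]
  }
  list(ref = ref, read = read)
}
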
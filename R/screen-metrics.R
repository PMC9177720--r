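#' Relative secretion titer from a 96-well screening plate
#'
#' Computes, per strain, the blank-corrected signal normalized to the mean
#' blank-corrected signal of the host-control wells on the same plate —
#' the normalization used when ranking library clones by secreted-protein
#' titer measured by single-point-dilution ELISA. Replicate wells of a
#' strain are averaged and a standard deviation is reported when at least
#' two replicates exist. The host strain's relative titer is exactly 1 on
#' every plate by construction, and calls are invariant to rescaling all
#' signals on a plate.
#'
#' @param plate A `data.frame` with columns `plate_id`, `well` (96-well
#'   addresses A1-H12), `strain_id`, `role` (`"sample"`, `"host_control"`
#'   or `"blank"`), `signal` (non-negative ELISA absorbance or
#'   back-calculated titer) and optionally `od660`.
#' @param dilution_factor Single-point dilution factor applied to the
#'   supernatants (default 25). It rescales corrected signals to the
#'   undiluted scale and cancels in the host-normalized ratio.
#' @return A `data.frame` with `strain_id`, `relative_titer`, `sd`
#'   (`NA` for a single well) and `n_wells`, sorted by `strain_id`.
#' @export
relativeTiter <- function(plate, dilution_factor = 25) {
  req <- c("plate_id", "well", "strain_id", "role", "signal")
  stopifnot(all(req %in% names(plate)), dilution_factor >= 1)
  if (!all(grepl("^[A-H](1[0-2]|[1-9])$", plate$well)))
    stop("invalid 96-well address(es): ",
         paste(unique(plate$well[!grepl("^[A-H](1[0-2]|[1-9])$",
                                        plate$well)]), collapse = ", "))
  stopifnot(all(is.finite(plate$signal)), all(plate$signal >= 0))
  ratios <- list()
  for (pid in unique(plate$plate_id)) {
    p <- plate[plate$plate_id == pid, , drop = FALSE]
    blank <- mean(p$signal[p$role == "blank"])
    if (is.nan(blank)) blank <- 0
    corrected <- pmax(p$signal - blank, 0) * dilution_factor
    host <- corrected[p$role == "host_control"]
    if (!length(host))
      stop("normalization error: no host_control wells on plate ", pid)
    hostMean <- mean(host)
    if (hostMean <= 0)
      stop("degenerate plate ", pid, ": host mean signal <= 0")
    keep <- p$role %in% c("sample", "host_control")
    ratios[[length(ratios) + 1L]] <- data.frame(
      strain_id = p$strain_id[keep], ratio = corrected[keep] / hostMean)
  }
  r <- do.call(rbind, ratios)
  agg <- split(r$ratio, r$strain_id)
  out <- data.frame(
    strain_id = names(agg),
    relative_titer = vapply(agg, mean, 0),
    sd = vapply(agg, function(v)
      if (length(v) >= 2L) stats::sd(v) else NA_real_, 0),
    n_wells = vapply(agg, length, 0L))
  rownames(out) <- NULL
  out[order(out$strain_id), , drop = FALSE]
}

#' Call screening hits from relative titers
#'
#' A strain is a hit iff its relative titer strictly exceeds the threshold
#' — "more than 1.3-times the host" means a ratio of exactly 1.30 is not a
#' hit. Output is sorted by descending ratio.
#'
#' @param titers `data.frame` from [relativeTiter()] (needs `strain_id` and
#'   `relative_titer`).
#' @param hit_threshold Strict ratio threshold (default 1.3; must be > 1).
#' @return The hit rows of `titers`, sorted descending by relative titer.
#' @examples
#' tt <- data.frame(strain_id = c("a", "b"), relative_titer = c(1.30, 1.31))
#' callHits(tt)$strain_id  # "b" only
#' @export
callHits <- function(titers, hit_threshold = 1.3) {
  stopifnot(hit_threshold > 1,
            all(c("strain_id", "relative_titer") %in% names(titers)))
  hits <- titers[titers$relative_titer > hit_threshold, , drop = FALSE]
  hits <- hits[order(-hits$relative_titer), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Secretion productivity: titer per unit biomass
#'
#' Productivity is defined as the secreted-protein titer (or enzymatic
#' activity) divided by the culture's optical density at 660 nm, separating
#' per-cell secretion capacity from growth differences.
#'
#' @param titer Numeric titer(s).
#' @param od660 Matching OD660 value(s); must be positive.
#' @return `titer / od660`, vectorized.
#' @export
productivity <- function(titer, od660) {
  if (any(od660 <= 0)) stop("od660 must be positive")
  titer / od660
}

#' Productivity normalized to a reference strain
#'
#' @param strains `data.frame` with `strain_id`, `titer`, `od660`.
#' @param reference Strain id used as the normalization reference (its
#'   relative productivity is 1).
#' @return The input with `productivity` and `relative_productivity`
#'   columns appended.
#' @export
relativeProductivity <- function(strains, reference = "host") {
  stopifnot(all(c("strain_id", "titer", "od660") %in% names(strains)))
  if (!reference %in% strains$strain_id)
    stop("reference strain not found: ", reference)
  strains$productivity <- productivity(strains$titer, strains$od660)
  ref <- mean(strains$productivity[strains$strain_id == reference])
  strains$relative_productivity <- strains$productivity / ref
  strains
}

#' Specific growth rate from an OD660 time series
#'
#' Estimates the specific growth rate mu (per hour) as the slope of the
#' least-squares line of `ln(OD660)` versus time over the exponential-phase
#' window: among all contiguous windows of at least `min_points`
#' measurements whose OD lies within `od_range`, the window maximizing the
#' coefficient of determination is chosen, ties broken toward the longer
#' and then the earlier window. Exact on noiseless exponentials.
#'
#' @param times Time points in hours, strictly increasing.
#' @param od660 Positive OD660 readings, same length (>= 4 points).
#' @param od_range Inclusive OD bounds delimiting the exponential phase
#'   (default `c(0.05, 1.0)`).
#' @param min_points Minimum window length (default 4).
#' @return A list of class `growth_fit` with `mu` (per hour), `window`
#'   (start and end index, inclusive), `r_squared` and `flags`
#'   (`"flat"` when the window shows no OD change, with `r_squared` 0).
#' @examples
#' t <- seq(0, 8, by = 0.5)
#' fitGrowthRate(t, 0.05 * exp(0.3 * t))$mu  # 0.3
#' @export
fitGrowthRate <- function(times, od660, od_range = c(0.05, 1.0),
                          min_points = 4L) {
  stopifnot(length(times) == length(od660), length(times) >= min_points,
            all(diff(times) > 0), all(od660 > 0), min_points >= 4L)
  eligible <- od660 >= od_range[1] & od660 <= od_range[2]
  runs <- rle(eligible)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  best <- NULL
  for (r in which(runs$values & runs$lengths >= min_points)) {
    i0 <- starts[r]; i1 <- ends[r]
    x <- times[i0:i1]; y <- log(od660[i0:i1])
    n <- length(x)
    for (w in n:min_points) {
      for (a in 1:(n - w + 1L)) {
        xi <- x[a:(a + w - 1L)]; yi <- y[a:(a + w - 1L)]
        sxx <- sum((xi - mean(xi))^2)
        syy <- sum((yi - mean(yi))^2)
        sxy <- sum((xi - mean(xi)) * (yi - mean(yi)))
        if (syy == 0) { slope <- 0; r2 <- 0; flat <- TRUE }
        else { slope <- sxy / sxx; r2 <- sxy^2 / (sxx * syy); flat <- FALSE }
        cand <- list(mu = slope, window = c(i0 + a - 1L, i0 + a + w - 2L),
                     r_squared = r2, flags = if (flat) "flat"
                     else character())
        better <- is.null(best) || r2 > best$r_squared + 1e-12 ||
          (abs(r2 - best$r_squared) <= 1e-12 &&
             (w > diff(best$window) + 1L ||
                (w == diff(best$window) + 1L &&
                   cand$window[1] < best$window[1])))
        if (better) best <- cand
      }
    }
  }
  if (is.null(best))
    stop("no eligible exponential-phase window of >= ", min_points,
         " points within OD range [", od_range[1], ", ", od_range[2], "]")
  structure(best, class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Growth fit: mu = %.4f /h over points [%d, %d], R^2 = %.4f%s\n",
              x$mu, x$window[1], x$window[2], x$r_squared,
              if (length(x$flags)) paste0(" (", paste(x$flags,
                collapse = ", "), ")") else ""))
  invisible(x)
}

#' Welch's unequal-variance two-sample t-test
#'
#' Two-sided t-test without the equal-variance assumption, using the
#' Welch-Satterthwaite approximation for the degrees of freedom — the test
#' used to compare strain groups (significance at p < 0.05).
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2; at least
#'   one group must have nonzero variance.
#' @return A list with `t`, `df` and `p` (two-sided).
#' @examples
#' welchTest(c(10, 11, 12), c(1, 2, 3))$p
#' @export
welchTest <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L)
    stop("each group needs at least 2 observations")
  va <- stats::var(group_a); vb <- stats::var(group_b)
  if (va == 0 && vb == 0)
    stop("both groups have zero variance")
  se2a <- va / na; se2b <- vb / nb
  t <- (mean(group_a) - mean(group_b)) / sqrt(se2a + se2b)
  df <- (se2a + se2b)^2 /
    (se2a^2 / (na - 1) + se2b^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Generations elapsed under serial-transfer propagation
#'
#' Each transfer dilutes the culture by `dilution_fraction` and regrowth to
#' the pre-transfer density requires `log2(1 / dilution_fraction)` cell
#' doublings, so `transfers * log2(1 / dilution_fraction)` generations
#' elapse in total. With the 0.2 % (v/v) daily transfers used for adaptive
#' laboratory evolution, 55 transfers correspond to roughly 493 (about 500)
#' generations.
#'
#' @param transfers Non-negative integer number of serial transfers.
#' @param dilution_fraction Fraction of culture carried over per transfer,
#'   in `(0, 1)` (0.002 for a 0.2 % v/v transfer).
#' @return Estimated number of generations.
#' @examples
#' estimateGenerations(55, 0.002)  # ~493
#' @export
estimateGenerations <- function(transfers, dilution_fraction) {
  stopifnot(transfers >= 0, transfers == round(transfers))
  if (dilution_fraction <= 0 || dilution_fraction >= 1)
    stop("dilution_fraction must be in (0, 1)")
  transfers * log2(1 / dilution_fraction)
}
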
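#' Build a viewpoint interaction profile
#'
#' Bins the distal ligated-end coordinates of a deduplicated 4C contact
#' table into sliding bins: bins advance by `step` (100 bp) and each bin's
#' raw count M collects contacts from its centred `window` (500 bp, i.e.
#' `[start - 200, start + 300)`). `M_norm` expresses M per 10,000 unique cis
#' contacts of the table.
#'
#' @param table a deduplicated [ContactTable-class] in 4C mode (side 1 =
#'   bait); only cis contacts (both sides on the viewpoint chromosome) are
#'   profiled.
#' @param viewpoint list(chrom, start, end) or "chrom:start-end" string,
#'   0-based half-open.
#' @param region analysed interval as list(chrom, start, end); defaults to
#'   the whole viewpoint chromosome when the table metadata carries
#'   seqlengths, else to the span of the data.
#' @param step bin step in bp (default 100).
#' @param window collection window in bp; must be an odd multiple of `step`
#'   (default 500).
#' @return an [InteractionProfile-class] (background columns not yet
#'   computed; see [addLocalBackground()]).
#' @export
binProfile <- function(table, viewpoint, region = NULL, step = 100L,
                       window = 500L) {
  stopifnot(is(table, "ContactTable"))
  vp <- .checkViewpoint(viewpoint)
  step <- as.integer(step); window <- as.integer(window)
  k <- window / step
  if (k != round(k) || (as.integer(k) %% 2L) != 1L)
    stop("'window' must be an odd multiple of 'step'")
  rec <- table@records
  cis <- rec[rec$chrom1 == vp$chrom & rec$chrom2 == vp$chrom, , drop = FALSE]
  total <- nrow(cis)

  if (is.null(region)) {
    sl <- table@metadata$seqlengths
    if (!is.null(sl) && vp$chrom %in% names(sl)) {
      region <- list(chrom = vp$chrom, start = 0L, end = as.integer(sl[[vp$chrom]]))
    } else {
      hi <- max(c(cis$pos2, vp$end, step)) + window
      region <- list(chrom = vp$chrom, start = 0L,
                     end = as.integer(ceiling(hi / step) * step))
    }
  } else {
    region <- .checkViewpoint(region)  # same shape checks
  }
  region$start <- as.integer(floor(region$start / step) * step)
  region$end <- as.integer(ceiling(region$end / step) * step)
  nb <- (region$end - region$start) %/% step
  if (nb < 1L) stop("analysed region shorter than one step")

  starts <- region$start + step * (seq_len(nb) - 1L)
  pos <- cis$pos2
  pos <- pos[pos >= region$start & pos < region$end]
  m_step <- tabulate((pos - region$start) %/% step + 1L, nbins = nb)
  half <- (as.integer(k) - 1L) %/% 2L
  M <- .windowSums(m_step, half)
  bins <- data.frame(start = starts, m_step = m_step, M = M,
                     M_norm = if (total > 0) M * 1e4 / total else 0)
  new("InteractionProfile", viewpoint = vp,
      region = region, step = step, window = window,
      bins = bins, total = as.numeric(total))
}

#' Local-background expected count for one bin
#'
#' MACS-style dynamic local background: the expected count N of a bin is the
#' collection window times the maximum contact density over centred spans of
#' the given half-widths (defaults 2.5/5/10/25 kb, i.e. total spans of 5 to
#' 50 kb), excluding an exclusion zone around the bin itself. Spans are
#' truncated at the edges of the profiled region with lengths adjusted, and
#' each span's read count is floored at a pseudo-count (default 0.5 reads
#' per span) so that N is always positive.
#'
#' @param profile an [InteractionProfile-class].
#' @param bin 1-based bin index (vectorised).
#' @param scales span half-widths in bp.
#' @param exclusion half-width of the exclusion zone around the bin, bp.
#' @param floor_reads pseudo-count floor per span.
#' @return numeric vector of expected counts N.
#' @seealso [addLocalBackground()] for whole-profile computation.
#' @export
localBackground <- function(profile, bin,
                            scales = c(2500, 5000, 10000, 25000),
                            exclusion = 1000, floor_reads = 0.5) {
  stopifnot(is(profile, "InteractionProfile"))
  nb <- nrow(profile@bins)
  bin <- as.integer(bin)
  if (any(bin < 1L | bin > nb)) stop("bin index outside profile")
  N <- .localBackgroundN(profile@bins$m_step, profile@step, profile@window,
                         scales = scales, exclusion = exclusion,
                         floor_reads = floor_reads)
  N[bin]
}

#' Complete a profile with the local background
#'
#' Fills the `N`, `p`, `FE` and `score` columns of an interaction profile
#' using the 5-50 kb max-over-scales local background (see
#' [localBackground()]) and exact Poisson upper-tail probabilities.
#'
#' @inheritParams localBackground
#' @return the completed [InteractionProfile-class].
#' @export
addLocalBackground <- function(profile,
                               scales = c(2500, 5000, 10000, 25000),
                               exclusion = 1000, floor_reads = 0.5) {
  stopifnot(is(profile, "InteractionProfile"))
  N <- .localBackgroundN(profile@bins$m_step, profile@step, profile@window,
                         scales = scales, exclusion = exclusion,
                         floor_reads = floor_reads)
  .completeProfile(profile, N)
}

.completeProfile <- function(profile, N) {
  b <- profile@bins
  b$N <- N
  b$p <- poissonPValue(b$M, N)
  b$FE <- b$M / N
  b$score <- -log10(b$p)
  profile@bins <- b
  profile
}

#' Exact Poisson upper-tail probability
#'
#' `p = P(X >= M)` for `X ~ Poisson(N)` — the exact tail, not a normal
#' approximation. `M = 0` gives p = 1 for any N.
#'
#' @param M observed count(s), non-negative integers.
#' @param N expected count(s), strictly positive.
#' @return numeric vector of upper-tail probabilities.
#' @examples
#' poissonPValue(4, 1)
#' @export
poissonPValue <- function(M, N) {
  if (any(N <= 0)) stop("'N' must be positive")
  if (any(M < 0) || any(M != round(M))) stop("'M' must be non-negative integers")
  stats::ppois(M - 1, N, lower.tail = FALSE)
}

#' Global distance-decay background
#'
#' Alternative expectation per bin from distance modelling of the global
#' interaction profile: mean M is computed over log-spaced bins of distance
#' to the viewpoint, a monotone-decreasing fit (isotonic regression on
#' log10 distance) smooths the means, and the fitted curve is evaluated at
#' every bin's distance. Drop-in replacement for the local background when
#' comparing calling algorithms.
#'
#' @param profile an [InteractionProfile-class].
#' @param n_dist_bins number of log-spaced distance bins for the fit.
#' @param min_dist bins closer than this to the viewpoint centre are not
#'   used for fitting (their expectation is extrapolated), bp.
#' @return the profile with `N`, `p`, `FE`, `score` computed from the
#'   distance model.
#' @export
distanceModelBackground <- function(profile, n_dist_bins = 50L,
                                    min_dist = 1000) {
  stopifnot(is(profile, "InteractionProfile"))
  b <- profile@bins
  if (all(b$M == 0)) stop("all-zero profile: cannot fit a distance model")
  vp_mid <- (profile@viewpoint$start + profile@viewpoint$end) / 2
  centre <- b$start + profile@step / 2
  d <- abs(centre - vp_mid)
  use <- d >= min_dist
  if (sum(use) < 10L) stop("profile too short for distance modelling")
  ld <- log10(d[use])
  br <- seq(min(ld), max(ld), length.out = n_dist_bins + 1L)
  grp <- findInterval(ld, br, rightmost.closed = TRUE)
  mids <- (br[-1L] + br[-length(br)]) / 2
  mM <- tapply(b$M[use], grp, mean)
  x <- mids[as.integer(names(mM))]
  ## monotone-decreasing fit: isotonic regression on the negated means
  o <- order(x)
  iso <- stats::isoreg(x[o], -as.numeric(mM)[o])
  yhat <- -iso$yf
  N <- stats::approx(x[o], yhat, xout = log10(pmax(d, 1)), rule = 2)$y
  N <- pmax(N, 1e-9)
  .completeProfile(profile, N)
}

## Merged significant intervals of one completed profile.
## Returns list(loops = data.frame, n_tested = int).
.callOne <- function(profile, alpha, min_dist, merge_gap) {
  b <- profile@bins
  vp <- profile@viewpoint
  centre <- b$start + profile@step / 2
  dist_vp <- pmax(vp$start - centre, centre - vp$end, 0)
  tested <- which(dist_vp >= min_dist)
  n_tested <- length(tested)
  half_lo <- (profile@window - profile@step) %/% 2L
  half_hi <- profile@window - half_lo
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), summit = integer(0),
                      p_min = numeric(0), p_adj = numeric(0),
                      strength = numeric(0), n_bins = integer(0))
  if (!n_tested) return(list(loops = empty, n_tested = 0L))
  sig <- tested[b$p[tested] * n_tested < alpha]
  if (!length(sig)) return(list(loops = empty, n_tested = n_tested))
  runs <- .runsByGap(b$start[sig], merge_gap)
  loops <- do.call(rbind, lapply(runs, function(ix) {
    ii <- sig[ix]
    summit <- ii[which.min(b$p[ii])]  # leftmost minimal-p bin
    data.frame(chrom = vp$chrom,
               start = as.integer(min(b$start[ii]) - half_lo),
               end = as.integer(max(b$start[ii]) + half_hi),
               summit = as.integer(b$start[summit]),
               p_min = b$p[summit],
               p_adj = min(b$p[summit] * n_tested, 1),
               strength = log2(b$M[summit] / b$N[summit]),
               n_bins = length(ii))
  }))
  rownames(loops) <- NULL
  list(loops = loops, n_tested = n_tested)
}

#' Call cis-regulatory loops from interaction profiles
#'
#' Tests every bin farther than `min_dist_from_viewpoint` from the viewpoint
#' with the exact Poisson upper tail of M against the expected count N,
#' applies Bonferroni correction over the tested bins, merges runs of
#' significant bins separated by less than `merge_gap` into loop intervals
#' (each at least one window long), and reports the summit (leftmost
#' minimal-p bin) and the loop strength log2(M/N) at the summit. With two or
#' more replicate profiles a loop is reproducible iff a significant merged
#' interval of every replicate overlaps it by at least 1 bp; by default only
#' reproducible loops are reported (intervals and summits come from the
#' first replicate). With a single profile the `reproducible` flag is NA.
#'
#' @param profiles an [InteractionProfile-class] or list of replicate
#'   profiles over the same region. Profiles without background columns are
#'   completed first using `background`.
#' @param alpha family-wise significance level after Bonferroni correction.
#' @param min_dist_from_viewpoint bins closer than this to the viewpoint are
#'   excluded from testing (self-ligation zone), bp.
#' @param merge_gap maximum gap between significant bins merged into one
#'   loop, bp.
#' @param background "local" (5-50 kb max-over-scales) or "distance"
#'   (global decay model) for profiles lacking N.
#' @param reproducible_only with >= 2 replicates, drop non-reproducible
#'   loops (default TRUE).
#' @return data.frame of loop calls (chrom, start, end, summit, p_min,
#'   p_adj, strength, n_bins, reproducible).
#' @export
callLoops <- function(profiles, alpha = 0.05,
                      min_dist_from_viewpoint = 5000, merge_gap = 500,
                      background = c("local", "distance"),
                      reproducible_only = TRUE) {
  background <- match.arg(background)
  if (is(profiles, "InteractionProfile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1L)
  profiles <- lapply(profiles, function(p) {
    stopifnot(is(p, "InteractionProfile"))
    if (!"N" %in% names(p@bins))
      p <- if (background == "local") addLocalBackground(p)
           else distanceModelBackground(p)
    p
  })
  if (all(vapply(profiles, function(p) sum(p@bins$M), 0) == 0))
    warning("zero-contact profile(s): no loops can be called")
  calls <- lapply(profiles, .callOne, alpha = alpha,
                  min_dist = min_dist_from_viewpoint, merge_gap = merge_gap)
  ref <- calls[[1L]]$loops
  if (length(profiles) == 1L) {
    ref$reproducible <- rep(NA, nrow(ref))
    return(ref)
  }
  if (nrow(ref)) {
    rep_ok <- rep(TRUE, nrow(ref))
    for (k in 2:length(calls)) {
      other <- calls[[k]]$loops
      rep_ok <- rep_ok & vapply(seq_len(nrow(ref)), function(i) {
        any(other$start < ref$end[i] & other$end > ref$start[i])
      }, TRUE)
    }
    ref$reproducible <- rep_ok
  } else {
    ref$reproducible <- logical(0)
  }
  if (reproducible_only) ref <- ref[which(ref$reproducible), , drop = FALSE]
  rownames(ref) <- NULL
  ref
}

## Raw contact count of a profile inside [start, end): sum of step counts.
.countInInterval <- function(profile, start, end) {
  b <- profile@bins
  sel <- b$start >= start & b$start < end
  sum(b$m_step[sel])
}

#' Differential loop test between two conditions
#'
#' Per loop, compares the raw contact counts of the two profiles inside the
#' loop interval with an exact conditional binomial test: under the null the
#' count from condition A among the pooled loop contacts is binomial with
#' success probability T_A / (T_A + T_B), where T are the library sizes
#' (total unique cis contacts of each profile over the analysed region).
#' Fold changes are computed on library-normalised counts; p-values are
#' Benjamini-Hochberg adjusted across loops.
#'
#' @param profileA,profileB [InteractionProfile-class] objects over the same
#'   region.
#' @param loops data.frame of loop intervals (chrom, start, end), from
#'   either condition.
#' @return data.frame with per-loop counts, library sizes, log2 fold change
#'   (A over B), p and p_adj.
#' @export
differentialLoopTest <- function(profileA, profileB, loops) {
  stopifnot(is(profileA, "InteractionProfile"),
            is(profileB, "InteractionProfile"))
  tA <- profileA@total; tB <- profileB@total
  if (tA <= 0 || tB <= 0) stop("zero library total")
  if (!nrow(loops)) stop("no loops supplied")
  mA <- vapply(seq_len(nrow(loops)), function(i)
    .countInInterval(profileA, loops$start[i], loops$end[i]), 0)
  mB <- vapply(seq_len(nrow(loops)), function(i)
    .countInInterval(profileB, loops$start[i], loops$end[i]), 0)
  p0 <- tA / (tA + tB)
  p <- vapply(seq_len(nrow(loops)), function(i) {
    n <- mA[i] + mB[i]
    if (n == 0) return(1)
    stats::binom.test(mA[i], n, p = p0)$p.value
  }, 0)
  lfc <- ifelse(mA > 0 & mB > 0,
                log2((mA / tA) / (mB / tB)),
                log2(((mA + 0.5) / tA) / ((mB + 0.5) / tB)))
  out <- data.frame(loop_id = seq_len(nrow(loops)),
                    chrom = loops$chrom, start = loops$start, end = loops$end,
                    count_a = mA, count_b = mB, total_a = tA, total_b = tB,
                    log2_fc = lfc, p = p,
                    p_adj = stats::p.adjust(p, method = "BH"))
  rownames(out) <- NULL
  out
}

#' Allele-specific loop test
#'
#' Two-sided exact binomial test of the reference-allele count among the
#' allele-assigned contacts of each loop, with expected proportion
#' totalRef / (totalRef + totalAlt) given by the allele library sizes.
#' Loops with zero contacts on both alleles are omitted with a warning.
#' Benjamini-Hochberg correction across the tested loops.
#'
#' @param countsRef,countsAlt per-loop contact counts on each allele.
#' @param totalRef,totalAlt allele library sizes.
#' @param loop_id optional loop identifiers.
#' @return data.frame with counts, log2 allelic ratio (ref over alt,
#'   library-normalised), p and p_adj.
#' @export
alleleSpecificTest <- function(countsRef, countsAlt, totalRef, totalAlt,
                               loop_id = seq_along(countsRef)) {
  stopifnot(length(countsRef) == length(countsAlt))
  if (totalRef <= 0 || totalAlt <= 0) stop("zero allele library total")
  keep <- countsRef + countsAlt > 0
  if (any(!keep))
    warning(sum(!keep), " loop(s) with zero counts on both alleles omitted")
  cr <- countsRef[keep]; ca <- countsAlt[keep]; id <- loop_id[keep]
  p0 <- totalRef / (totalRef + totalAlt)
  p <- vapply(seq_along(cr), function(i)
    stats::binom.test(cr[i], cr[i] + ca[i], p = p0)$p.value, 0)
  lfc <- ifelse(cr > 0 & ca > 0,
                log2((cr / totalRef) / (ca / totalAlt)),
                log2(((cr + 0.5) / totalRef) / ((ca + 0.5) / totalAlt)))
  data.frame(loop_id = id, count_ref = cr, count_alt = ca,
             log2_ratio = lfc, p = p,
             p_adj = stats::p.adjust(p, method = "BH"))
}

#' Label profile bins by overlap with intervals
#'
#' A bin `[start, start + step)` is positive iff it overlaps any of the
#' given intervals by at least 1 bp.
#'
#' @param profile an [InteractionProfile-class].
#' @param intervals data.frame with `start`, `end` (0-based half-open);
#'   a `chrom` column, when present, is matched against the profile.
#' @return logical vector, one element per bin.
#' @export
labelBins <- function(profile, intervals) {
  stopifnot(is(profile, "InteractionProfile"))
  if (!is.null(intervals$chrom))
    intervals <- intervals[intervals$chrom == profile@region$chrom, , drop = FALSE]
  s <- profile@bins$start
  e <- s + profile@step
  pos <- rep(FALSE, length(s))
  for (i in seq_len(nrow(intervals)))
    pos <- pos | (s < intervals$end[i] & e > intervals$start[i])
  pos
}

#' ROC curve and AUC for bin scores
#'
#' Rank-based AUC: the probability that a randomly chosen positive bin
#' outscores a randomly chosen negative bin, ties counting one half.
#'
#' @param score numeric scores (e.g. -log10 p per bin).
#' @param positive logical labels, same length.
#' @return list with `auc` and a data.frame `roc` of (threshold, fpr, tpr)
#'   points at every distinct score, sorted by decreasing threshold.
#' @examples
#' rocAuc(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE))$auc
#' @export
rocAuc <- function(score, positive) {
  stopifnot(length(score) == length(positive))
  keep <- !is.na(score) & !is.na(positive)
  score <- score[keep]; positive <- as.logical(positive[keep])
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0L || nn == 0L)
    stop("both positive and negative bins are required")
  r <- rank(score)  # midranks: ties count 1/2
  auc <- (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
  o <- order(score, decreasing = TRUE)
  sc <- score[o]; po <- positive[o]
  idx <- which(!duplicated(sc, fromLast = TRUE))
  tpr <- cumsum(po)[idx] / np
  fpr <- cumsum(!po)[idx] / nn
  list(auc = auc,
       roc = data.frame(threshold = sc[idx], fpr = c(fpr), tpr = c(tpr)))
}
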
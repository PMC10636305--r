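#' Bin cis contacts into a sparse contact matrix
#'
#' Entry (i, j), i <= j in 0-based bin indices, counts the records whose two
#' ligated-end coordinates fall in bins i and j at the chosen resolution.
#' The matrix total equals the number of records.
#'
#' @param table a [ContactTable-class]; only cis records of `chrom` are
#'   binned.
#' @param resolution bin size in bp (> 0).
#' @param chrom chromosome; defaults to the single chromosome present.
#' @return a [ContactMatrix-class].
#' @export
binMatrix <- function(table, resolution, chrom = NULL) {
  stopifnot(is(table, "ContactTable"))
  resolution <- as.integer(resolution)
  if (is.na(resolution) || resolution <= 0L) stop("'resolution' must be positive")
  rec <- table@records
  rec <- rec[rec$chrom1 == rec$chrom2, , drop = FALSE]
  if (is.null(chrom)) {
    ch <- unique(rec$chrom1)
    if (length(ch) != 1L)
      stop("table covers ", length(ch), " chromosomes; give 'chrom'")
    chrom <- ch
  }
  rec <- rec[rec$chrom1 == chrom, , drop = FALSE]
  sl <- table@metadata$seqlengths
  L <- if (!is.null(sl) && chrom %in% names(sl)) sl[[chrom]]
       else if (nrow(rec)) max(rec$pos1, rec$pos2) + 1L else resolution
  nbins <- as.integer(ceiling(L / resolution))
  bi <- rec$pos1 %/% resolution
  bj <- rec$pos2 %/% resolution
  swap <- bi > bj
  tmp <- bi[swap]; bi[swap] <- bj[swap]; bj[swap] <- tmp
  if (nrow(rec)) {
    key <- bi * as.numeric(nbins) + bj
    agg <- rowsum(rep(1L, length(key)), key)
    k <- as.numeric(rownames(agg))
    entries <- data.frame(i = as.integer(k %/% nbins),
                          j = as.integer(k %% nbins),
                          count = as.integer(agg[, 1L]))
    entries <- entries[order(entries$i, entries$j), , drop = FALSE]
    rownames(entries) <- NULL
  } else {
    entries <- data.frame(i = integer(0), j = integer(0), count = integer(0))
  }
  new("ContactMatrix", chrom = chrom, resolution = resolution,
      entries = entries, nbins = nbins, total = as.numeric(sum(entries$count)))
}

#' Virtual 4C profile from Hi-C contacts
#'
#' Extracts the contacts touching a viewpoint interval with exactly one side
#' (contacts fully inside the viewpoint are self-interactions and are
#' dropped), reorients them so the viewpoint side is side 1, and bins the
#' distal side exactly as [binProfile()] does. Downstream loop calling
#' reuses [callLoops()].
#'
#' @param table a deduplicated [ContactTable-class] (anchor-free mode).
#' @param viewpoint list(chrom, start, end) or "chrom:start-end".
#' @param ... passed to [binProfile()] (`region`, `step`, `window`).
#' @return an [InteractionProfile-class].
#' @export
virtual4C <- function(table, viewpoint, ...) {
  stopifnot(is(table, "ContactTable"))
  vp <- .checkViewpoint(viewpoint)
  rec <- table@records
  in1 <- rec$chrom1 == vp$chrom & rec$pos1 >= vp$start & rec$pos1 < vp$end
  in2 <- rec$chrom2 == vp$chrom & rec$pos2 >= vp$start & rec$pos2 < vp$end
  keep <- xor(in1, in2)
  rec <- rec[keep, , drop = FALSE]
  flip <- in2[keep]
  if (any(flip)) {
    sw <- function(a, b) { tmp <- rec[[a]][flip]; rec[[a]][flip] <<- rec[[b]][flip]; rec[[b]][flip] <<- tmp }
    sw("chrom1", "chrom2"); sw("pos1", "pos2")
    sw("strand1", "strand2"); sw("frag1", "frag2")
  }
  md <- table@metadata
  md$viewpoint <- vp
  vtab <- new("ContactTable", records = rec,
              metadata = c(md[setdiff(names(md), "mode")], list(mode = "4C")))
  binProfile(vtab, vp, ...)
}

#' Distal-interactivity hotspot track
#'
#' Per 100 bp bin, D counts the contact ends falling in the bin's centred
#' 500 bp window whose ligation partner lies at least `min_dist` away (both
#' ends of every cis contact are candidates). The expected count E applies
#' the same 5-50 kb max-over-scales local background used by the loop caller
#' to the D track, p is the exact Poisson upper tail, S = -log10 p, and bins
#' with p below the Bonferroni-motivated threshold (default 3e-7) are
#' flagged as hotspots. Adjacent flagged bins are merged into hotspot
#' intervals, available via [hotspotIntervals()].
#'
#' @param table a deduplicated [ContactTable-class] with cis contacts of one
#'   chromosome.
#' @param resolution bin step in bp (default 100).
#' @param min_dist minimum partner distance for an end to count as distal,
#'   bp (default 10 kb).
#' @param window collection window, odd multiple of `resolution`.
#' @param p_threshold hotspot flag threshold on p (default 3e-7).
#' @param chrom chromosome; defaults to the single chromosome present.
#' @param scales,exclusion,floor_reads background parameters, see
#'   [localBackground()].
#' @return data.frame (start, D, E, p, score, hotspot) with attributes
#'   `step` and `intervals`.
#' @export
distalInteractivity <- function(table, resolution = 100L, min_dist = 10000,
                                window = 500L, p_threshold = 3e-7,
                                chrom = NULL,
                                scales = c(2500, 5000, 10000, 25000),
                                exclusion = 1000, floor_reads = 0.5) {
  stopifnot(is(table, "ContactTable"))
  resolution <- as.integer(resolution); window <- as.integer(window)
  k <- window / resolution
  if (k != round(k) || (as.integer(k) %% 2L) != 1L)
    stop("'window' must be an odd multiple of 'resolution'")
  rec <- table@records
  rec <- rec[rec$chrom1 == rec$chrom2, , drop = FALSE]
  if (is.null(chrom)) {
    ch <- unique(rec$chrom1)
    if (length(ch) != 1L)
      stop("table covers ", length(ch), " chromosomes; give 'chrom'")
    chrom <- ch
  }
  rec <- rec[rec$chrom1 == chrom, , drop = FALSE]
  distal <- abs(rec$pos2 - rec$pos1) >= min_dist
  ends <- c(rec$pos1[distal], rec$pos2[distal])
  sl <- table@metadata$seqlengths
  L <- if (!is.null(sl) && chrom %in% names(sl)) sl[[chrom]]
       else max(c(ends, window)) + window
  nb <- as.integer(ceiling(L / resolution))
  step_counts <- tabulate(ends %/% resolution + 1L, nbins = nb)
  half <- (as.integer(k) - 1L) %/% 2L
  D <- .windowSums(step_counts, half)
  E <- .localBackgroundN(step_counts, resolution, window, scales = scales,
                         exclusion = exclusion, floor_reads = floor_reads)
  p <- poissonPValue(D, E)
  out <- data.frame(start = resolution * (seq_len(nb) - 1L),
                    D = D, E = E, p = p, score = -log10(p),
                    hotspot = p < p_threshold)
  attr(out, "step") <- resolution
  attr(out, "chrom") <- chrom
  attr(out, "intervals") <- .mergeFlagged(out$start, out$hotspot, resolution, chrom)
  out
}

.mergeFlagged <- function(starts, flag, step, chrom) {
  s <- starts[flag]
  runs <- .runsByGap(s, step)
  if (!length(runs))
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0)))
  data.frame(chrom = chrom,
             start = vapply(runs, function(ix) s[ix[1L]], 0),
             end = vapply(runs, function(ix) s[ix[length(ix)]] + step, 0))
}

#' Merged hotspot intervals of a distal-interactivity track
#'
#' @param track the data.frame returned by [distalInteractivity()].
#' @return BED-style data.frame (chrom, start, end) of merged runs of
#'   flagged bins.
#' @export
hotspotIntervals <- function(track) {
  iv <- attr(track, "intervals")
  if (is.null(iv)) stop("not a distal-interactivity track")
  iv
}

#' Insulation score track and boundary calls
#'
#' For each bin i, the diamond mean is the average count over pairs (a, b)
#' with i - w <= a < i < b <= i + w; the insulation score is the log2 ratio
#' of the bin's diamond mean to the chromosome-wide mean of diamond means
#' (so the track is centred near 0). Boundaries are local minima of the
#' score (plateaus merged) whose prominence — the lower of the maximum
#' scores within w bins on each side minus the minimum — exceeds
#' `delta_threshold`. The reported boundary coordinate is the centre of the
#' minimal run, which for an abrupt two-block junction is exactly the block
#' junction coordinate.
#'
#' @param mat a [ContactMatrix-class].
#' @param window_bins diamond half-width w in bins (default 25).
#' @param delta_threshold minimum boundary prominence (default 0.1).
#' @return data.frame (bin, start, score) with NA score where the diamond
#'   leaves the chromosome; boundary calls in attribute `boundaries`
#'   (data.frame chrom, coord, score, delta).
#' @export
insulationTrack <- function(mat, window_bins = 25L, delta_threshold = 0.1) {
  stopifnot(is(mat, "ContactMatrix"))
  w <- as.integer(window_bins)
  nb <- mat@nbins
  if (w < 1L) stop("'window_bins' must be >= 1")
  if (2L * w >= nb) stop("'window_bins' exceeds half the matrix")
  M <- .denseCounts(mat)
  ## summed-area table for O(1) rectangle sums
  C <- rbind(0, apply(M, 2, cumsum))
  C <- cbind(0, t(apply(C, 1, cumsum)))
  rect <- function(r1, r2, c1, c2) C[r2 + 1L, c2 + 1L] - C[r1, c2 + 1L] -
    C[r2 + 1L, c1] + C[r1, c1]
  dm <- rep(NA_real_, nb)
  for (i in (w + 1L):(nb - w)) {
    dm[i] <- rect(i - w, i - 1L, i + 1L, i + w) / (w * w)
  }
  gm <- mean(dm, na.rm = TRUE)
  score <- log2(dm / gm)
  r <- mat@resolution
  out <- data.frame(bin = 0:(nb - 1L), start = r * (0:(nb - 1L)),
                    score = score)
  attr(out, "boundaries") <- .findBoundaries(score, w, delta_threshold, r,
                                             mat@chrom)
  attr(out, "resolution") <- r
  out
}

## Local minima (with plateau merging) of a score track; prominence is the
## lower of the two flanking maxima within w bins minus the minimum score.
.findBoundaries <- function(score, w, delta_threshold, resolution, chrom) {
  fin <- which(is.finite(score))
  empty <- data.frame(chrom = character(0), coord = numeric(0),
                      score = numeric(0), delta = numeric(0))
  if (length(fin) < 3L) return(empty)
  res <- list()
  i <- 1L
  n <- length(fin)
  while (i <= n) {
    j <- i
    while (j < n && score[fin[j + 1L]] == score[fin[i]]) j <- j + 1L
    s <- score[fin[i]]
    left_ok <- i > 1L && score[fin[i - 1L]] > s
    right_ok <- j < n && score[fin[j + 1L]] > s
    if (left_ok && right_ok) {
      lw <- fin[max(1L, i - w):(i - 1L)]
      rw <- fin[(j + 1L):min(n, j + w)]
      delta <- min(max(score[lw]), max(score[rw])) - s
      if (delta >= delta_threshold) {
        u <- fin[i]; v <- fin[j]  # 1-based bin indices of the minimal run
        coord <- ((u - 1L) + v) / 2 * resolution
        res[[length(res) + 1L]] <-
          data.frame(chrom = chrom, coord = coord, score = s, delta = delta)
      }
    }
    i <- j + 1L
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

## Pixel (0-based bin pair, i < j) of each BEDPE loop on a matrix.
.loopPixels <- function(mat, loops) {
  if (!is.null(loops$chrom1) &&
      any(loops$chrom1 != mat@chrom | loops$chrom2 != mat@chrom))
    stop("loop list contains chromosomes absent from the matrix")
  r <- mat@resolution
  bi <- as.integer(((loops$start1 + loops$end1) / 2) %/% r)
  bj <- as.integer(((loops$start2 + loops$end2) / 2) %/% r)
  swap <- bi > bj
  tmp <- bi[swap]; bi[swap] <- bj[swap]; bj[swap] <- tmp
  data.frame(i = bi, j = bj)
}

#' Aggregate peak analysis
#'
#' Element-wise mean of the (2k+1) x (2k+1) observed/expected submatrices
#' centred on each loop pixel, where expected is the matrix's distance-decay
#' expectation (per-diagonal mean count). The centre fold enrichment is the
#' mean of the central 3x3 cells divided by the mean of the lower-left
#' corner 3x3 cells (short-distance corner); the Z matrix standardises every
#' cell against the mean and standard deviation of the non-central cells.
#' Loops closer than k + 2 bins to the diagonal, or whose window leaves the
#' matrix, are dropped with a warning.
#'
#' @param mat a [ContactMatrix-class].
#' @param loops BEDPE-style data.frame (chrom1, start1, end1, chrom2,
#'   start2, end2).
#' @param flank_bins k, the flank half-width in bins (default 10).
#' @return list with `apa` (mean O/E matrix), `z` (Z-score matrix),
#'   `center_fe`, and `n_loops` used.
#' @export
apa <- function(mat, loops, flank_bins = 10L) {
  stopifnot(is(mat, "ContactMatrix"))
  k <- as.integer(flank_bins)
  px <- .loopPixels(mat, loops)
  nb <- mat@nbins
  ok <- (px$j - px$i) >= (k + 2L) & px$i - k >= 0L & px$j + k <= nb - 1L
  if (any(!ok))
    warning(sum(!ok), " loop(s) too close to the diagonal or matrix edge dropped")
  px <- px[ok, , drop = FALSE]
  if (!nrow(px)) stop("no usable loops for APA")
  OE <- .observedExpected(.denseCounts(mat))
  dim_out <- 2L * k + 1L
  acc <- matrix(0, dim_out, dim_out)
  cnt <- matrix(0, dim_out, dim_out)
  for (q in seq_len(nrow(px))) {
    sub <- OE[(px$i[q] - k):(px$i[q] + k) + 1L, (px$j[q] - k):(px$j[q] + k) + 1L]
    fin <- is.finite(sub)
    acc[fin] <- acc[fin] + sub[fin]
    cnt <- cnt + fin
  }
  A <- acc / cnt
  ctr <- k + 1L
  central <- matrix(FALSE, dim_out, dim_out)
  central[(ctr - 1L):(ctr + 1L), (ctr - 1L):(ctr + 1L)] <- TRUE
  corner <- mean(A[(dim_out - 2L):dim_out, 1:3], na.rm = TRUE)
  center_fe <- mean(A[central], na.rm = TRUE) / corner
  nc <- A[!central]
  z <- (A - mean(nc, na.rm = TRUE)) / stats::sd(nc[is.finite(nc)])
  list(apa = A, z = z, center_fe = center_fe, n_loops = nrow(px))
}

#' Loop strength from a contact matrix
#'
#' Mean observed/expected over the (2h+1) x (2h+1) neighbourhood of each
#' loop pixel — the matrix-level analogue of the profile fold enrichment.
#'
#' @param mat a [ContactMatrix-class].
#' @param loops BEDPE-style data.frame.
#' @param halfwidth neighbourhood half-width in bins (default 1).
#' @return numeric vector of fold enrichments, one per loop.
#' @export
loopStrengthFromMatrix <- function(mat, loops, halfwidth = 1L) {
  stopifnot(is(mat, "ContactMatrix"))
  h <- as.integer(halfwidth)
  px <- .loopPixels(mat, loops)
  OE <- .observedExpected(.denseCounts(mat))
  nb <- mat@nbins
  vapply(seq_len(nrow(px)), function(q) {
    ri <- max(px$i[q] - h, 0L):min(px$i[q] + h, nb - 1L)
    rj <- max(px$j[q] - h, 0L):min(px$j[q] + h, nb - 1L)
    mean(OE[ri + 1L, rj + 1L], na.rm = TRUE)
  }, 0)
}

#' Stripe-residual decomposition of loop strength
#'
#' Compares each loop's fold enrichment to the product of the
#' distal-interactivity fold enrichments of its two anchors: residual =
#' FE_loop / (FE_a1 * FE_a2). A residual near 1 means the loop pixel is
#' explained by the multiplicative overlap of two nonspecific interaction
#' stripes; residuals above 1 indicate point-to-point looping beyond the
#' stripes. Each anchor is matched to the nearest flagged hotspot bin within
#' `max_match` bp; anchors without a nearby hotspot use their own bin's D/E.
#'
#' @param loops BEDPE-style data.frame with a numeric `fe` column (loop fold
#'   enrichment, e.g. from [loopStrengthFromMatrix()]).
#' @param hotspots a track from [distalInteractivity()].
#' @param max_match maximum anchor-to-hotspot distance, bp (default 1 kb).
#' @return data.frame (loop_id, fe_loop, fe_a1, fe_a2, residual,
#'   log2_residual); loops with non-positive components are skipped with a
#'   warning.
#' @export
stripeResidual <- function(loops, hotspots, max_match = 1000) {
  if (is.null(loops$fe)) stop("loops must carry an 'fe' column")
  step <- attr(hotspots, "step")
  if (is.null(step)) stop("'hotspots' is not a distal-interactivity track")
  hs_centre <- hotspots$start + step / 2
  flagged <- which(hotspots$hotspot)
  anchorFE <- function(mid) {
    pick <- NA_integer_
    if (length(flagged)) {
      dd <- abs(hs_centre[flagged] - mid)
      if (min(dd) <= max_match) pick <- flagged[which.min(dd)]
    }
    if (is.na(pick)) pick <- which.min(abs(hs_centre - mid))
    hotspots$D[pick] / hotspots$E[pick]
  }
  mid1 <- (loops$start1 + loops$end1) / 2
  mid2 <- (loops$start2 + loops$end2) / 2
  fa1 <- vapply(mid1, anchorFE, 0)
  fa2 <- vapply(mid2, anchorFE, 0)
  fe <- loops$fe
  ok <- is.finite(fe) & fe > 0 & fa1 > 0 & fa2 > 0
  if (any(!ok))
    warning(sum(!ok), " loop(s) with non-positive fold enrichment skipped")
  res <- fe[ok] / (fa1[ok] * fa2[ok])
  data.frame(loop_id = which(ok), fe_loop = fe[ok],
             fe_a1 = fa1[ok], fe_a2 = fa2[ok],
             residual = res, log2_residual = log2(res))
}

#' Interior/exterior stripe intensity and loop asymmetry
#'
#' For each anchor of a loop, measures the mean observed/expected in a band
#' `halfwidth` bins wide centred on the anchor, extending `span_bins` bins
#' toward the loop interior and, separately, away from it (bands start two
#' bins from the anchor to avoid the diagonal). The asymmetry ratio
#' exterior/interior is near 1 for a freely extending stripe and below 1
#' when the partner anchor blocks the stripe beyond the loop.
#'
#' @param mat a [ContactMatrix-class].
#' @param loops BEDPE-style data.frame.
#' @param span_bins band length in bins (default 10).
#' @param halfwidth band half-width in bins (default 1).
#' @return data.frame per loop: interior/exterior means and asymmetry for
#'   each anchor, plus a `truncated` flag when a band was clipped at the
#'   matrix edge.
#' @export
loopAsymmetry <- function(mat, loops, span_bins = 10L, halfwidth = 1L) {
  stopifnot(is(mat, "ContactMatrix"))
  span <- as.integer(span_bins); h <- as.integer(halfwidth)
  px <- .loopPixels(mat, loops)
  OE <- .observedExpected(.denseCounts(mat))
  nb <- mat@nbins
  band <- function(anchor, cols) {
    rows <- (anchor - h):(anchor + h)
    keep_r <- rows >= 0L & rows <= nb - 1L
    keep_c <- cols >= 0L & cols <= nb - 1L
    trunc <- any(!keep_r) || any(!keep_c)
    cols <- cols[keep_c]; rows <- rows[keep_r]
    if (!length(cols) || !length(rows)) return(list(mean = NA_real_, trunc = TRUE))
    list(mean = mean(OE[rows + 1L, cols + 1L, drop = FALSE], na.rm = TRUE),
         trunc = trunc)
  }
  out <- lapply(seq_len(nrow(px)), function(q) {
    b1 <- px$i[q]; b2 <- px$j[q]
    i1 <- band(b1, (b1 + 2L):(b1 + 1L + span))        # anchor 1, toward loop
    e1 <- band(b1, (b1 - 1L - span):(b1 - 2L))        # anchor 1, away
    i2 <- band(b2, (b2 - 1L - span):(b2 - 2L))        # anchor 2, toward loop
    e2 <- band(b2, (b2 + 2L):(b2 + 1L + span))        # anchor 2, away
    data.frame(loop_id = q,
               interior1 = i1$mean, exterior1 = e1$mean,
               asymmetry1 = e1$mean / i1$mean,
               interior2 = i2$mean, exterior2 = e2$mean,
               asymmetry2 = e2$mean / i2$mean,
               truncated = i1$trunc || e1$trunc || i2$trunc || e2$trunc)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
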
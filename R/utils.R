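## Internal helpers shared across modules.

## Evaluate expr under a fixed, named RNG state without disturbing the
## caller's stream. Generator fixed so seeded output is identical across
## platforms and R sessions.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

## Sliding sum of v over [i - half, i + half] (in element units), truncated
## at the ends of the vector.
.windowSums <- function(v, half) {
  n <- length(v)
  cs <- c(0, cumsum(as.numeric(v)))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  cs[hi + 1L] - cs[lo]
}

## Local-background expected count per bin, MACS-style: for each bin the
## density is measured over centred spans of several half-widths (in bp),
## excluding a +-exclusion zone around the bin itself, and the maximum
## density across spans (floored at `floor_reads` reads per span) times the
## collection window gives N. Spans are measured in whole step bins and
## truncated at the ends of the profiled region.
.localBackgroundN <- function(step_counts, step, window,
                              scales = c(2500, 5000, 10000, 25000),
                              exclusion = 1000, floor_reads = 0.5) {
  n <- length(step_counts)
  idx <- seq_len(n)
  cs <- c(0, cumsum(as.numeric(step_counts)))
  es <- as.integer(round(exclusion / step))
  exc_lo <- pmax(idx - es, 1L); exc_hi <- pmin(idx + es, n)
  exc_cnt <- cs[exc_hi + 1L] - cs[exc_lo]
  exc_len <- (exc_hi - exc_lo + 1L) * step
  best <- rep(0, n)
  for (sc in sort(scales)) {
    ss <- as.integer(round(sc / step))
    if (ss <= es)
      stop("background scale ", sc, " does not exceed the exclusion zone")
    lo <- pmax(idx - ss, 1L); hi <- pmin(idx + ss, n)
    cnt <- cs[hi + 1L] - cs[lo] - exc_cnt
    len <- (hi - lo + 1L) * step - exc_len
    best <- pmax(best, pmax(cnt, floor_reads) / len)
  }
  window * best
}

## Merge runs of positions (sorted bin starts, bp) into intervals: a new run
## starts when the jump to the next position exceeds `gap`. Returns a list
## of integer index vectors into `starts`.
.runsByGap <- function(starts, gap) {
  if (!length(starts)) return(list())
  brk <- c(0L, which(diff(starts) > gap), length(starts))
  lapply(seq_len(length(brk) - 1L),
         function(k) (brk[k] + 1L):brk[k + 1L])
}

## Parse "chrom:start-end" (0-based half-open) into list(chrom, start, end).
.parseRegion <- function(s) {
  m <- regmatches(s, regexec("^(.+):([0-9]+)-([0-9]+)$", s))[[1]]
  if (length(m) != 4L) stop("cannot parse region '", s, "' (chrom:start-end)")
  list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}

.checkViewpoint <- function(vp) {
  if (is.character(vp) && length(vp) == 1L) vp <- .parseRegion(vp)
  if (!is.list(vp) || !all(c("chrom", "start", "end") %in% names(vp)))
    stop("viewpoint must be list(chrom, start, end) or 'chrom:start-end'")
  if (vp$end <= vp$start) stop("empty viewpoint interval")
  vp
}

## Dense symmetric count matrix from a ContactMatrix (guarded: test- and
## locus-scale matrices only).
.denseCounts <- function(mat, max_bins = 20000L) {
  nb <- mat@nbins
  if (nb > max_bins)
    stop("matrix too large to densify (", nb, " bins); use a coarser resolution")
  M <- matrix(0, nb, nb)
  e <- mat@entries
  if (nrow(e)) {
    M[cbind(e$i + 1L, e$j + 1L)] <- e$count
    lower <- e$i != e$j
    M[cbind(e$j[lower] + 1L, e$i[lower] + 1L)] <- e$count[lower]
  }
  M
}

## Observed/expected transform of a dense symmetric matrix, expected being
## the per-diagonal mean count (distance-decay expected). Diagonals with
## zero mean give NA.
.observedExpected <- function(M) {
  nb <- nrow(M)
  d <- abs(row(M) - col(M))
  dm <- rowsum(as.vector(M), as.vector(d)) /
    rowsum(rep(1, length(d)), as.vector(d))
  E <- matrix(dm[d + 1L], nb, nb)
  OE <- M / E
  OE[E == 0] <- NA_real_
  OE
}
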
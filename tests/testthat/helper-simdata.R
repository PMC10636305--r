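## Shared fixtures built in code. Heavier shared objects are built once per
## test run and cached in the helper environment.

.fixtures <- new.env(parent = emptyenv())

## A large fragment map emulating a triple-digested 10 Mb chromosome: cut
## spacings drawn once from the analytic spacing distribution (mean 256/3
## bp for three distinct 4-mers on iid sequence). Used by simulation-heavy
## tests where generating and digesting a full random genome per test would
## dominate the runtime.
bigMap <- function() {
  if (is.null(.fixtures$bigMap)) {
    L <- 1e7L
    cuts <- withr::with_seed(20240901, {
      x <- cumsum(stats::rexp(2e5, 3 / 256))
      as.integer(x[x < L - 1])
    })
    .fixtures$bigMap <- buildFragmentMap(
      data.frame(pos = cuts, enzyme = "DpnII"), c(chrS = L))
  }
  .fixtures$bigMap
}

bigMapViewpoint <- function() list(chrom = "chrS", start = 4999500L,
                                   end = 5000500L)

## Small genuine genome + triple-digest map for end-to-end chains.
smallGenomeMap <- function() {
  if (is.null(.fixtures$smallMap)) {
    g <- makeGenome(4e5, gc = 0.5, seed = 20240902)
    .fixtures$smallGenome <- g
    .fixtures$smallMap <- digestGenome(g, c("DpnII", "Csp6I", "NlaIII"))
  }
  list(genome = .fixtures$smallGenome, map = .fixtures$smallMap)
}

## A deterministic tiny contact table for I/O and dedup unit tests.
tinyTable <- function() {
  rec <- data.frame(
    read_id = sprintf("r%02d", 1:6),
    chrom1 = "chrS", pos1 = 1000L, strand1 = "+", frag1 = 1L,
    chrom2 = "chrS",
    pos2 = c(5000L, 5000L, 5000L, 7000L, 7000L, 9000L),
    strand2 = c("+", "+", "+", "-", "-", "+"),
    frag2 = c(10L, 10L, 10L, 20L, 20L, 30L),
    sonication_end = c(5100L, 5100L, 5101L, 7050L, 7050L, NA),
    allele = NA_character_, copies = 1L, viewpoint_id = "vp1",
    stringsAsFactors = FALSE)
  makeContactTable(rec, mode = "4C",
                   metadata = list(seqlengths = c(chrS = 20000L)))
}

## Build an InteractionProfile directly from per-step counts, for unit
## tests that need exact control over the count track.
profileFromSteps <- function(m_step, step = 100L, window = 500L,
                             vp_start = NULL, chrom = "chrS") {
  nb <- length(m_step)
  region_end <- as.integer(nb * step)
  if (is.null(vp_start)) vp_start <- as.integer(region_end / 2)
  half <- (window %/% step - 1L) %/% 2L
  cs <- c(0, cumsum(as.numeric(m_step)))
  lo <- pmax(seq_len(nb) - half, 1L); hi <- pmin(seq_len(nb) + half, nb)
  M <- cs[hi + 1L] - cs[lo]
  total <- sum(m_step)
  bins <- data.frame(start = step * (seq_len(nb) - 1L), m_step = m_step,
                     M = M, M_norm = if (total > 0) M * 1e4 / total else 0)
  new("InteractionProfile",
      viewpoint = list(chrom = chrom, start = vp_start,
                       end = vp_start + 1000L),
      region = list(chrom = chrom, start = 0L, end = region_end),
      step = as.integer(step), window = as.integer(window),
      bins = bins, total = as.numeric(total))
}

## ContactMatrix from a dense symmetric count matrix (upper triangle kept).
matrixFromDense <- function(M, resolution = 1000L, chrom = "chrS") {
  nb <- nrow(M)
  ut <- which(upper.tri(M, diag = TRUE), arr.ind = TRUE)
  keep <- M[ut] > 0
  entries <- data.frame(i = ut[keep, 1] - 1L, j = ut[keep, 2] - 1L,
                        count = as.integer(M[ut][keep]))
  entries <- entries[order(entries$i, entries$j), ]
  rownames(entries) <- NULL
  new("ContactMatrix", chrom = chrom, resolution = as.integer(resolution),
      entries = entries, nbins = nb, total = as.numeric(sum(entries$count)))
}
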
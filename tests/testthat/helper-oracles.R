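## Independent oracles used to freeze expected values. These deliberately
## use naive algorithms (character scans, full enumerations, term-by-term
## tail sums) so they share no code with the implementation they check.

## Naive restriction-site scan: compare every length-4 window of the
## sequence against every recognition word.
naiveFindSites <- function(seq, enzymes) {
  seq <- toupper(seq)
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  hits <- data.frame(pos = integer(0), enzyme = character(0))
  if (n < 4L) return(hits)
  words <- vapply(seq_len(n - 3L), function(i)
    paste(chars[i:(i + 3L)], collapse = ""), "")
  for (e in enzymes) {
    at <- which(words == e$recognition)
    if (length(at))
      hits <- rbind(hits, data.frame(pos = at - 1L + e$offset,
                                     enzyme = e$name))
  }
  hits <- hits[order(hits$pos, hits$enzyme), , drop = FALSE]
  hits <- hits[!duplicated(hits$pos), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

oracleEnzymes <- list(
  list(name = "DpnII", recognition = "GATC", offset = 0L),
  list(name = "Csp6I", recognition = "GTAC", offset = 1L),
  list(name = "NlaIII", recognition = "CATG", offset = 4L),
  list(name = "CviAII", recognition = "CATG", offset = 1L))

## Exact Poisson upper tail by term-by-term summation of the density,
## P(X >= m) = 1 - sum_{k < m} e^-N N^k / k!, terms built by recurrence.
poisTailOracle <- function(m, N) {
  if (m == 0L) return(1)
  term <- exp(-N)
  acc <- term
  k <- 0L
  while (k < m - 1L) {
    k <- k + 1L
    term <- term * N / k
    acc <- acc + term
  }
  1 - acc
}

## Two-sided exact binomial p-value by full tail summation: sum the
## probabilities of all outcomes no more likely than the observed one.
binomTwoSidedOracle <- function(k, n, p) {
  d <- vapply(0:n, function(i) stats::dbinom(i, n, p), 0)
  sum(d[d <= d[k + 1L] * (1 + 1e-7)])
}

## Brute-force UMI grouping on the full key.
bruteDedupCounts <- function(rec, mode = "4C") {
  key <- paste(rec$viewpoint_id, rec$chrom2, rec$frag2, rec$pos2,
               rec$strand2, rec$sonication_end, sep = "|")
  if (mode == "HiC")
    key <- paste(rec$chrom1, rec$pos1, rec$strand1, key, sep = "|")
  tab <- tapply(rec$copies, key, sum)
  tab[order(names(tab))]
}

## All-pairs AUC: fraction of (positive, negative) pairs where the positive
## outscores the negative, ties counting one half.
aucOracle <- function(score, positive) {
  ps <- score[positive]; ns <- score[!positive]
  tot <- 0
  for (x in ps) tot <- tot + sum(x > ns) + 0.5 * sum(x == ns)
  tot / (length(ps) * length(ns))
}

## Random A/C/G/T sequence (test-local RNG).
randomSeq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
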
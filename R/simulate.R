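#' Simulation specification
#'
#' Bundle of parameters for the ligation-library simulator. The defaults
#' encode the generic study conditions: contact probability decaying with
#' genomic distance as d^(-alpha) with alpha = 1 (the intra-TAD regime of
#' the overall log-linear decay), sonication shear breaks uniform within
#' +-300 bp of the ligated cut (the 300-400 bp sonication target), no PCR
#' duplication, no trans contacts, and uniform ligation-end orientations.
#'
#' @param genome_length genome length in bp.
#' @param n_molecules number of unique ligation molecules to draw.
#' @param mode "4C" (viewpoint-anchored) or "HiC" (anchor-free).
#' @param viewpoint 4C viewpoint as list(chrom, start, end) or
#'   "chrom:start-end" (required in 4C mode).
#' @param gc genome GC fraction in (0, 1).
#' @param seed integer seed; fully determines the simulator output.
#' @param alpha distance-decay exponent (contact probability ~ d^-alpha).
#' @param loops data.frame of injected loops: 4C mode columns (pos, fold,
#'   width); HiC mode columns (pos1, pos2, fold, width). Folds multiply the
#'   underlying contact probability inside the loop window(s).
#' @param hotspots data.frame (pos, fold, width): marginal interactivity
#'   folds h; a Hi-C pair picks up h_i * h_j.
#' @param domains list(boundaries = numeric, ratio = numeric): pairs
#'   crossing a boundary are down-weighted by the interior/exterior contact
#'   ratio per crossing (HiC mode).
#' @param trans_rate fraction of molecules ligated to a different
#'   chromosome.
#' @param dup_rate fraction of the final (pre-dedup) records that are PCR
#'   duplicates.
#' @param orientation probabilities of the in-in, in-out, out-in, out-out
#'   ligation-end orientations (must sum to 1).
#' @param sonication_halfwidth half-range of the shear-break offset, bp.
#' @param max_span optional maximum pair distance enumerated in HiC mode.
#' @return a validated list of class `SimulationSpec`.
#' @export
simulationSpec <- function(genome_length, n_molecules,
                           mode = c("4C", "HiC"), viewpoint = NULL,
                           gc = 0.5, seed = 1L, alpha = 1.0,
                           loops = NULL, hotspots = NULL, domains = NULL,
                           trans_rate = 0, dup_rate = 0,
                           orientation = c(0.25, 0.25, 0.25, 0.25),
                           sonication_halfwidth = 300L, max_span = NULL) {
  mode <- match.arg(mode)
  if (genome_length <= 0) stop("'genome_length' must be positive")
  if (gc <= 0 || gc >= 1) stop("'gc' must be in (0, 1)")
  if (n_molecules < 1) stop("'n_molecules' must be >= 1")
  if (!is.null(loops) && any(loops$fold <= 0)) stop("loop folds must be > 0")
  if (!is.null(hotspots) && any(hotspots$fold <= 0))
    stop("hotspot folds must be > 0")
  if (trans_rate < 0 || trans_rate >= 1 || dup_rate < 0 || dup_rate >= 1)
    stop("rates must be in [0, 1)")
  if (length(orientation) != 4L || any(orientation < 0) ||
      abs(sum(orientation) - 1) > 1e-8)
    stop("'orientation' must be 4 probabilities summing to 1")
  if (mode == "4C") {
    if (is.null(viewpoint)) stop("4C mode requires a viewpoint")
    viewpoint <- .checkViewpoint(viewpoint)
  }
  structure(list(genome_length = as.integer(genome_length),
                 n_molecules = as.integer(n_molecules), mode = mode,
                 viewpoint = viewpoint, gc = gc, seed = as.integer(seed),
                 alpha = alpha, loops = loops, hotspots = hotspots,
                 domains = domains, trans_rate = trans_rate,
                 dup_rate = dup_rate, orientation = orientation,
                 sonication_halfwidth = as.integer(sonication_halfwidth),
                 max_span = max_span),
            class = "SimulationSpec")
}

#' Generate a random genome sequence
#'
#' iid nucleotides with P(G) + P(C) = `gc`, deterministic under the seed
#' (fixed Mersenne-Twister stream; the caller's RNG state is untouched).
#'
#' @param length sequence length in bp.
#' @param gc GC fraction in (0, 1).
#' @param seed integer seed.
#' @param name sequence record name.
#' @return a named [Biostrings::DNAStringSet] with one record.
#' @export
makeGenome <- function(length, gc = 0.5, seed = 1L, name = "chrS") {
  if (length <= 0) stop("'length' must be positive")
  if (gc <= 0 || gc >= 1) stop("'gc' must be in (0, 1)")
  seq <- .withSeed(seed, sample(c("A", "C", "G", "T"), length, replace = TRUE,
                                prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                         (1 - gc) / 2)))
  out <- Biostrings::DNAStringSet(paste(seq, collapse = ""))
  names(out) <- name
  out
}

## Basepair extent tagged by each cut site (half-way to each neighbouring
## cut, clamped at the chromosome ends). The underlying contact probability
## is uniform per bp, and a ligation is recorded at the nearest assayable
## cut coordinate, so a cut site's sampling weight carries the measure of
## its cell; window counts then track genomic extent, not local cut-site
## density.
.cutCells <- function(cuts, L) {
  lo <- c(0, (cuts[-length(cuts)] + cuts[-1L]) / 2)
  hi <- c((cuts[-length(cuts)] + cuts[-1L]) / 2, L)
  hi - lo
}

## Per-cut marginal hotspot folds.
.hotspotFolds <- function(cutpos, hotspots) {
  h <- rep(1, length(cutpos))
  if (!is.null(hotspots))
    for (q in seq_len(nrow(hotspots))) {
      w2 <- hotspots$width[q] / 2
      sel <- cutpos >= hotspots$pos[q] - w2 & cutpos < hotspots$pos[q] + w2
      h[sel] <- h[sel] * hotspots$fold[q]
    }
  h
}

## Append PCR duplicates so that `rate` of the final records are duplicates;
## duplicates share every molecular field (including the sonication end) and
## get fresh read ids.
.addDuplicates <- function(rec, rate) {
  n_extra <- round(nrow(rec) * rate / (1 - rate))
  if (n_extra < 1) return(rec)
  pick <- sample.int(nrow(rec), n_extra, replace = TRUE)
  dup <- rec[pick, , drop = FALSE]
  dup$read_id <- sprintf("d%07d", seq_len(n_extra))
  out <- rbind(rec, dup)
  rownames(out) <- NULL
  out
}

#' Simulate a triple-digest 4C library
#'
#' Draws `n_molecules` ligation products for one viewpoint: the distal cut
#' coordinate is sampled from the restriction cut sites of the map with
#' probability proportional to d^(-alpha) times any injected loop fold, the
#' sonication end is uniform within +-300 bp of the distal cut, trans
#' molecules (if requested) ligate to a uniform cut on another chromosome,
#' and PCR duplicates are appended at the requested rate. The ground-truth
#' ledger records the true molecule count, the number of distinct UMI keys
#' among the molecules (the exact expectation for [dedupContacts()]; two
#' molecules drawing identical distal cut, strand and shear break are
#' indistinguishable by construction), and the injected features.
#'
#' @param spec a [simulationSpec()] in 4C mode.
#' @param map a [FragmentMap-class] of the same genome.
#' @return list with `table` (pre-dedup [ContactTable-class]) and `truth`
#'   (ledger list).
#' @export
simulateTri4C <- function(spec, map) {
  stopifnot(inherits(spec, "SimulationSpec"), is(map, "FragmentMap"))
  if (spec$mode != "4C") stop("spec is not in 4C mode")
  vp <- spec$viewpoint
  if (!vp$chrom %in% names(map@seqlengths))
    stop("viewpoint chromosome absent from map")
  cuts <- map@cuts[[vp$chrom]]$pos
  vp_cuts <- cuts[cuts >= vp$start & cuts < vp$end]
  if (!length(vp_cuts))
    stop("viewpoint contains no restriction cut site")
  vp_mid <- (vp$start + vp$end) / 2
  bait <- vp_cuts[which.min(abs(vp_cuts - vp_mid))]

  d <- abs(cuts - vp_mid)
  w <- pmax(d, 1)^(-spec$alpha) * .cutCells(cuts, map@seqlengths[[vp$chrom]])
  w[d < (vp$end - vp$start) / 2] <- 0  # no self-ligation back into the bait
  if (!is.null(spec$loops))
    for (q in seq_len(nrow(spec$loops))) {
      w2 <- spec$loops$width[q] / 2
      sel <- cuts >= spec$loops$pos[q] - w2 & cuts < spec$loops$pos[q] + w2
      w[sel] <- w[sel] * spec$loops$fold[q]
    }
  if (all(w == 0)) stop("no distal cut sites with positive weight")

  out <- .withSeed(spec$seed, {
    n <- spec$n_molecules
    is_trans <- stats::rbinom(n, 1L, spec$trans_rate) == 1L
    n_cis <- sum(!is_trans)
    chrom2 <- rep(vp$chrom, n)
    pos2 <- integer(n)
    pos2[!is_trans] <- cuts[sample.int(length(cuts), n_cis, replace = TRUE,
                                       prob = w)]
    if (any(is_trans)) {
      others <- setdiff(names(map@seqlengths), vp$chrom)
      if (!length(others))
        stop("trans_rate > 0 requires a map with >= 2 chromosomes")
      tch <- sample(others, sum(is_trans), replace = TRUE)
      chrom2[is_trans] <- tch
      pos2[is_trans] <- vapply(tch, function(ch) {
        cc <- map@cuts[[ch]]$pos
        cc[sample.int(length(cc), 1L)]
      }, 0L)
    }
    sw <- spec$sonication_halfwidth
    rec <- data.frame(
      read_id = sprintf("m%07d", seq_len(n)),
      chrom1 = vp$chrom, pos1 = bait, strand1 = "+",
      frag1 = assignToFragment(vp$chrom, pmin(bait, map@seqlengths[[vp$chrom]] - 1L), map),
      chrom2 = chrom2, pos2 = pos2,
      strand2 = sample(c("+", "-"), n, replace = TRUE),
      frag2 = NA_integer_,
      sonication_end = pos2 + sample.int(2L * sw + 1L, n, replace = TRUE) - sw - 1L,
      allele = NA_character_, copies = 1L, viewpoint_id = "vp1",
      stringsAsFactors = FALSE)
    rec$frag2 <- assignToFragment(rec$chrom2,
                                  pmin(rec$pos2, map@seqlengths[rec$chrom2] - 1L),
                                  map)
    n_unique <- length(unique(.umiKey(rec, "4C")))
    rec <- .addDuplicates(rec, spec$dup_rate)
    list(rec = rec, n_unique = n_unique)
  })
  table <- new("ContactTable", records = out$rec,
               metadata = list(mode = "4C", source = "simulateTri4C",
                               viewpoint = vp, viewpoint_cut = bait,
                               seqlengths = map@seqlengths,
                               enzymes = map@enzymes, deduped = FALSE))
  truth <- list(n_molecules = spec$n_molecules, n_unique_umi = out$n_unique,
                n_records = nrow(out$rec), loops = spec$loops,
                alpha = spec$alpha, viewpoint = vp, bait_cut = bait)
  list(table = table, truth = truth)
}

#' Simulate a triple-digest Hi-C library
#'
#' Enumerates cut-site pairs (i, j) on one chromosome (optionally bounded by
#' `max_span`) and draws `n_molecules` pairs with probability proportional
#' to |pos_j - pos_i|^(-alpha) times the domain factor (down-weighting per
#' crossed boundary), the product of the anchors' marginal hotspot folds
#' h_i * h_j, and any injected loop fold. Ligation-end orientations are
#' sampled from the configured 4-vector, the sonication end is uniform around
#' the second cut, and PCR duplicates are appended at the requested rate.
#'
#' @param spec a [simulationSpec()] in HiC mode.
#' @param map a [FragmentMap-class] of the same genome.
#' @return list with `table` (pre-dedup anchor-free [ContactTable-class])
#'   and `truth` (ledger list).
#' @export
simulateTriHiC <- function(spec, map) {
  stopifnot(inherits(spec, "SimulationSpec"), is(map, "FragmentMap"))
  if (spec$mode != "HiC") stop("spec is not in HiC mode")
  chrom <- names(map@seqlengths)[1L]
  cuts <- map@cuts[[chrom]]$pos
  nc <- length(cuts)
  if (nc < 2L) stop("need at least two cut sites")
  span <- if (is.null(spec$max_span)) map@seqlengths[[chrom]] else spec$max_span
  hi <- findInterval(cuts + span, cuts)
  cnt <- pmax(hi - seq_len(nc), 0L)
  if (sum(cnt) > 2e7)
    stop("pair enumeration too large (", sum(cnt), "); reduce max_span")
  i <- rep(seq_len(nc), cnt)
  j <- i + sequence(cnt)

  d <- cuts[j] - cuts[i]
  cells <- .cutCells(cuts, map@seqlengths[[chrom]])
  w <- pmax(d, 1)^(-spec$alpha) * cells[i] * cells[j]
  h <- .hotspotFolds(cuts, spec$hotspots)
  w <- w * h[i] * h[j]
  if (!is.null(spec$domains)) {
    db <- sort(spec$domains$boundaries)
    dom <- findInterval(cuts, db)
    ncross <- abs(dom[j] - dom[i])
    w <- w * spec$domains$ratio^(-ncross)
  }
  if (!is.null(spec$loops))
    for (q in seq_len(nrow(spec$loops))) {
      w2 <- spec$loops$width[q] / 2
      lo <- min(spec$loops$pos1[q], spec$loops$pos2[q])
      hi2 <- max(spec$loops$pos1[q], spec$loops$pos2[q])
      sel <- cuts[i] >= lo - w2 & cuts[i] < lo + w2 &
        cuts[j] >= hi2 - w2 & cuts[j] < hi2 + w2
      w[sel] <- w[sel] * spec$loops$fold[q]
    }

  ## orientation classes: side 1 "-" points away from its partner (out),
  ## side 2 "+" points away. in-in = (+,-) ... out-out = (-,+).
  ori_s1 <- c("+", "+", "-", "-")
  ori_s2 <- c("-", "+", "-", "+")

  out <- .withSeed(spec$seed, {
    n <- spec$n_molecules
    pick <- sample.int(length(w), n, replace = TRUE, prob = w)
    cls <- sample.int(4L, n, replace = TRUE, prob = spec$orientation)
    sw <- spec$sonication_halfwidth
    p1 <- cuts[i[pick]]; p2 <- cuts[j[pick]]
    L <- map@seqlengths[[chrom]]
    rec <- data.frame(
      read_id = sprintf("m%07d", seq_len(n)),
      chrom1 = chrom, pos1 = p1, strand1 = ori_s1[cls],
      frag1 = assignToFragment(chrom, pmin(p1, L - 1L), map),
      chrom2 = chrom, pos2 = p2, strand2 = ori_s2[cls],
      frag2 = assignToFragment(chrom, pmin(p2, L - 1L), map),
      sonication_end = p2 + sample.int(2L * sw + 1L, n, replace = TRUE) - sw - 1L,
      allele = NA_character_, copies = 1L, viewpoint_id = NA_character_,
      stringsAsFactors = FALSE)
    n_unique <- length(unique(.umiKey(rec, "HiC")))
    rec <- .addDuplicates(rec, spec$dup_rate)
    list(rec = rec, n_unique = n_unique)
  })
  table <- new("ContactTable", records = out$rec,
               metadata = list(mode = "HiC", source = "simulateTriHiC",
                               seqlengths = map@seqlengths,
                               enzymes = map@enzymes, deduped = FALSE))
  truth <- list(n_molecules = spec$n_molecules, n_unique_umi = out$n_unique,
                n_records = nrow(out$rec), loops = spec$loops,
                hotspots = spec$hotspots, domains = spec$domains,
                alpha = spec$alpha, chrom = chrom)
  list(table = table, truth = truth)
}
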
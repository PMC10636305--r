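test_that("matrix binning places contacts and conserves total mass", {
  rec <- data.frame(chrom1 = "chrS", pos1 = 150L, strand1 = "+",
                    chrom2 = "chrS", pos2 = 950L, strand2 = "-")
  tab <- makeContactTable(rec, mode = "HiC",
                          metadata = list(seqlengths = c(chrS = 2000L)))
  mat <- binMatrix(tab, 100L)
  e <- matrixEntries(mat)
  expect_equal(e$i, 1L); expect_equal(e$j, 9L); expect_equal(e$count, 1L)
  expect_error(binMatrix(tab, 0L), "positive")

  withr::with_seed(401, {
    n <- 5000L
    p1 <- sample(0:99999, n, TRUE); p2 <- sample(0:99999, n, TRUE)
    tab2 <- makeContactTable(
      data.frame(chrom1 = "c1", pos1 = pmin(p1, p2), strand1 = "+",
                 chrom2 = "c1", pos2 = pmax(p1, p2), strand2 = "-"),
      mode = "HiC", metadata = list(seqlengths = c(c1 = 100000L)))
    m100 <- binMatrix(tab2, 100L)
    expect_equal(matrixTotal(m100), n)
    ## rebinning the 100 bp matrix to 1 kb equals direct 1 kb binning
    m1000 <- binMatrix(tab2, 1000L)
    e100 <- matrixEntries(m100)
    i2 <- pmin(e100$i %/% 10L, e100$j %/% 10L)
    j2 <- pmax(e100$i %/% 10L, e100$j %/% 10L)
    agg <- rowsum(e100$count, paste(i2, j2, sep = ","))
    e1k <- matrixEntries(m1000)
    expect_equal(nrow(e1k), nrow(agg))
    expect_equal(e1k$count,
                 as.integer(agg[paste(e1k$i, e1k$j, sep = ","), 1]))
  })
})

test_that("virtual 4C equals direct profiling when every contact touches the viewpoint", {
  withr::with_seed(402, {
    vp <- list(chrom = "chrS", start = 49500L, end = 50500L)
    n <- 2000L
    rec <- data.frame(chrom1 = "chrS",
                      pos1 = sample(49500:50499, n, TRUE), strand1 = "+",
                      chrom2 = "chrS",
                      pos2 = sample(c(0:49000, 51000:199999), n, TRUE),
                      strand2 = "-")
    ## anchor-free order for the HiC table
    hic <- makeContactTable(
      data.frame(chrom1 = "chrS", pos1 = pmin(rec$pos1, rec$pos2),
                 strand1 = "+", chrom2 = "chrS",
                 pos2 = pmax(rec$pos1, rec$pos2), strand2 = "-"),
      mode = "HiC", metadata = list(seqlengths = c(chrS = 200000L)))
    fourc <- makeContactTable(rec, mode = "4C",
                              metadata = list(seqlengths = c(chrS = 200000L)))
    v <- virtual4C(hic, vp)
    d <- binProfile(fourc, vp)
    expect_equal(profileBins(v)$M, profileBins(d)$M)
    expect_equal(profileTotal(v), profileTotal(d))
    ## viewpoint with no touching contacts (49001-49499 is never sampled)
    v0 <- virtual4C(hic, list(chrom = "chrS", start = 49050L, end = 49450L))
    expect_true(all(profileBins(v0)$M == 0))
    expect_error(virtual4C(hic, list(chrom = "chrS", start = 5L, end = 5L)),
                 "empty viewpoint")
  })
})

test_that("virtual 4C plus the loop caller recovers loops touching the viewpoint", {
  sm <- smallGenomeMap()
  vp <- list(chrom = "chrS", start = 99500L, end = 100500L)
  loop_pos <- 150250
  hits <- vapply(1:5, function(s) {
    spec <- simulationSpec(4e5, 3e6, mode = "HiC", seed = 410 + s, alpha = 1,
                           max_span = 1e5,
                           loops = data.frame(pos1 = 100000, pos2 = loop_pos,
                                              fold = 8, width = 500))
    sim <- simulateTriHiC(spec, sm$map)
    prof <- addLocalBackground(virtual4C(sim$table, vp))
    loops <- callLoops(prof)
    any(loops$start <= loop_pos & loops$end >= loop_pos)
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("distal interactivity flags an injected hotspot and stays monotone", {
  sm <- smallGenomeMap()
  hp <- 150050  # centre at a step-bin window centre
  spec <- simulationSpec(4e5, 15000, mode = "HiC", seed = 420, alpha = 1,
                         max_span = 100000,
                         hotspots = data.frame(pos = hp, fold = 10,
                                               width = 500))
  sim <- simulateTriHiC(spec, sm$map)
  track <- distalInteractivity(dedupContacts(sim$table))
  iv <- hotspotIntervals(track)
  expect_equal(nrow(iv), 1L)
  expect_true(iv$start <= hp && iv$end >= hp)
  ## expected reads at the hotspot are ample (>= 50)
  expect_gt(track$D[track$start == hp - 50], 50)

  ## null: no features, no flags
  spec0 <- simulationSpec(4e5, 15000, mode = "HiC", seed = 421, alpha = 1,
                          max_span = 100000)
  track0 <- distalInteractivity(dedupContacts(simulateTriHiC(spec0, sm$map)$table))
  expect_equal(nrow(hotspotIntervals(track0)), 0L)

  ## S = -log10 p is monotone non-decreasing in D at fixed E
  s <- -log10(poissonPValue(0:50, 7.5))
  expect_true(all(diff(s) >= 0))
})

test_that("insulation scores are flat on constant matrices and find block junctions", {
  nb <- 60L
  const <- matrixFromDense(matrix(5L, nb, nb))
  tr <- insulationTrack(const, window_bins = 10L)
  expect_true(all(abs(tr$score[is.finite(tr$score)]) < 1e-12))
  expect_equal(nrow(attr(tr, "boundaries")), 0L)

  ## two blocks, junction between 0-based bins 29 and 30 (coordinate 30 kb)
  M <- matrix(1L, nb, nb)
  M[1:30, 1:30] <- 10L
  M[31:nb, 31:nb] <- 10L
  blocks <- matrixFromDense(M)
  tr2 <- insulationTrack(blocks, window_bins = 10L)
  bd <- attr(tr2, "boundaries")
  expect_equal(nrow(bd), 1L)
  expect_equal(bd$coord, 30 * 1000)
  ## the log-ratio-to-mean convention keeps the track centred near zero
  ## even on this extreme bimodal construction
  expect_lt(abs(mean(tr2$score, na.rm = TRUE)), 0.35)
  expect_error(insulationTrack(blocks, window_bins = 30L), "half")
})

test_that("APA is unity on decay-only matrices and identity for one loop", {
  withr::with_seed(430, {
    nb <- 150L
    d <- abs(row(diag(nb)) - col(diag(nb)))
    lam <- 400 / (d + 2)
    M <- matrix(stats::rpois(nb * nb, lam), nb, nb)
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    mat <- matrixFromDense(M, resolution = 500L)
    loops <- data.frame(chrom1 = "chrS",
                        start1 = c(20, 40, 60, 80) * 500,
                        end1 = c(21, 41, 61, 81) * 500,
                        chrom2 = "chrS",
                        start2 = c(60, 90, 100, 130) * 500,
                        end2 = c(61, 91, 101, 131) * 500)
    res <- apa(mat, loops, flank_bins = 10L)
    expect_equal(res$n_loops, 4L)
    expect_lt(abs(res$center_fe - 1), 0.3)
    ## a single loop with k = 1 reproduces its own 3x3 O/E neighbourhood
    one <- loops[1, ]
    r1 <- apa(mat, one, flank_bins = 1L)
    OE <- trichrom:::.observedExpected(trichrom:::.denseCounts(mat))
    bi <- 20L; bj <- 60L
    expect_equal(r1$apa, OE[bi + (-1:1) + 1L, bj + (-1:1) + 1L])
    ## loops hugging the diagonal are unusable
    expect_error(suppressWarnings(
      apa(mat, data.frame(chrom1 = "chrS", start1 = 20 * 500,
                          end1 = 21 * 500, chrom2 = "chrS",
                          start2 = 25 * 500, end2 = 26 * 500),
          flank_bins = 10L)), "no usable loops")
  })
})

test_that("injected matrix loops are recovered by APA at their fold", {
  sm <- smallGenomeMap()
  r <- 500L
  pos1 <- c(60250, 100250, 150250, 200250, 250250, 300250)
  pos2 <- pos1 + c(20000, 30000, 25000, 40000, 30000, 22000)
  loops <- data.frame(pos1 = pos1, pos2 = pos2, fold = 6, width = 3 * r)
  spec <- simulationSpec(4e5, 1e6, mode = "HiC", seed = 431, alpha = 1,
                         loops = loops)
  sim <- simulateTriHiC(spec, sm$map)
  mat <- binMatrix(sim$table, r)
  bedpe <- data.frame(chrom1 = "chrS", start1 = loops$pos1 - 250,
                      end1 = loops$pos1 + 250, chrom2 = "chrS",
                      start2 = loops$pos2 - 250, end2 = loops$pos2 + 250)
  res <- apa(mat, bedpe, flank_bins = 10L)
  expect_lt(abs(res$center_fe - 6), 6 * 0.3)
  ## z-scores light up the centre
  k <- 10L + 1L
  expect_gt(res$z[k, k], 2.5)
})

test_that("stripe residuals compare loop strength to anchor stripe products", {
  ## arithmetic contract on a hand-built track
  hs <- data.frame(start = seq(0, 9900, by = 100), D = 10, E = 5,
                   p = 0.5, score = 0.3, hotspot = FALSE)
  hs$hotspot[hs$start == 2000] <- TRUE
  hs$D[hs$start == 2000] <- 10  # FE 2 at both anchors
  hs$hotspot[hs$start == 8000] <- TRUE
  hs$D[hs$start == 8000] <- 10
  attr(hs, "step") <- 100L
  loops <- data.frame(chrom1 = "c", start1 = 1800, end1 = 2300,
                      chrom2 = "c", start2 = 7800, end2 = 8300, fe = 8)
  res <- stripeResidual(loops, hs)
  expect_equal(res$residual, 2.0)
  expect_equal(res$log2_residual, 1.0)
  expect_warning(stripeResidual(transform(loops, fe = -1), hs), "skipped")

  ## multiplicative null: loop pixel O/E ~ product of anchor stripe FEs
  sm <- smallGenomeMap()
  ## anchor centres on a matrix-pixel centre (x+250 for 500 bp pixels) so
  ## the 1D windows, hotspot windows and loop pixel coincide exactly
  anchors <- c(130250, 170250)
  base <- data.frame(pos = anchors, fold = 5, width = 500)
  spec0 <- simulationSpec(4e5, 3e5, mode = "HiC", seed = 440, alpha = 1,
                          hotspots = base, max_span = 100000)
  tab0 <- dedupContacts(simulateTriHiC(spec0, sm$map)$table)
  track0 <- distalInteractivity(tab0)
  bedpe <- data.frame(chrom1 = "chrS", start1 = anchors[1] - 250,
                      end1 = anchors[1] + 250, chrom2 = "chrS",
                      start2 = anchors[2] - 250, end2 = anchors[2] + 250)
  mat0 <- binMatrix(tab0, 500L)
  bedpe$fe <- loopStrengthFromMatrix(mat0, bedpe, halfwidth = 0L)
  r0 <- stripeResidual(bedpe, track0)
  expect_lt(abs(r0$log2_residual), 0.75)

  ## super-multiplicative loop on the same hotspot background
  spec6 <- simulationSpec(4e5, 3e5, mode = "HiC", seed = 441, alpha = 1,
                          hotspots = base, max_span = 100000,
                          loops = data.frame(pos1 = anchors[1],
                                             pos2 = anchors[2],
                                             fold = 6, width = 500))
  tab6 <- dedupContacts(simulateTriHiC(spec6, sm$map)$table)
  track6 <- distalInteractivity(tab6)
  mat6 <- binMatrix(tab6, 500L)
  bedpe$fe <- loopStrengthFromMatrix(mat6, bedpe, halfwidth = 0L)
  r6 <- stripeResidual(bedpe, track6)
  expect_gt(r6$residual, 3)
})

test_that("loop asymmetry reads interior and exterior stripe bands", {
  nb <- 200L
  d <- abs(row(diag(nb)) - col(diag(nb)))
  base <- 1000 / (d + 5)
  b1 <- 80L; b2 <- 120L  # 0-based anchors
  ## symmetric loop with equal stripes both sides of both anchors
  S <- base
  rows <- (b1 + 1L) + (-1:1)
  S[rows, ] <- S[rows, ] * 3; S[, rows] <- S[, rows] * 3
  cols <- (b2 + 1L) + (-1:1)
  S[cols, ] <- S[cols, ] * 3; S[, cols] <- S[, cols] * 3
  diag(S) <- base[1, 1]
  sym <- matrixFromDense(matrix(as.integer(round(S)), nb, nb),
                         resolution = 500L)
  loop <- data.frame(chrom1 = "chrS", start1 = b1 * 500, end1 = (b1 + 1) * 500,
                     chrom2 = "chrS", start2 = b2 * 500, end2 = (b2 + 1) * 500)
  a <- loopAsymmetry(sym, loop, span_bins = 10L)
  expect_lt(abs(a$asymmetry1 - 1), 0.25)
  expect_lt(abs(a$asymmetry2 - 1), 0.25)

  ## anchor 1's stripe halved beyond the loop (exterior side)
  S2 <- S
  ext_cols <- seq_len(b1 - 1L)  # columns left of anchor 1 (1-based)
  S2[rows, ext_cols] <- S2[rows, ext_cols] / 2
  S2[ext_cols, rows] <- S2[ext_cols, rows] / 2
  half <- matrixFromDense(matrix(as.integer(round(S2)), nb, nb),
                          resolution = 500L)
  a2 <- loopAsymmetry(half, loop, span_bins = 10L)
  expect_lt(abs(a2$asymmetry1 - 0.5), 0.15)
  expect_lt(abs(a2$asymmetry2 - 1), 0.25)

  ## decay-only matrix: all bands near unity
  withr::with_seed(450, {
    Mn <- matrix(stats::rpois(nb * nb, base * 3), nb, nb)
    Mn[lower.tri(Mn)] <- t(Mn)[lower.tri(Mn)]
    dec <- matrixFromDense(Mn, resolution = 500L)
    a3 <- loopAsymmetry(dec, loop, span_bins = 10L)
    for (v in c("interior1", "exterior1", "interior2", "exterior2"))
      expect_lt(abs(a3[[v]] - 1), 0.2)
    expect_false(a3$truncated)
  })
})
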
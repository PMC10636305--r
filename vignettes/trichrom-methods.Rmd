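---
title: "Models and methods behind trichrom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind trichrom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

trichrom analyses chromatin conformation capture libraries built with
*multiple* 4-bp cutter restriction enzymes, which fragment the genome
finely enough (mean spacing ~85 bp for a triple digest) that contacts can
be profiled at 100 bp resolution — the scale of individual cis-regulatory
elements. This vignette explains the statistical models, the tunable
parameters, and the design choices that were genuinely open; the README
shows the workflows.

## Coordinates and containers

All coordinates are 0-based, half-open (the BED convention), both on disk
and in memory. A restriction *cut coordinate* is the inter-base position of
the forward-strand nick: occurrence start + the enzyme's cut offset. Four
S4 classes carry the data: `FragmentMap` (cut sites and the fragments they
delimit, which tile each chromosome exactly), `ContactTable` (ligation
contacts located at the *ligated restriction-cut coordinate* of each side —
the position the assay actually tags, not the fragment midpoint),
`InteractionProfile` (a 100 bp-step viewpoint profile) and `ContactMatrix`
(sparse upper-triangular binned counts). Tracks and per-loop results are
plain data frames.

## In silico digestion

Recognition words are matched exactly on the forward strand
(`Biostrings::matchPattern`); all built-in words (GATC, GTAC, CATG) are
reverse-complement palindromes, so one strand suffices. Windows containing
N never match, so runs of N inflate fragment length rather than being
special-cased. When two enzymes nick the same coordinate a single cut is
kept, labelled with the lexicographically first enzyme name — a
deterministic, testable tie-break. Only the blunted-product boundary
matters downstream, so overhang geometry beyond the cut offset is not
modelled.

One analytic subtlety: the naive cut density for k distinct 4-mers, k/256
per position, overcounts slightly because different words can nick the same
coordinate (GATC at c with CATG at c-4; GTAC at c-1 with CATG at c-4 via
the overlap word CATGTAC). The exact density for the DpnII/Csp6I/NlaIII
triple is 3/256 − 1/4^8 − 1/4^7, giving a mean fragment of 85.9 bp rather
than 85.3 bp on an iid-uniform sequence; the test suite asserts the exact
value because at the simulated scale the difference is statistically
detectable.

## UMI deduplication

Sonication shear breaks are effectively unique per molecule, so the shear
coordinate serves as a molecular identifier. The dedup key is the
viewpoint id, the distal side's chromosome, fragment id, ligated-end
coordinate and strand, and the *exact* sonication-end coordinate — no ±1 bp
tolerance, because exactness is deterministic and matches UMI practice. In
anchor-free (Hi-C) mode the key additionally includes side 1: there the
first side is itself a distal end, and the 4C key would spuriously collapse
distinct molecules that merely share their second end. The survivor's
`copies` is the summed multiplicity of its group, which makes deduplication
idempotent and conserves the total read count. Records lacking a
sonication end cannot be keyed; they pass through unchanged with a counted
warning.

Two real molecules that draw the same distal cut, strand and shear break
are genuinely indistinguishable; the simulator therefore records the number
of *distinct UMI keys* among its molecules as the exact expectation for the
dedup output (collisions concentrate at bait-proximal sites and are rare,
<2% at the simulated coverages).

## Viewpoint profiles and loop calling

Each 100 bp sliding bin collects the raw unique-contact count M from its
centred 500 bp window (`[start − 200, start + 300)`); the window must be an
odd multiple of the step. `M_norm` rescales M per 10,000 unique cis
contacts for cross-library display.

The expected count N follows the dynamic local-background convention of
peak callers in the MACS tradition: the bin's density is measured over
centred spans with half-widths 2.5/5/10/25 kb (total spans 5–50 kb),
excluding ±1 kb around the bin so a peak does not inflate its own
background, and the *maximum* density across spans — the conservative
choice — times the window gives N. Spans are truncated at the region edges
with their lengths adjusted, and each span's count is floored at a
pseudo-count of 0.5 reads so N is always positive (configurable). p is the
exact Poisson upper tail P(X ≥ M), never a normal approximation.

Loop calling Bonferroni-corrects over the tested bins at family-wise alpha
0.05 (the significance policy is not dictated by the data model; Bonferroni
mirrors the hotspot caller's threshold philosophy). Bins within 5 kb of the
viewpoint are excluded — the self-ligation/re-ligation zone, and also where
background spans inevitably cross the viewpoint. Runs of significant bins
separated by less than 500 bp (one window) merge into a loop; the summit is
the leftmost minimal-p bin and the loop strength is log2(M/N) there. With
two or more replicates a loop is *reproducible* if a significant merged
interval of every replicate overlaps it by ≥1 bp (summit identity is not
required), and only reproducible loops are reported by default. Background
estimation is single-pass: previously called loops are not excluded when
computing N.

The alternative global background (`distanceModelBackground`) fits mean M
against log10 distance with a monotone-decreasing isotonic regression over
50 log-spaced distance bins and evaluates the fit per bin — a drop-in
replacement for comparing the local-background algorithm against
distance-model callers.

Differential tests between conditions use the exact conditional binomial:
conditioned on the pooled loop count, the condition-A count is binomial
with success probability T_A/(T_A + T_B) given the library sizes, so global
scaling cancels; fold changes are computed on library-normalised counts and
Benjamini–Hochberg corrected across loops. Allele-specific tests are the
same construction with allele library sizes. ROC evaluation uses the
rank-based AUC (ties count one half), identical to all-pairs counting.

## Matrix-level analytics

`distalInteractivity` applies the loop caller's machinery to the marginal
track: D counts contact *ends* in each bin's 500 bp window whose partner
lies ≥10 kb away ("distal" is not externally defined; 10 kb clears the
strongest decay region and is configurable), E reuses the 5–50 kb
max-over-scales background, and bins with p < 3e-7 — a stringent
Bonferroni-scale threshold — are flagged and merged into hotspot intervals.

The expected model for APA, stripe and asymmetry analytics is the
per-diagonal mean count (distance-decay expected), not iterative matrix
balancing: every quantitative target here is simulation-based and the
smallest faithful model is preferred; balancing is out of scope. APA
averages (2k+1)×(2k+1) observed/expected submatrices over loop pixels; the
centre fold enrichment divides the central 3×3 mean by the lower-left
corner 3×3 mean, and Z-scores standardise against the non-central cells.
Insulation follows the log2-ratio-to-mean diamond convention (default 1 kb
bins, w = 25 bins, the sub-TAD scale); boundary calls are score minima
(plateaus merged) with prominence ≥ 0.1, and the reported coordinate is the
centre of the minimal run — exactly the junction coordinate for an abrupt
two-block matrix, because the diamond is symmetric around the junction's
two flanking bins.

Stripe residuals quantify whether a loop exceeds the multiplicative overlap
of its anchors' nonspecific stripes: residual = FE_loop/(FE_a1·FE_a2), with
anchor FEs taken from the 1D interactivity track (nearest flagged hotspot
bin within 1 kb, else the anchor bin's own D/E). The alternative of
measuring stripe strength from a matrix band is available
through `loopAsymmetry`'s band means; which definition the original
analysis used is not asserted.

## The simulator

`simulateTri4C`/`simulateTriHiC` generate ligation libraries with known
ground truth. The underlying contact intensity is uniform per basepair
times d^(−alpha) (default alpha = 1, the intra-TAD regime of the observed
log-linear decay; the exponent is configurable because only the overall
log-linearity is established) times injected loop folds, hotspot marginal
folds h_i·h_j, and a per-crossing domain down-weight. A ligation is
recorded at the nearest assayable *cut coordinate*, which therefore carries
the basepair measure of its Voronoi cell (half-way to each neighbouring
cut): a long fragment's end collects proportionally more contacts, exactly
as a fragment-constrained assay does. Sonication ends are uniform within
±300 bp of the distal cut (the 300–400 bp shear target); PCR duplicates are
appended so that the requested fraction of final records are copies;
orientations follow the configured 4-vector; everything is driven by one
seed
through a fixed Mersenne-Twister stream, so output is bit-reproducible
across platforms and the caller's RNG state is left untouched.

What the simulator deliberately does not emulate: sequencing errors and
read-level artefacts, mappability, GC/tagmentation bias, chromatin
compartments, and biological replicate variability beyond Poisson sampling.
Passing tests therefore demonstrate calibration and recovery under the
generative model, not robustness to genomic confounders.

A consequence of fragment-constrained coordinates worth knowing: window
counts inherit a granularity variance of roughly 10–15% (the window's cell
measure fluctuates with local fragment structure), so at very high window
occupancy (hundreds of reads, e.g. within ~30 kb of a deeply sequenced
viewpoint) the Poisson model is mildly overdispersed and occasional
borderline calls appear even on feature-free libraries. The study
conditions for null calibration — 100,000 molecules over a 10 Mb
chromosome, i.e. ~5 reads per 500 bp window on the uniform background —
keep tested bins in the Poisson-dominated regime; at those conditions 20
seeded null runs (10 uniform, 10 decay) produce zero reproducible loops in
at least 19, and 20 null Hi-C runs produce zero hotspots at 3e-7.

## Problem sizes used by the checks

The packaged checks run on: a 10 Mb chromosome for digestion statistics and
viewpoint-caller calibration (cut spacings drawn from the analytic triple-
digest distribution where a full sequence is unnecessary); a 400 kb
digested random genome for matrix-level callers (500 bp matrices, 15k–3M
contacts depending on the statistic's power needs); and constructed
matrices for exact checks (insulation junctions, asymmetry bands). Loop
recovery is measured at injected folds 2/4/8 with 100k molecules and two
replicates over 20 seeds; APA at fold 6 over 20 seeds; stripe residuals
over 5 seeds under the multiplicative null and with a fold-6 loop.

## Known limitations

- Loops closer than ~30 kb to a deeply covered viewpoint are hard to
  detect with the max-over-scales background, because the 50 kb span
  crosses the viewpoint's hot zone and inflates N; this is the price of the
  conservative background and matches the caller's intent.
- Trans-chromosomal loop calling, matrix balancing, compartment analysis
  and motif-level analyses are out of scope.
- The pairs-format adapter consumes pre-mapped coordinates; alignment is
  upstream of this package.
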
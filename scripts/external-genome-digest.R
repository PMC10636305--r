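#!/usr/bin/env Rscript
## OPTIONAL EXTERNAL CHECK — requires a locally available human (or other
## large) genome assembly FASTA; nothing is downloaded. Reproduces the
## genome-scale digestion summaries: the fraction of triple-digest
## fragments shorter than 500 bp and the single-enzyme vs triple-digest
## fold reduction in mean fragment length.
##
## Usage: Rscript scripts/external-genome-digest.R --fasta /path/to/assembly.fa

suppressPackageStartupMessages(library(trichrom))

args <- commandArgs(trailingOnly = TRUE)
i <- which(args == "--fasta")
if (!length(i) || i == length(args))
  stop("usage: Rscript scripts/external-genome-digest.R --fasta assembly.fa")
fasta <- args[i + 1L]

enzymes <- c("DpnII", "Csp6I", "NlaIII")
triple <- fragmentStats(digestGenome(fasta, enzymes))
cat(sprintf("triple digest: mean %.1f bp, %.2f%% of fragments < 500 bp\n",
            triple$mean, 100 * triple$frac_below))
for (e in enzymes) {
  single <- fragmentStats(digestGenome(fasta, e))
  cat(sprintf("%s alone: mean %.1f bp; fold reduction vs triple %.2f\n",
              e, single$mean, single$mean / triple$mean))
}
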
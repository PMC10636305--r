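#' Construct an enzyme specification
#'
#' @param name short enzyme name.
#' @param recognition 4-letter recognition word over A/C/G/T.
#' @param cutOffset cut position within the recognition word (0..4), measured
#'   from its first base on the forward strand.
#' @return an [EnzymeSpec-class] object.
#' @examples
#' enzymeSpec("DpnII", "GATC", 0)
#' @export
enzymeSpec <- function(name, recognition, cutOffset) {
  new("EnzymeSpec", name = as.character(name),
      recognition = toupper(as.character(recognition)),
      cutOffset = as.integer(cutOffset))
}

#' Built-in 4-bp cutter enzymes
#'
#' The four enzyme/isoschizomer specifications used by triple-digest 4C and
#' Hi-C libraries: DpnII/MboI (GATC, cut before the site), Csp6I/CviQI
#' (GTAC, cut after the G), NlaIII (CATG, cut after the site) and CviAII
#' (CATG, cut after the C). All recognition words are reverse-complement
#' palindromes, so forward-strand matching finds every site.
#'
#' @return named list of [EnzymeSpec-class] objects.
#' @examples
#' names(builtinEnzymes())
#' @export
builtinEnzymes <- function() {
  list(
    DpnII  = enzymeSpec("DpnII",  "GATC", 0L),
    MboI   = enzymeSpec("MboI",   "GATC", 0L),
    Csp6I  = enzymeSpec("Csp6I",  "GTAC", 1L),
    CviQI  = enzymeSpec("CviQI",  "GTAC", 1L),
    NlaIII = enzymeSpec("NlaIII", "CATG", 4L),
    CviAII = enzymeSpec("CviAII", "CATG", 1L)
  )
}

## Normalise `enzymes` (character names, a single EnzymeSpec, or a list of
## them) to a list of validated EnzymeSpec objects.
.resolveEnzymes <- function(enzymes) {
  if (is(enzymes, "EnzymeSpec")) enzymes <- list(enzymes)
  if (is.character(enzymes)) {
    reg <- builtinEnzymes()
    unknown <- setdiff(enzymes, names(reg))
    if (length(unknown))
      stop("unknown enzyme(s): ", paste(unknown, collapse = ", "),
           " (use enzymeSpec() for custom enzymes)")
    enzymes <- reg[enzymes]
  }
  if (!is.list(enzymes) || length(enzymes) == 0L)
    stop("at least one enzyme must be supplied")
  for (e in enzymes) {
    if (!is(e, "EnzymeSpec")) stop("enzymes must be EnzymeSpec objects or names")
    validObject(e)
  }
  enzymes
}

#' Find restriction cut sites in a nucleotide sequence
#'
#' Exact forward-strand matching of each enzyme's 4-letter recognition word;
#' a site's cut coordinate is its occurrence start plus the enzyme's cut
#' offset (0-based inter-base position). Matching is case-insensitive and
#' windows containing N never match. Overlapping occurrences of different
#' words are each reported; if two enzymes cut at the same coordinate a
#' single cut is kept, labelled with the lexicographically first enzyme
#' name.
#'
#' @param sequence a character string or [Biostrings::DNAString] over
#'   A/C/G/T/N.
#' @param enzymes enzyme names (see [builtinEnzymes()]) or a list of
#'   [EnzymeSpec-class] objects.
#' @return data.frame with columns `pos` (sorted cut coordinates) and
#'   `enzyme`.
#' @examples
#' findCutSites("TTGATCTTGTACTTCATGTT", c("DpnII", "Csp6I", "NlaIII"))
#' @export
findCutSites <- function(sequence, enzymes) {
  enzymes <- .resolveEnzymes(enzymes)
  subject <- if (is(sequence, "DNAString")) sequence
             else Biostrings::DNAString(toupper(as.character(sequence)))
  pos <- integer(0); enz <- character(0)
  for (e in enzymes) {
    ## fixed = TRUE: N in the subject matches nothing
    hits <- Biostrings::matchPattern(e@recognition, subject, fixed = TRUE)
    if (length(hits)) {
      pos <- c(pos, Biostrings::start(hits) - 1L + e@cutOffset)
      enz <- c(enz, rep(e@name, length(hits)))
    }
  }
  ord <- order(pos, enz)
  pos <- pos[ord]; enz <- enz[ord]
  keep <- !duplicated(pos)
  data.frame(pos = pos[keep], enzyme = enz[keep], stringsAsFactors = FALSE)
}

#' Build a fragment map from cut coordinates
#'
#' Turns per-chromosome sorted cut lists into restriction fragments that
#' tile each chromosome exactly as half-open intervals. Cuts at coordinate 0
#' or at the chromosome length are deduplicated with the chromosome
#' boundaries (no empty fragments). Fragment ids are globally unique,
#' assigned sequentially across chromosomes.
#'
#' @param cuts a data.frame as from [findCutSites()] (single chromosome), or
#'   a named list of such data.frames (one per chromosome). Bare integer
#'   vectors are also accepted (enzyme label then unknown).
#' @param chrom_lengths named integer vector of chromosome lengths; for the
#'   single-chromosome data.frame form, a single possibly unnamed length.
#' @param enzymes character vector of enzyme names for the map metadata.
#' @return a [FragmentMap-class].
#' @examples
#' buildFragmentMap(data.frame(pos = c(2L, 9L, 18L), enzyme = "DpnII"),
#'                  c(chrS = 20L))
#' @export
buildFragmentMap <- function(cuts, chrom_lengths, enzymes = character()) {
  norm1 <- function(x) {
    if (is.numeric(x)) x <- data.frame(pos = as.integer(x),
                                       enzyme = rep("unknown", length(x)),
                                       stringsAsFactors = FALSE)
    x[order(x$pos), , drop = FALSE]
  }
  if (!is.list(cuts) || is.data.frame(cuts)) {
    if (length(chrom_lengths) != 1L)
      stop("single cut table but ", length(chrom_lengths), " chromosome lengths")
    nm <- names(chrom_lengths)
    cuts <- stats::setNames(list(cuts), if (is.null(nm)) "chr1" else nm)
    names(chrom_lengths) <- names(cuts)
  }
  if (is.null(names(chrom_lengths)) || is.null(names(cuts)))
    stop("cuts and chrom_lengths must be named by chromosome")
  if (!all(names(cuts) %in% names(chrom_lengths)))
    stop("missing chromosome length(s) for: ",
         paste(setdiff(names(cuts), names(chrom_lengths)), collapse = ", "))
  chrom_lengths <- stats::setNames(as.integer(chrom_lengths),
                                   names(chrom_lengths))[names(cuts)]

  frag_list <- list(); cut_list <- list()
  next_id <- 1L
  for (ch in names(cuts)) {
    L <- chrom_lengths[[ch]]
    if (is.na(L) || L <= 0L) stop("invalid length for chromosome ", ch)
    cu <- norm1(cuts[[ch]])
    if (nrow(cu) && (any(cu$pos < 0L) || any(cu$pos > L)))
      stop("cut beyond chromosome ", ch, " (length ", L, ")")
    ## interior cuts only; boundary cuts collapse with the chromosome ends
    interior <- cu[cu$pos > 0L & cu$pos < L, , drop = FALSE]
    interior <- interior[!duplicated(interior$pos), , drop = FALSE]
    bounds <- c(0L, interior$pos, L)
    nf <- length(bounds) - 1L
    frag_list[[ch]] <- data.frame(
      start = bounds[-length(bounds)], end = bounds[-1L],
      id = seq.int(next_id, length.out = nf))
    cut_list[[ch]] <- interior
    next_id <- next_id + nf
  }
  new("FragmentMap", cuts = cut_list, fragments = frag_list,
      seqlengths = stats::setNames(chrom_lengths, names(cuts)),
      enzymes = as.character(enzymes))
}

#' Digest a genome in silico
#'
#' Convenience wrapper: finds cut sites for the given enzymes on every
#' record of a genome and builds the [FragmentMap-class].
#'
#' @param genome a [Biostrings::DNAStringSet], a named character vector of
#'   sequences, or the path to a FASTA file.
#' @param enzymes enzyme names or [EnzymeSpec-class] list.
#' @return a [FragmentMap-class].
#' @examples
#' digestGenome(c(chrS = "TTGATCTTGTACTTCATGTT"), c("DpnII", "Csp6I", "NlaIII"))
#' @export
digestGenome <- function(genome, enzymes) {
  enzymes <- .resolveEnzymes(enzymes)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(toupper(genome))
  if (!is(genome, "DNAStringSet")) stop("cannot interpret 'genome'")
  if (is.null(names(genome))) stop("genome records must be named")
  nm <- sub("\\s.*$", "", names(genome))
  cuts <- lapply(seq_along(genome), function(k) findCutSites(genome[[k]], enzymes))
  names(cuts) <- nm
  lens <- stats::setNames(Biostrings::width(genome), nm)
  buildFragmentMap(cuts, lens,
                   enzymes = vapply(enzymes, function(e) e@name, ""))
}

#' Fragment-length summary statistics
#'
#' @param map a [FragmentMap-class].
#' @param threshold report the fraction of fragments shorter than this many
#'   bp (default 500).
#' @return list with `n`, `mean`, `median`, `frac_below` and the `threshold`
#'   used.
#' @export
fragmentStats <- function(map, threshold = 500) {
  stopifnot(is(map, "FragmentMap"))
  len <- unlist(lapply(map@fragments, function(f) f$end - f$start),
                use.names = FALSE)
  if (!length(len)) stop("empty fragment map")
  list(n = length(len), mean = mean(len),
       median = stats::median(len),
       frac_below = mean(len < threshold), threshold = threshold)
}

#' Underdigested gap intervals
#'
#' Fragments longer than `min_gap` bp, i.e. stretches of the genome that the
#' digestion leaves untagged at the chosen granularity.
#'
#' @param map a [FragmentMap-class].
#' @param min_gap minimum fragment length in bp (must be positive).
#' @return BED-style data.frame (chrom, start, end, id), sorted.
#' @export
gapIntervals <- function(map, min_gap = 1000) {
  stopifnot(is(map, "FragmentMap"))
  if (min_gap <= 0) stop("'min_gap' must be positive")
  fr <- fragments(map)
  fr[fr$end - fr$start > min_gap, , drop = FALSE]
}
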
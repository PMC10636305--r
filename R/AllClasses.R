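#' @import methods
NULL

## All genomic coordinates in this package are 0-based, half-open (BED
## convention). A restriction "cut coordinate" is the inter-base position of
## the forward-strand nick, i.e. occurrence start + cut offset.

#' EnzymeSpec: a 4-bp-cutter restriction enzyme
#'
#' Describes a restriction enzyme by its 4-letter recognition word and the
#' position of the forward-strand nick within that word. Only enzymes with
#' 4-base recognition sites are supported; all built-in words are
#' reverse-complement palindromes so forward-strand matching suffices.
#'
#' @slot name short enzyme name.
#' @slot recognition 4-letter recognition word over A/C/G/T.
#' @slot cutOffset integer in 0..4, cut position within the recognition word
#'   measured from its first base.
#' @seealso [enzymeSpec()], [builtinEnzymes()]
#' @export
setClass("EnzymeSpec", representation(
  name = "character",
  recognition = "character",
  cutOffset = "integer"
))

setValidity("EnzymeSpec", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  rec <- object@recognition
  if (length(rec) != 1L || nchar(rec) != 4L)
    msg <- c(msg, "'recognition' must be a single 4-letter word")
  else if (grepl("[^ACGT]", rec))
    msg <- c(msg, "'recognition' must be over {A,C,G,T} (no N or IUPAC codes)")
  off <- object@cutOffset
  if (length(off) != 1L || is.na(off) || off < 0L || off > 4L)
    msg <- c(msg, "'cutOffset' must be an integer in 0..4")
  if (length(msg)) msg else TRUE
})

#' FragmentMap: genome tiling by restriction fragments
#'
#' Per-chromosome sorted cut coordinates together with the restriction
#' fragments they delimit. Fragments are half-open intervals `[start, end)`
#' that tile each chromosome exactly: the first fragment starts at 0, the
#' last ends at the chromosome length, and adjacent fragments abut. Every
#' interior boundary carries exactly one enzyme label (coordinate ties are
#' resolved to the lexicographically first enzyme name). Fragment ids are
#' integers, globally unique across chromosomes.
#'
#' @slot cuts named list (one element per chromosome) of data.frames with
#'   columns `pos` (0-based cut coordinate, strictly increasing) and
#'   `enzyme`.
#' @slot fragments named list of data.frames with columns `start`, `end`,
#'   `id`.
#' @slot seqlengths named integer vector of chromosome lengths.
#' @slot enzymes character vector of enzyme names used for the digestion.
#' @seealso [digestGenome()], [buildFragmentMap()], [fragmentStats()]
#' @export
setClass("FragmentMap", representation(
  cuts = "list",
  fragments = "list",
  seqlengths = "integer",
  enzymes = "character"
))

setValidity("FragmentMap", function(object) {
  msg <- character()
  chroms <- names(object@seqlengths)
  if (is.null(chroms) || !identical(sort(chroms), sort(names(object@fragments))) ||
      !identical(sort(chroms), sort(names(object@cuts))))
    return("'cuts', 'fragments' and 'seqlengths' must share chromosome names")
  for (ch in chroms) {
    fr <- object@fragments[[ch]]
    cu <- object@cuts[[ch]]
    L <- object@seqlengths[[ch]]
    if (nrow(fr) == 0L) { msg <- c(msg, sprintf("chromosome %s has no fragments", ch)); next }
    if (fr$start[1L] != 0L || fr$end[nrow(fr)] != L ||
        (nrow(fr) > 1L && any(fr$start[-1L] != fr$end[-nrow(fr)])))
      msg <- c(msg, sprintf("fragments do not tile chromosome %s", ch))
    if (any(fr$end <= fr$start))
      msg <- c(msg, sprintf("empty fragment on chromosome %s", ch))
    if (nrow(cu) > 1L && any(diff(cu$pos) <= 0))
      msg <- c(msg, sprintf("cut coordinates not strictly increasing on %s", ch))
    if (nrow(cu) && (any(cu$pos < 0L) || any(cu$pos > L)))
      msg <- c(msg, sprintf("cut coordinate outside chromosome %s", ch))
  }
  ids <- unlist(lapply(object@fragments, `[[`, "id"), use.names = FALSE)
  if (anyDuplicated(ids)) msg <- c(msg, "fragment ids are not globally unique")
  if (length(msg)) msg else TRUE
})

## Columns every ContactTable records data.frame must carry, in canonical
## order (matches the pairs-like TSV with viewpoint_id kept in memory only).
.CONTACT_COLS <- c("read_id", "chrom1", "pos1", "strand1", "frag1",
                   "chrom2", "pos2", "strand2", "frag2",
                   "sonication_end", "allele", "copies", "viewpoint_id")

#' ContactTable: deduplicable ligation contacts
#'
#' An ordered collection of ligation contact records plus header metadata.
#' Each record has two sides located at the restriction cut coordinate that
#' was ligated, a strand per side, the sonication shear-break coordinate of
#' the distal side (the UMI), an optional allele tag and a positive
#' multiplicity `copies`. In 4C mode side 1 is the bait/viewpoint side and
#' `viewpoint_id` names the viewpoint; in Hi-C (anchor-free) mode records
#' satisfy `pos1 <= pos2` in genomic order for cis pairs.
#'
#' @slot records data.frame with columns read_id, chrom1, pos1, strand1,
#'   frag1, chrom2, pos2, strand2, frag2, sonication_end, allele, copies,
#'   viewpoint_id. Missing values are NA.
#' @slot metadata list; recognised entries include `mode` ("4C" or "HiC"),
#'   `source`, `enzymes`, `fragmap`, `viewpoint` (list(chrom,start,end)),
#'   `seqlengths`, `deduped` (logical) and `header` (verbatim '#' header
#'   lines for lossless file round trips).
#' @seealso [makeContactTable()], [dedupContacts()], [readPairs()]
#' @export
setClass("ContactTable", representation(
  records = "data.frame",
  metadata = "list"
))

setValidity("ContactTable", function(object) {
  msg <- character()
  rec <- object@records
  miss <- setdiff(.CONTACT_COLS, names(rec))
  if (length(miss))
    return(paste("records missing columns:", paste(miss, collapse = ", ")))
  if (nrow(rec)) {
    if (any(rec$copies < 1L, na.rm = TRUE))
      msg <- c(msg, "'copies' must be positive")
    bad <- !(rec$strand1 %in% c("+", "-")) | !(rec$strand2 %in% c("+", "-"))
    if (any(bad)) msg <- c(msg, "strands must be '+' or '-'")
    if (any(!is.na(rec$allele) & !(rec$allele %in% c("ref", "alt", "unassigned"))))
      msg <- c(msg, "allele must be ref/alt/unassigned or NA")
    sl <- object@metadata$seqlengths
    if (!is.null(sl)) {
      for (side in 1:2) {
        ch <- rec[[paste0("chrom", side)]]
        po <- rec[[paste0("pos", side)]]
        known <- ch %in% names(sl)
        if (any(known & (po < 0 | po > sl[ch])))
          msg <- c(msg, sprintf("side %d coordinates outside chromosome bounds", side))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' InteractionProfile: 100 bp-step viewpoint interaction profile
#'
#' Sliding-bin profile of distal contacts for a single 4C viewpoint (or
#' virtual 4C viewpoint). Bins advance by `step` (default 100 bp); each bin
#' collects the raw unique-contact count M from its centred `window`
#' (default 500 bp, i.e. `[start - 200, start + 300)`). `M_norm` is M per
#' 10,000 unique cis contacts. After background estimation each bin also has
#' the expected count N, the Poisson upper-tail probability p, the fold
#' enrichment FE = M/N and score = -log10 p.
#'
#' @slot viewpoint list(chrom, start, end), 0-based half-open.
#' @slot region list(chrom, start, end): the analysed interval the bins tile.
#' @slot step bin step in bp.
#' @slot window bin collection window in bp (odd multiple of step).
#' @slot bins data.frame with columns `start`, `m_step` (contacts whose
#'   distal end falls in `[start, start+step)`), `M`, `M_norm`, and after
#'   background computation `N`, `p`, `FE`, `score`.
#' @slot total total unique cis contacts used for normalisation.
#' @seealso [binProfile()], [addLocalBackground()], [callLoops()]
#' @export
setClass("InteractionProfile", representation(
  viewpoint = "list",
  region = "list",
  step = "integer",
  window = "integer",
  bins = "data.frame",
  total = "numeric"
))

setValidity("InteractionProfile", function(object) {
  msg <- character()
  if (object@step <= 0L) msg <- c(msg, "'step' must be positive")
  k <- object@window / object@step
  if (k != round(k) || (k %% 2L) != 1L)
    msg <- c(msg, "'window' must be an odd multiple of 'step'")
  b <- object@bins
  if (!all(c("start", "m_step", "M", "M_norm") %in% names(b)))
    msg <- c(msg, "bins must have columns start, m_step, M, M_norm")
  else if (nrow(b)) {
    if (any(b$M < 0)) msg <- c(msg, "M must be non-negative")
    if (nrow(b) > 1L && any(diff(b$start) != object@step))
      msg <- c(msg, "bin starts must advance by 'step'")
    if ("N" %in% names(b) && any(!is.na(b$p) & is.na(b$N)))
      msg <- c(msg, "p computed where N is missing")
  }
  if (length(msg)) msg else TRUE
})

#' ContactMatrix: sparse symmetric binned contact counts
#'
#' Upper-triangular sparse representation of a cis contact matrix for one
#' chromosome at a fixed resolution. Entry (i, j) with 0-based bin indices
#' i <= j counts contacts whose two ligated-end coordinates fall in bins i
#' and j; symmetry is implied on query.
#'
#' @slot chrom chromosome name.
#' @slot resolution bin size in bp.
#' @slot entries data.frame with integer columns `i`, `j` (i <= j, unique
#'   pairs) and `count`.
#' @slot nbins number of bins (chromosome length / resolution, rounded up).
#' @slot total total contact count (sum of entries).
#' @seealso [binMatrix()], [apa()], [insulationTrack()]
#' @export
setClass("ContactMatrix", representation(
  chrom = "character",
  resolution = "integer",
  entries = "data.frame",
  nbins = "integer",
  total = "numeric"
))

setValidity("ContactMatrix", function(object) {
  msg <- character()
  if (object@resolution <= 0L) msg <- c(msg, "'resolution' must be positive")
  e <- object@entries
  if (!all(c("i", "j", "count") %in% names(e)))
    return("entries must have columns i, j, count")
  if (nrow(e)) {
    if (any(e$i > e$j)) msg <- c(msg, "entries must satisfy i <= j")
    if (any(e$count < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(e$j >= object@nbins) || any(e$i < 0L))
      msg <- c(msg, "bin indices outside [0, nbins)")
    if (anyDuplicated(paste(e$i, e$j)))
      msg <- c(msg, "duplicate (i, j) entries")
    if (!isTRUE(all.equal(sum(e$count), object@total)))
      msg <- c(msg, "'total' does not match sum of entries")
  }
  if (length(msg)) msg else TRUE
})
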
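#' Construct a ContactTable
#'
#' Validating constructor for [ContactTable-class]. Missing optional columns
#' (read_id, frag ids, sonication_end, allele, copies, viewpoint_id) are
#' filled with defaults; `copies` defaults to 1.
#'
#' @param records data.frame with at least chrom1, pos1, strand1, chrom2,
#'   pos2, strand2.
#' @param mode "4C" (side 1 is the bait) or "HiC" (anchor-free).
#' @param metadata additional metadata entries (source, enzymes, viewpoint,
#'   seqlengths, ...).
#' @return a [ContactTable-class].
#' @export
makeContactTable <- function(records, mode = c("4C", "HiC"), metadata = list()) {
  mode <- match.arg(mode)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  n <- nrow(records)
  defaults <- list(read_id = if (n) sprintf("r%06d", seq_len(n)) else character(0),
                   frag1 = NA_integer_, frag2 = NA_integer_,
                   sonication_end = NA_integer_, allele = NA_character_,
                   copies = 1L, viewpoint_id = NA_character_)
  for (col in names(defaults))
    if (is.null(records[[col]])) records[[col]] <- rep(defaults[[col]], length.out = n)
  records <- records[, .CONTACT_COLS]
  metadata$mode <- mode
  new("ContactTable", records = records, metadata = metadata)
}

#' Assign coordinates to restriction fragments
#'
#' Returns the id of the unique fragment whose half-open interval contains
#' each coordinate (binary-search semantics: a coordinate equal to a cut
#' site belongs to the fragment starting there).
#'
#' @param chrom chromosome name(s), recycled against `pos`.
#' @param pos 0-based coordinate(s).
#' @param map a [FragmentMap-class].
#' @return integer vector of fragment ids.
#' @export
assignToFragment <- function(chrom, pos, map) {
  stopifnot(is(map, "FragmentMap"))
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  out <- rep(NA_integer_, n)
  for (ch in unique(chrom)) {
    fr <- map@fragments[[ch]]
    if (is.null(fr)) stop("chromosome absent from fragment map: ", ch)
    sel <- which(chrom == ch)
    p <- pos[sel]
    if (any(p < 0 | p >= map@seqlengths[[ch]]))
      stop("coordinate outside chromosome ", ch)
    out[sel] <- fr$id[findInterval(p, fr$start)]
  }
  out
}

## The UMI key of each record. 4C mode follows the distal-side key
## (viewpoint, distal chrom/fragment/cut/strand, sonication end); anchor-free
## mode additionally keys on side 1, which is itself a distal end there.
.umiKey <- function(rec, mode) {
  base <- paste(rec$viewpoint_id, rec$chrom2, rec$frag2, rec$pos2,
                rec$strand2, rec$sonication_end, sep = "\r")
  if (identical(mode, "HiC"))
    base <- paste(rec$chrom1, rec$pos1, rec$strand1, base, sep = "\r")
  base
}

#' Deduplicate PCR copies by sonication-end UMI
#'
#' Collapses records sharing the full UMI key: viewpoint id, distal
#' chromosome, distal fragment id, distal ligated-end coordinate, distal
#' strand and the exact sonication-end coordinate (no tolerance). The
#' surviving record's `copies` is the total multiplicity of the collapsed
#' group, so the sum of `copies` is conserved. Output records are sorted by
#' key (deterministic); within a key the earliest input record survives.
#' Records without a sonication end cannot be keyed and are passed through
#' unchanged, with a warning giving their count; they are appended after the
#' deduplicated records.
#'
#' @param table a [ContactTable-class].
#' @return a deduplicated [ContactTable-class] (`metadata$deduped = TRUE`).
#' @export
dedupContacts <- function(table) {
  stopifnot(is(table, "ContactTable"))
  rec <- table@records
  md <- table@metadata
  if (!nrow(rec)) {
    md$deduped <- TRUE
    return(new("ContactTable", records = rec, metadata = md))
  }
  nokey <- is.na(rec$sonication_end)
  passthrough <- rec[nokey, , drop = FALSE]
  if (nrow(passthrough))
    warning(nrow(passthrough),
            " record(s) without sonication_end passed through undeduplicated")
  rec <- rec[!nokey, , drop = FALSE]
  if (nrow(rec)) {
    key <- .umiKey(rec, md$mode)
    ## radix = C-locale byte order: deterministic across platforms/locales;
    ## stable: earliest record first per key
    o <- order(key, seq_along(key), method = "radix")
    k <- key[o]
    first <- !duplicated(k)
    grp <- cumsum(first)
    copies <- as.integer(rowsum(as.numeric(rec$copies[o]), grp)[, 1L])
    rec <- rec[o, , drop = FALSE][first, , drop = FALSE]
    rec$copies <- copies
  }
  out <- rbind(rec, passthrough)
  rownames(out) <- NULL
  md$deduped <- TRUE
  new("ContactTable", records = out, metadata = md)
}

#' Contact orientation profile by distance
#'
#' For anchor-free cis pairs ordered pos1 < pos2, side 1 on the minus strand
#' points away from its partner ("out") and side 2 on the plus strand points
#' away ("out"); the four orientation classes in-in, in-out, out-in, out-out
#' are tallied per log-spaced distance bin. Frequencies in each distance bin
#' sum to 1. Short-range out-out overrepresentation diagnoses self-circle
#' ligation.
#'
#' @param table a [ContactTable-class] with both strands recorded.
#' @param breaks increasing numeric distance-bin breakpoints in bp; default
#'   log-spaced from 100 bp to 10 Mb.
#' @return data.frame with bin bounds, total `n` and the four frequencies;
#'   zero rows for an empty table.
#' @export
orientationProfile <- function(table, breaks = 10^seq(2, 7, by = 0.25)) {
  stopifnot(is(table, "ContactTable"))
  rec <- table@records
  rec <- rec[rec$chrom1 == rec$chrom2 & rec$pos2 > rec$pos1, , drop = FALSE]
  empty <- data.frame(bin_lo = numeric(0), bin_hi = numeric(0), n = integer(0),
                      in_in = numeric(0), in_out = numeric(0),
                      out_in = numeric(0), out_out = numeric(0))
  if (!nrow(rec)) return(empty)
  d <- rec$pos2 - rec$pos1
  cls <- paste0(ifelse(rec$strand1 == "-", "out", "in"), "_",
                ifelse(rec$strand2 == "+", "out", "in"))
  bin <- findInterval(d, breaks, rightmost.closed = FALSE)
  keep <- bin >= 1L & bin < length(breaks)
  if (!any(keep)) return(empty)
  tab <- table(factor(bin[keep], levels = seq_len(length(breaks) - 1L)),
               factor(cls[keep], levels = c("in_in", "in_out", "out_in", "out_out")))
  n <- rowSums(tab)
  freq <- tab / ifelse(n == 0, NA, n)
  out <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1L],
                    n = as.integer(n),
                    in_in = as.numeric(freq[, "in_in"]),
                    in_out = as.numeric(freq[, "in_out"]),
                    out_in = as.numeric(freq[, "out_in"]),
                    out_out = as.numeric(freq[, "out_out"]))
  out[out$n > 0L, , drop = FALSE]
}

#' Cis/trans contact statistics
#'
#' Fraction of contacts with both sides on the same chromosome (Hi-C mode)
#' or on the viewpoint's chromosome (4C mode), with a per-viewpoint
#' breakdown when viewpoint ids are present.
#'
#' @param table a [ContactTable-class].
#' @return list with `n`, `cis_fraction` and data.frame `per_viewpoint`.
#' @export
cisTransStats <- function(table) {
  stopifnot(is(table, "ContactTable"))
  rec <- table@records
  cis <- rec$chrom1 == rec$chrom2
  per <- data.frame(viewpoint_id = character(0), n = integer(0),
                    cis_fraction = numeric(0))
  if (nrow(rec) && any(!is.na(rec$viewpoint_id))) {
    sp <- split(cis, rec$viewpoint_id)
    per <- data.frame(viewpoint_id = names(sp),
                      n = vapply(sp, length, 0L),
                      cis_fraction = vapply(sp, mean, 0),
                      row.names = NULL)
  }
  list(n = nrow(rec),
       cis_fraction = if (nrow(rec)) mean(cis) else NA_real_,
       per_viewpoint = per)
}
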
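#' @describeIn FragmentMap fragments as one BED-like data.frame
#'   (chrom, start, end, id), concatenated across chromosomes.
#' @param x a trichrom S4 object.
#' @param chrom optional chromosome name to restrict to.
#' @export
setMethod("fragments", "FragmentMap", function(x, chrom = NULL) {
  chroms <- if (is.null(chrom)) names(x@fragments) else chrom
  out <- lapply(chroms, function(ch) {
    fr <- x@fragments[[ch]]
    if (is.null(fr)) stop("unknown chromosome: ", ch)
    cbind(data.frame(chrom = rep(ch, nrow(fr)), stringsAsFactors = FALSE), fr)
  })
  do.call(rbind, out)
})

#' @describeIn FragmentMap cut sites as a data.frame (chrom, pos, enzyme).
#' @export
setMethod("cutSites", "FragmentMap", function(x, chrom = NULL) {
  chroms <- if (is.null(chrom)) names(x@cuts) else chrom
  out <- lapply(chroms, function(ch) {
    cu <- x@cuts[[ch]]
    if (is.null(cu)) stop("unknown chromosome: ", ch)
    cbind(data.frame(chrom = rep(ch, nrow(cu)), stringsAsFactors = FALSE), cu)
  })
  do.call(rbind, out)
})

#' @describeIn FragmentMap named integer vector of chromosome lengths.
#' @export
setMethod("chromLengths", "FragmentMap", function(x) x@seqlengths)

setMethod("show", "FragmentMap", function(object) {
  nfr <- sum(vapply(object@fragments, nrow, 0L))
  cat(sprintf("FragmentMap: %d chromosome(s), %d fragments, enzymes: %s\n",
              length(object@seqlengths), nfr,
              paste(object@enzymes, collapse = ",")))
  len <- unlist(lapply(object@fragments, function(f) f$end - f$start),
                use.names = FALSE)
  cat(sprintf("  mean fragment length %.1f bp (median %d)\n",
              mean(len), as.integer(stats::median(len))))
})

#' @describeIn ContactTable the records data.frame.
#' @param x a ContactTable.
#' @export
setMethod("contacts", "ContactTable", function(x) x@records)

#' @describeIn ContactTable number of records.
#' @export
setMethod("nContacts", "ContactTable", function(x) nrow(x@records))

#' @describeIn ContactTable the metadata list.
#' @export
setMethod("contactMetadata", "ContactTable", function(x) x@metadata)

setMethod("show", "ContactTable", function(object) {
  md <- object@metadata
  cat(sprintf("ContactTable: %d records, mode %s%s\n", nrow(object@records),
              if (is.null(md$mode)) "?" else md$mode,
              if (isTRUE(md$deduped)) " (deduplicated)" else ""))
  if (!is.null(md$viewpoint))
    cat(sprintf("  viewpoint %s:%d-%d\n", md$viewpoint$chrom,
                md$viewpoint$start, md$viewpoint$end))
})

#' @describeIn InteractionProfile the per-bin data.frame.
#' @param x an InteractionProfile.
#' @export
setMethod("profileBins", "InteractionProfile", function(x) x@bins)

#' @describeIn InteractionProfile the viewpoint as list(chrom, start, end).
#' @export
setMethod("viewpoint", "InteractionProfile", function(x) x@viewpoint)

#' @describeIn InteractionProfile total unique cis contacts used for
#'   normalisation.
#' @export
setMethod("profileTotal", "InteractionProfile", function(x) x@total)

setMethod("show", "InteractionProfile", function(object) {
  cat(sprintf("InteractionProfile: %s:%d-%d, %d bins (step %d, window %d)\n",
              object@region$chrom, object@region$start, object@region$end,
              nrow(object@bins), object@step, object@window))
  cat(sprintf("  viewpoint %s:%d-%d, %g unique cis contacts, background %s\n",
              object@viewpoint$chrom, object@viewpoint$start,
              object@viewpoint$end, object@total,
              if ("N" %in% names(object@bins)) "computed" else "not computed"))
})

#' @describeIn ContactMatrix sparse entries (i, j, count), i <= j.
#' @param x a ContactMatrix.
#' @export
setMethod("matrixEntries", "ContactMatrix", function(x) x@entries)

#' @describeIn ContactMatrix bin size in bp.
#' @export
setMethod("matrixResolution", "ContactMatrix", function(x) x@resolution)

#' @describeIn ContactMatrix number of bins.
#' @export
setMethod("nBins", "ContactMatrix", function(x) x@nbins)

#' @describeIn ContactMatrix total contact count.
#' @export
setMethod("matrixTotal", "ContactMatrix", function(x) x@total)

setMethod("show", "ContactMatrix", function(object) {
  cat(sprintf(
    "ContactMatrix: %s, %d bp resolution, %d bins, %d non-zero entries, %g contacts\n",
    object@chrom, object@resolution, object@nbins, nrow(object@entries),
    object@total))
})
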
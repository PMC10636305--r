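## All on-disk coordinates are 0-based half-open; writers never shift or
## merge records, so canonical files round-trip byte-identically.

.PAIRS_COLS <- c("read_id", "chrom1", "pos1", "strand1", "frag1",
                 "chrom2", "pos2", "strand2", "frag2",
                 "sonication_end", "allele", "copies")

.na2dot <- function(x) ifelse(is.na(x), ".", as.character(x))
.dot2na <- function(x) ifelse(x == ".", NA_character_, x)

#' Read a pairs-like contact TSV
#'
#' One record per line, 12 tab-separated columns: readID chrom1 pos1 strand1
#' frag1 chrom2 pos2 strand2 frag2 sonication_end allele copies, with '.'
#' for missing values and '#' header lines. Recognised header keys
#' (`#mode:`, `#viewpoint:`, `#seqlengths:`) populate the table metadata;
#' all header lines are kept verbatim for lossless round trips. Malformed
#' lines raise an error naming the line number.
#'
#' @param path input file.
#' @return a [ContactTable-class].
#' @export
readPairs <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  body_idx <- which(!is_hdr & nzchar(lines))
  header <- lines[is_hdr]
  md <- list(header = header, mode = "HiC")
  for (h in header) {
    if (startsWith(h, "#mode:"))
      md$mode <- trimws(sub("^#mode:", "", h))
    if (startsWith(h, "#viewpoint:"))
      md$viewpoint <- .parseRegion(trimws(sub("^#viewpoint:", "", h)))
    if (startsWith(h, "#seqlengths:")) {
      kv <- strsplit(trimws(sub("^#seqlengths:", "", h)), ",", fixed = TRUE)[[1]]
      parts <- strsplit(kv, "=", fixed = TRUE)
      md$seqlengths <- stats::setNames(
        as.integer(vapply(parts, `[`, "", 2L)),
        vapply(parts, `[`, "", 1L))
    }
  }
  if (!length(body_idx)) {
    rec <- makeContactTable(
      data.frame(chrom1 = character(0), pos1 = integer(0),
                 strand1 = character(0), chrom2 = character(0),
                 pos2 = integer(0), strand2 = character(0)),
      mode = if (identical(md$mode, "4C")) "4C" else "HiC")@records
    return(new("ContactTable", records = rec, metadata = md))
  }
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 12L)
  if (length(bad))
    stop("line ", body_idx[bad[1L]], ": expected 12 tab-separated columns, found ",
         nf[bad[1L]])
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  rec <- data.frame(
    read_id = m[, 1L], chrom1 = m[, 2L],
    pos1 = as.integer(m[, 3L]), strand1 = m[, 4L],
    frag1 = as.integer(.dot2na(m[, 5L])),
    chrom2 = m[, 6L], pos2 = as.integer(m[, 7L]), strand2 = m[, 8L],
    frag2 = as.integer(.dot2na(m[, 9L])),
    sonication_end = as.integer(.dot2na(m[, 10L])),
    allele = .dot2na(m[, 11L]),
    copies = as.integer(m[, 12L]),
    stringsAsFactors = FALSE)
  rec$viewpoint_id <- if (identical(md$mode, "4C")) "vp1" else NA_character_
  new("ContactTable", records = rec, metadata = md)
}

#' Write a pairs-like contact TSV
#'
#' Inverse of [readPairs()]; header lines carried in the table metadata are
#' re-emitted verbatim, otherwise a canonical header is generated from the
#' metadata.
#'
#' @param table a [ContactTable-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePairs <- function(table, path) {
  stopifnot(is(table, "ContactTable"))
  md <- table@metadata
  header <- md$header
  if (is.null(header)) {
    header <- c("## trichrom pairs-like TSV v1",
                paste0("#mode: ", if (is.null(md$mode)) "HiC" else md$mode))
    if (!is.null(md$viewpoint))
      header <- c(header, sprintf("#viewpoint: %s:%d-%d", md$viewpoint$chrom,
                                  md$viewpoint$start, md$viewpoint$end))
    if (!is.null(md$seqlengths))
      header <- c(header, paste0("#seqlengths: ",
                                 paste(names(md$seqlengths), md$seqlengths,
                                       sep = "=", collapse = ",")))
    header <- c(header, paste0("#columns: readID chrom1 pos1 strand1 frag1 ",
                               "chrom2 pos2 strand2 frag2 sonication_end ",
                               "allele copies"))
  }
  r <- table@records
  body <- if (nrow(r)) {
    paste(r$read_id, r$chrom1, r$pos1, r$strand1, .na2dot(r$frag1),
          r$chrom2, r$pos2, r$strand2, .na2dot(r$frag2),
          .na2dot(r$sonication_end), .na2dot(r$allele), r$copies,
          sep = "\t")
  } else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

.readTsvNoHeader <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) return(NULL)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- unique(lengths(fields))
  if (length(nf) != 1L) stop("ragged rows in ", path)
  matrix(unlist(fields), ncol = nf, byrow = TRUE)
}

#' Read/write BED, bedGraph and BEDPE interval files
#'
#' Standard tab-separated dialects, 0-based half-open, no 1-based shifting
#' and no silent merging of adjacent records. `readBed` accepts BED3-BED6
#' (columns beyond the first three: name, score, strand); `readBedGraph`
#' expects chrom/start/end/value; `readBedpe` expects the six BEDPE
#' coordinate columns plus optional name and score. Writers emit exactly the
#' columns present. Records with end <= start raise an error.
#'
#' @param path file path.
#' @param x data.frame to write (columns as produced by the matching
#'   reader).
#' @return readers: a data.frame; writers: `path`, invisibly.
#' @name interval-io
NULL

#' @rdname interval-io
#' @export
readBed <- function(path) {
  m <- .readTsvNoHeader(path)
  if (is.null(m))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  if (ncol(m) < 3L) stop("BED needs >= 3 columns")
  out <- data.frame(chrom = m[, 1L], start = as.integer(m[, 2L]),
                    end = as.integer(m[, 3L]), stringsAsFactors = FALSE)
  if (ncol(m) >= 4L) out$name <- m[, 4L]
  if (ncol(m) >= 5L) out$score <- as.numeric(m[, 5L])
  if (ncol(m) >= 6L) out$strand <- m[, 6L]
  if (any(out$end <= out$start)) stop("BED record with end <= start")
  out
}

#' @rdname interval-io
#' @export
writeBed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  body <- do.call(paste, c(lapply(x[cols], as.character), sep = "\t"))
  writeLines(body, path)
  invisible(path)
}

#' @rdname interval-io
#' @export
readBedGraph <- function(path) {
  m <- .readTsvNoHeader(path)
  if (is.null(m))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), value = numeric(0)))
  if (ncol(m) != 4L) stop("bedGraph needs 4 columns")
  out <- data.frame(chrom = m[, 1L], start = as.integer(m[, 2L]),
                    end = as.integer(m[, 3L]), value = as.numeric(m[, 4L]),
                    stringsAsFactors = FALSE)
  if (any(out$end <= out$start)) stop("bedGraph record with end <= start")
  out
}

#' @rdname interval-io
#' @export
writeBedGraph <- function(x, path) {
  writeLines(paste(x$chrom, x$start, x$end, as.character(x$value), sep = "\t"),
             path)
  invisible(path)
}

#' @rdname interval-io
#' @export
readBedpe <- function(path) {
  m <- .readTsvNoHeader(path)
  if (is.null(m))
    return(data.frame(chrom1 = character(0), start1 = integer(0),
                      end1 = integer(0), chrom2 = character(0),
                      start2 = integer(0), end2 = integer(0)))
  if (ncol(m) < 6L) stop("BEDPE needs >= 6 columns")
  out <- data.frame(chrom1 = m[, 1L], start1 = as.integer(m[, 2L]),
                    end1 = as.integer(m[, 3L]), chrom2 = m[, 4L],
                    start2 = as.integer(m[, 5L]), end2 = as.integer(m[, 6L]),
                    stringsAsFactors = FALSE)
  if (ncol(m) >= 7L) out$name <- m[, 7L]
  if (ncol(m) >= 8L) out$score <- as.numeric(m[, 8L])
  if (any(out$end1 <= out$start1) || any(out$end2 <= out$start2))
    stop("BEDPE record with end <= start")
  out
}

#' @rdname interval-io
#' @export
writeBedpe <- function(x, path) {
  cols <- intersect(c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                      "name", "score"), names(x))
  body <- do.call(paste, c(lapply(x[cols], as.character), sep = "\t"))
  writeLines(body, path)
  invisible(path)
}

#' Read/write a contact matrix as COO TSV
#'
#' Three tab-separated columns (bin_i, bin_j, count; i <= j, 0-based) with
#' `#` header lines carrying the chromosome, resolution and bin count.
#'
#' @param mat a [ContactMatrix-class].
#' @param path file path.
#' @return `readContactMatrix`: a [ContactMatrix-class]; the writer returns
#'   `path` invisibly.
#' @export
writeContactMatrix <- function(mat, path) {
  stopifnot(is(mat, "ContactMatrix"))
  header <- c(paste0("#chrom: ", mat@chrom),
              paste0("#resolution: ", mat@resolution),
              paste0("#nbins: ", mat@nbins))
  e <- mat@entries
  writeLines(c(header, paste(e$i, e$j, e$count, sep = "\t")), path)
  invisible(path)
}

#' @rdname writeContactMatrix
#' @export
readContactMatrix <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) {
    h <- hdr[startsWith(hdr, paste0("#", key, ":"))]
    if (!length(h)) stop("matrix file lacks #", key, " header")
    trimws(sub(paste0("^#", key, ":"), "", h[1L]))
  }
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body)) {
    fields <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(fields) != 3L)) stop("COO matrix rows need 3 columns")
    m <- matrix(as.integer(unlist(fields)), ncol = 3L, byrow = TRUE)
    entries <- data.frame(i = m[, 1L], j = m[, 2L], count = m[, 3L])
  } else {
    entries <- data.frame(i = integer(0), j = integer(0), count = integer(0))
  }
  new("ContactMatrix", chrom = get("chrom"),
      resolution = as.integer(get("resolution")), entries = entries,
      nbins = as.integer(get("nbins")), total = as.numeric(sum(entries$count)))
}

#' Write fragment map files
#'
#' Writes `<prefix>.fragments.bed` (BED4: chrom, start, end, fragment id)
#' and `<prefix>.cuts.bed` (BED4: 1 bp interval at each cut coordinate,
#' enzyme name in column 4).
#'
#' @param map a [FragmentMap-class].
#' @param prefix output path prefix.
#' @return the two paths, invisibly.
#' @export
writeFragmentMap <- function(map, prefix) {
  stopifnot(is(map, "FragmentMap"))
  fr <- fragments(map)
  f1 <- paste0(prefix, ".fragments.bed")
  writeBed(data.frame(chrom = fr$chrom, start = fr$start, end = fr$end,
                      name = fr$id), f1)
  cu <- cutSites(map)
  f2 <- paste0(prefix, ".cuts.bed")
  writeBed(data.frame(chrom = cu$chrom, start = cu$pos, end = cu$pos + 1L,
                      name = cu$enzyme), f2)
  invisible(c(f1, f2))
}

#' Write profile tracks as bedGraph
#'
#' One bedGraph per quantity: `<prefix>.Mnorm.bedGraph`,
#' `<prefix>.FE.bedGraph` and `<prefix>.score.bedGraph` (the latter two only
#' when the background has been computed). Each bin is written as its step
#' interval, unmerged.
#'
#' @param profile an [InteractionProfile-class].
#' @param prefix output path prefix.
#' @return written paths, invisibly.
#' @export
writeProfileTracks <- function(profile, prefix) {
  stopifnot(is(profile, "InteractionProfile"))
  b <- profile@bins
  ch <- profile@region$chrom
  mk <- function(v) data.frame(chrom = ch, start = b$start,
                               end = b$start + profile@step,
                               value = signif(v, 6))
  paths <- paste0(prefix, ".Mnorm.bedGraph")
  writeBedGraph(mk(b$M_norm), paths[1L])
  if ("FE" %in% names(b)) {
    p2 <- paste0(prefix, c(".FE.bedGraph", ".score.bedGraph"))
    writeBedGraph(mk(b$FE), p2[1L])
    writeBedGraph(mk(b$score), p2[2L])
    paths <- c(paths, p2)
  }
  invisible(paths)
}

#' Write loop calls
#'
#' `<prefix>.loops.bed` is BED6 (name = loop id, score = -log10 p at the
#' summit, strand '.') and `<prefix>.loops.tsv` carries the full table
#' including summit, strength and reproducibility.
#'
#' @param loops loop data.frame from [callLoops()].
#' @param prefix output path prefix.
#' @return written paths, invisibly.
#' @export
writeLoops <- function(loops, prefix) {
  f1 <- paste0(prefix, ".loops.bed")
  f2 <- paste0(prefix, ".loops.tsv")
  if (nrow(loops)) {
    writeBed(data.frame(chrom = loops$chrom, start = loops$start,
                        end = loops$end, name = sprintf("loop%d", seq_len(nrow(loops))),
                        score = signif(-log10(pmax(loops$p_min, 1e-300)), 6),
                        strand = "."), f1)
  } else writeLines(character(0), f1)
  utils::write.table(loops, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(f1, f2))
}
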
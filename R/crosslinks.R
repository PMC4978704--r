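#' @include AllClasses.R utils.R
NULL

#' Convert aligned read spans to crosslink events
#'
#' iCLIP truncation geometry: the crosslink nucleotide is the position
#' immediately 5' of the read start on the read's strand. In 0-based
#' half-open coordinates a plus-strand read [s, e) yields an event at s-1
#' and a minus-strand read [s, e) an event at e. Events falling before the
#' chromosome start are dropped and counted in the \code{"dropped"}
#' attribute.
#'
#' @param reads \code{GRanges} of aligned read spans with strand; metadata
#'   (e.g. \code{name} carrying the UMI) is propagated.
#' @return width-1 \code{GRanges} of crosslink events with attribute
#'   \code{dropped} (number of out-of-bounds events).
#' @export
readsToCrosslinks <- function(reads) {
  st <- as.character(strand(reads))
  if (any(st == "*")) stop("reads must carry strand information")
  pos <- ifelse(st == "+", start(reads) - 1L, end(reads) + 1L)
  sl <- seqlengths(reads)[as.character(seqnames(reads))]
  bad <- pos < 1L | (!is.na(sl) & pos > sl)
  if (any(bad))
    warning(sum(bad), " crosslink events outside chromosome bounds dropped")
  out <- GRanges(seqnames(reads)[!bad], IRanges(pos[!bad], pos[!bad]),
                 strand = st[!bad], seqinfo = seqinfo(reads))
  mcols(out) <- mcols(reads)[!bad, , drop = FALSE]
  attr(out, "dropped") <- sum(bad)
  out
}

#' Collapse PCR duplicates by random barcode (UMI)
#'
#' Events with identical (chrom, strand, position, UMI) are one unique
#' cDNA; their copies are PCR duplicates. The ratio raw/unique is the
#' overamplification rate.
#'
#' @param events width-1 \code{GRanges}; UMI taken from \code{umi} metadata
#'   column, or from the suffix of \code{name} ("readid:UMI").
#' @param library_id label for the resulting track.
#' @return a \code{\linkS4class{CrosslinkTrack}} of unique event counts.
#' @export
dedupUmis <- function(events, library_id = "library") {
  umi <- if ("umi" %in% colnames(mcols(events))) {
    as.character(mcols(events)$umi)
  } else if ("name" %in% colnames(mcols(events))) {
    sub("^.*:", "", as.character(mcols(events)$name))
  } else stop("events carry no UMI (need 'umi' or 'name' metadata column)")
  key <- paste(as.character(seqnames(events)), as.character(strand(events)),
               start(events), umi)
  uniq <- !duplicated(key)
  ue <- events[uniq]
  poskey <- paste(as.character(seqnames(ue)), as.character(strand(ue)),
                  start(ue))
  cnt <- table(poskey)
  first <- !duplicated(poskey)
  pe <- ue[first]
  mcols(pe) <- NULL
  mcols(pe)$count <- as.integer(cnt[poskey[first]])
  newCrosslinkTrack(library_id, pe, totalRaw = length(events))
}

#' Pool crosslink tracks (e.g. replicates) by summing positional counts
#'
#' @param tracks list of \code{\linkS4class{CrosslinkTrack}}.
#' @param library_id label for the pooled track.
#' @return a \code{\linkS4class{CrosslinkTrack}}.
#' @export
poolTracks <- function(tracks, library_id = "pooled") {
  ev <- do.call(c, unname(lapply(tracks, eventRanges)))
  key <- paste(as.character(seqnames(ev)), as.character(strand(ev)), start(ev))
  agg <- rowsum(as.numeric(mcols(ev)$count), key)
  first <- !duplicated(key)
  pe <- ev[first]
  mcols(pe) <- NULL
  mcols(pe)$count <- as.integer(agg[key[first], 1L])
  newCrosslinkTrack(library_id, pe,
                    totalRaw = sum(vapply(tracks, totalRaw, numeric(1))))
}

#' Reads-per-million of a track over intervals
#'
#' Unique events inside the interval(s), scaled per million unique library
#' events.
#'
#' @param track a \code{\linkS4class{CrosslinkTrack}}.
#' @param interval \code{GRanges}; strand-specific unless the interval
#'   strand is \code{"*"}.
#' @return numeric vector of RPM values, one per interval.
#' @export
rpm <- function(track, interval) {
  if (totalUnique(track) == 0)
    stop("RPM undefined for an empty library (total unique events = 0)")
  ev <- eventRanges(track)
  hits <- GenomicRanges::findOverlaps(interval, ev, ignore.strand = FALSE)
  sums <- rep(0, length(interval))
  if (length(hits)) {
    agg <- rowsum(as.numeric(mcols(ev)$count[S4Vectors::subjectHits(hits)]),
                  S4Vectors::queryHits(hits))
    sums[as.integer(rownames(agg))] <- agg[, 1L]
  }
  sums * 1e6 / totalUnique(track)
}

#' Count unique crosslink events per gene (HTSeq union-mode analog)
#'
#' An event inside exactly one gene's exonic union (same strand) counts for
#' that gene; events in the exonic union of two or more genes are ambiguous
#' and counted for none. Non-exonic events inside exactly one gene span are
#' tallied in a parallel intronic counter; inside several gene spans they are
#' ambiguous; outside all genes, unassigned. Conservation holds:
#' exonic + intronic + ambiguous + unassigned = total unique events.
#'
#' @param track a \code{\linkS4class{CrosslinkTrack}}.
#' @param ann a \code{\linkS4class{GenomeAnnotation}}.
#' @return list: \code{exonic} and \code{intronic} named per-gene counts,
#'   \code{ambiguous}, \code{unassigned}.
#' @export
countPerGene <- function(track, ann) {
  ev <- eventRanges(track)
  cnt <- as.numeric(mcols(ev)$count)
  g <- genes(ann)
  gids <- mcols(g)$gene_id
  tx <- transcriptTable(ann)
  ebt <- exonsByTranscript(ann)
  exonic <- stats::setNames(numeric(length(gids)), gids)
  intronic <- exonic
  exUnion <- list()
  for (gid in gids) {
    tids <- tx$transcript_id[tx$gene_id == gid]
    exUnion[[gid]] <- GenomicRanges::reduce(
      unlist(GRangesList(lapply(tids, function(t) ebt[[t]]))))
  }
  nExon <- integer(length(ev))
  whichGene <- integer(length(ev))
  for (i in seq_along(gids)) {
    hit <- IRanges::overlapsAny(ev, exUnion[[gids[i]]], ignore.strand = FALSE)
    nExon <- nExon + hit
    whichGene[hit & nExon == 1L] <- i
  }
  nSpan <- GenomicRanges::countOverlaps(ev, g, ignore.strand = FALSE)
  spanHit <- GenomicRanges::findOverlaps(ev, g, ignore.strand = FALSE)
  spanGene <- integer(length(ev))
  spanGene[S4Vectors::queryHits(spanHit)] <- S4Vectors::subjectHits(spanHit)

  ambiguous <- 0; unassigned <- 0
  for (j in seq_along(ev)) {
    if (nExon[j] == 1L) {
      exonic[whichGene[j]] <- exonic[whichGene[j]] + cnt[j]
    } else if (nExon[j] >= 2L) {
      ambiguous <- ambiguous + cnt[j]
    } else if (nSpan[j] == 1L) {
      intronic[spanGene[j]] <- intronic[spanGene[j]] + cnt[j]
    } else if (nSpan[j] >= 2L) {
      ambiguous <- ambiguous + cnt[j]
    } else {
      unassigned <- unassigned + cnt[j]
    }
  }
  list(exonic = exonic, intronic = intronic, ambiguous = ambiguous,
       unassigned = unassigned)
}

#' Write a genes x libraries count matrix as TSV
#'
#' Exports raw per-gene exonic counts for external differential tools.
#'
#' @param counts named list of \code{\link{countPerGene}} results (one per
#'   library) or a numeric matrix.
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
writeCountMatrix <- function(counts, path) {
  m <- if (is.matrix(counts)) counts else
    do.call(cbind, lapply(counts, function(x) x$exonic))
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write raw crosslink events as BED6
#'
#' BED start is the 0-based crosslink nucleotide; the name field carries
#' "readid:UMI" (or "." when absent); score is 0 for raw reads.
#'
#' @param events width-1 \code{GRanges} (e.g. from \code{simulateIclip}).
#' @param path output BED file.
#' @return \code{path}, invisibly.
#' @export
writeCrosslinkBed <- function(events, path) {
  nm <- if ("name" %in% colnames(mcols(events)))
    as.character(mcols(events)$name) else rep(".", length(events))
  df <- data.frame(as.character(seqnames(events)), bed0Start(events),
                   bed0End(events), nm, 0L, as.character(strand(events)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 crosslink file
#'
#' @param path BED6 file; the name field may carry "readid:UMI".
#' @param seqinfo optional \code{Seqinfo}.
#' @return width-1 \code{GRanges} with \code{name} metadata column; if the
#'   score column holds positive counts (pre-deduplicated input) it is kept
#'   as \code{count}.
#' @export
readCrosslinkBed <- function(path, seqinfo = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  gr <- GRanges(df[[1L]], IRanges(df[[2L]] + 1L, df[[3L]]), strand = df[[6L]])
  if (!is.null(seqinfo)) GenomeInfoDb::seqinfo(gr) <- seqinfo
  mcols(gr)$name <- as.character(df[[4L]])
  if (any(df[[5L]] > 0)) mcols(gr)$count <- df[[5L]]
  gr
}

#' Write a crosslink track as bedGraph, one file per strand
#'
#' Positions with count > 0 are emitted as single-nt intervals (0-based
#' half-open).
#'
#' @param track a \code{\linkS4class{CrosslinkTrack}}.
#' @param prefix output path prefix; files are
#'   \code{<prefix>.plus.bedgraph} and \code{<prefix>.minus.bedgraph}.
#' @return character vector of the two paths, invisibly.
#' @export
writeBedgraph <- function(track, prefix) {
  ev <- eventRanges(track)
  paths <- c(plus = paste0(prefix, ".plus.bedgraph"),
             minus = paste0(prefix, ".minus.bedgraph"))
  for (st in c("+", "-")) {
    sel <- ev[strand(ev) == st]
    df <- data.frame(as.character(seqnames(sel)), bed0Start(sel),
                     bed0End(sel), mcols(sel)$count)
    utils::write.table(df, paths[[if (st == "+") "plus" else "minus"]],
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(paths)
}

#' Read a pair of per-strand bedGraph files into a track
#'
#' @param prefix path prefix used by \code{\link{writeBedgraph}}.
#' @param library_id label for the track.
#' @param seqinfo optional \code{Seqinfo}.
#' @return a \code{\linkS4class{CrosslinkTrack}}.
#' @export
readBedgraph <- function(prefix, library_id = "library", seqinfo = NULL) {
  parts <- list()
  for (st in c("+", "-")) {
    path <- paste0(prefix, if (st == "+") ".plus.bedgraph" else ".minus.bedgraph")
    if (!file.exists(path) || !file.size(path)) next
    df <- utils::read.table(path, sep = "\t", header = FALSE)
    gr <- GRanges(df[[1L]], IRanges(df[[2L]] + 1L, df[[3L]]), strand = st)
    mcols(gr)$count <- df[[4L]]
    parts[[length(parts) + 1L]] <- gr
  }
  ev <- if (length(parts)) do.call(c, parts) else GRanges()
  if (!is.null(seqinfo)) GenomeInfoDb::seqinfo(ev) <- seqinfo
  if (!"count" %in% colnames(mcols(ev))) mcols(ev)$count <- integer(0)
  newCrosslinkTrack(library_id, ev)
}
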
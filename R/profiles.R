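#' @include AllClasses.R utils.R crosslinks.R annotation.R
NULL

#' Relative-length binned coverage matrix over exons
#'
#' Each exon is rescaled to \code{n_profile_bins} equal-width bins
#' (bin = floor(offset * n_bins / length), transcript orientation, no
#' interpolation, so counts are conserved exactly) and rows are ordered by
#' absolute exon length. Values are unique crosslink events per bin, scaled
#' to RPM of the track unless \code{scale_rpm = FALSE}.
#'
#' @param track a \code{\linkS4class{CrosslinkTrack}}.
#' @param exons exon \code{GRanges}.
#' @param params \code{\link{pipelineParams}}.
#' @param scale_rpm scale counts to events per million library events.
#' @return list: \code{matrix} (exons x bins, rows in length order),
#'   \code{exons} (the reordered \code{GRanges}), \code{order} (permutation
#'   applied to the input).
#' @export
exonMatrix <- function(track, exons, params = pipelineParams(),
                       scale_rpm = TRUE) {
  nb <- params$n_profile_bins
  o <- order(width(exons), start(exons))
  ex <- exons[o]
  M <- matrix(0, nrow = length(ex), ncol = nb)
  ev <- eventRanges(track)
  hits <- GenomicRanges::findOverlaps(ex, ev, ignore.strand = FALSE)
  if (length(hits)) {
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    pos <- start(ev)[si]
    st <- as.character(strand(ex))[qi]
    off <- ifelse(st == "-", end(ex)[qi] - pos, pos - start(ex)[qi])
    bin <- pmin(nb - 1L, floor(off * nb / width(ex)[qi])) + 1L
    cnt <- as.numeric(mcols(ev)$count[si])
    li <- qi + (bin - 1L) * nrow(M)  # column-major linear index
    agg <- rowsum(cnt, li)
    M[as.integer(rownames(agg))] <- agg[, 1L]
  }
  if (scale_rpm) M <- M * 1e6 / totalUnique(track)
  list(matrix = M, exons = ex, order = o)
}

#' Mean relative-length exon profile
#'
#' Average binned coverage across exons (RPM-scaled by default).
#'
#' @inheritParams exonMatrix
#' @return list: \code{mean} (per-bin average), \code{n} exons.
#' @export
exonMetaprofile <- function(track, exons, params = pipelineParams(),
                            scale_rpm = TRUE) {
  em <- exonMatrix(track, exons, params, scale_rpm)
  list(mean = colMeans(em$matrix), n = length(exons))
}

#' Junction-anchored metaplot
#'
#' Mean signal by signed offset from junction-bearing exon 3' ends
#' (transcript orientation; the canonical EJC window is offsets -24..-20).
#'
#' @param track a \code{\linkS4class{CrosslinkTrack}}.
#' @param ends width-1 \code{GRanges} of exon 3' ends (e.g.
#'   \code{\link{junctionExonEnds}}) or a
#'   \code{\linkS4class{GenomeAnnotation}}.
#' @param offsets integer offsets to tabulate (default -50..10).
#' @param scale_rpm scale to RPM.
#' @return named numeric vector: mean signal per offset.
#' @export
junctionMetaplot <- function(track, ends, offsets = -50:10,
                             scale_rpm = TRUE) {
  if (methods::is(ends, "GenomeAnnotation")) ends <- junctionExonEnds(ends)
  ev <- eventRanges(track)
  out <- stats::setNames(numeric(length(offsets)), offsets)
  for (i in seq_along(offsets)) {
    o <- offsets[i]
    shifted <- GenomicRanges::shift(ends,
      ifelse(as.character(strand(ends)) == "-", -o, o))
    out[i] <- sum(intervalCountsRaw(ev, shifted))
  }
  out <- out / length(ends)
  if (scale_rpm) out <- out * 1e6 / totalUnique(track)
  out
}

intervalCountsRaw <- function(ev, intervals) {
  hits <- GenomicRanges::findOverlaps(intervals, ev, ignore.strand = FALSE)
  out <- rep(0, length(intervals))
  if (length(hits)) {
    agg <- rowsum(as.numeric(mcols(ev)$count[S4Vectors::subjectHits(hits)]),
                  S4Vectors::queryHits(hits))
    out[as.integer(rownames(agg))] <- agg[, 1L]
  }
  out
}

#' Rank exons by RNA-seq minus iCLIP signal and label four categories
#'
#' Ranks exon rows by (mean normalized RNA-seq bin value - mean normalized
#' iCLIP bin value), both matrices normalized to unit overall mean, largest
#' difference first. Exons are labelled by the 2x2 of RNA-seq and iCLIP row
#' means against the medians of expressed exons (RNA-seq mean > 0):
#' category 1 = abundant with weak iCLIP, 2 = expressed with matching EJC
#' signal, 3 = not expressed and no EJC signal, 4 = weakly expressed but
#' EJC-enriched.
#'
#' @param iclipMat,rnaseqMat matrices from \code{\link{exonMatrix}} with
#'   identical row order.
#' @return data.frame (input row order) with \code{diff}, \code{rank},
#'   \code{category}, plus \code{order} attribute giving the ranked
#'   permutation.
#' @export
rankExonsByDifference <- function(iclipMat, rnaseqMat) {
  if (is.list(iclipMat)) iclipMat <- iclipMat$matrix
  if (is.list(rnaseqMat)) rnaseqMat <- rnaseqMat$matrix
  stopifnot(nrow(iclipMat) == nrow(rnaseqMat))
  normRow <- function(m) {
    mm <- mean(m)
    rowMeans(m) / if (mm > 0) mm else 1
  }
  rn <- normRow(rnaseqMat); ic <- normRow(iclipMat)
  d <- rn - ic
  ord <- order(-d)
  expressed <- rn > 0
  medR <- stats::median(rn[expressed])
  medI <- stats::median(ic[expressed])
  hiR <- rn > medR; hiI <- ic > medI
  category <- ifelse(hiR & !hiI, 1L,
              ifelse(hiR & hiI, 2L,
              ifelse(!hiR & !hiI, 3L, 4L)))
  res <- data.frame(diff = d, rank = match(seq_along(d), ord),
                    category = category)
  attr(res, "order") <- ord
  res
}

#' Per-exon log2 fold difference of iCLIP vs RNA-seq maxima
#'
#' For each exon, log2((max iCLIP bin + 0.5) / (max RNA-seq bin + 0.5)) on
#' RPM-scaled bins; per-category aggregates are medians with a bootstrap
#' confidence interval.
#'
#' @param iclipTrack,rnaseqTrack \code{\linkS4class{CrosslinkTrack}}s.
#' @param exons exon \code{GRanges}; if it carries a \code{category}
#'   metadata column, per-category aggregates are computed.
#' @param params \code{\link{pipelineParams}}.
#' @param n_boot bootstrap resamples for the CI.
#' @param seed RNG seed for the bootstrap.
#' @return list: \code{per_exon} (values in length order with the reordered
#'   exons), \code{aggregate} data.frame (category, n, median, ci_lo,
#'   ci_hi).
#' @export
log2FoldDifference <- function(iclipTrack, rnaseqTrack, exons,
                               params = pipelineParams(), n_boot = 200L,
                               seed = 1L) {
  icl <- exonMatrix(iclipTrack, exons, params)
  rna <- exonMatrix(rnaseqTrack, exons, params)
  lfc <- log2((apply(icl$matrix, 1L, max) + 0.5) /
              (apply(rna$matrix, 1L, max) + 0.5))
  cat <- if ("category" %in% colnames(mcols(icl$exons)))
    mcols(icl$exons)$category else rep("all", length(lfc))
  agg <- withSeed(seed, {
    do.call(rbind, lapply(unique(cat), function(cc) {
      v <- lfc[cat == cc]
      meds <- vapply(seq_len(n_boot), function(i)
        stats::median(sample(v, replace = TRUE)), numeric(1))
      data.frame(category = cc, n = length(v), median = stats::median(v),
                 ci_lo = unname(stats::quantile(meds, 0.025)),
                 ci_hi = unname(stats::quantile(meds, 0.975)),
                 stringsAsFactors = FALSE)
    }))
  })
  list(per_exon = data.frame(lfc = lfc, category = cat), exons = icl$exons,
       aggregate = agg)
}

#' Regional distribution and enrichment of peaks
#'
#' Assigns each peak the region label of its summit, reports the percentage
#' of peaks per region (sums to 100) and the enrichment factor
#' peaks-per-nt (peak count divided by the cumulative region length).
#'
#' @param peakGr peaks (\code{GRanges} with \code{summit} or
#'   \code{\linkS4class{PeakSet}}).
#' @param rm a \code{\linkS4class{RegionMap}}.
#' @return data.frame per region: \code{n_peaks}, \code{pct},
#'   \code{cumulative_length}, \code{enrichment}.
#' @export
regionDistribution <- function(peakGr, rm) {
  if (methods::is(peakGr, "PeakSet")) peakGr <- peaks(peakGr)
  summit1 <- mcols(peakGr)$summit + 1L
  pos <- GRanges(seqnames(peakGr), IRanges(summit1, summit1),
                 strand = strand(peakGr))
  lab <- regionOfPositions(rm, pos)
  lbls <- names(cumulativeRegionLengths(rm))
  n <- vapply(lbls, function(l) sum(lab == l), numeric(1))
  cl <- cumulativeRegionLengths(rm)[lbls]
  data.frame(region = lbls, n_peaks = n,
             pct = 100 * n / length(peakGr),
             cumulative_length = as.numeric(cl),
             enrichment = as.numeric(n / cl),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a binned exon matrix as TSV
#' @param em result of \code{\link{exonMatrix}}.
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
writeExonMatrix <- function(em, path) {
  df <- data.frame(
    exon = sprintf("%s:%d-%d(%s)", as.character(seqnames(em$exons)),
                   bed0Start(em$exons), bed0End(em$exons),
                   as.character(strand(em$exons))),
    em$matrix, check.names = FALSE)
  colnames(df) <- c("exon", sprintf("bin%d", seq_len(ncol(em$matrix))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
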
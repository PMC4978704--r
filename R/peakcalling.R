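#' @include AllClasses.R utils.R crosslinks.R
NULL

#' Default analysis parameters
#'
#' One bundle of the tunable thresholds used across peak calling, motif
#' analysis, candidate-exon discovery and the exon filters. Defaults: flank
#' 15 nt, 100 permutations, FDR < 0.05 for peak calling; 5mers counted
#' within +/-40 nt of peak midpoints and normalized over +/-100 nt; top 20
#' motifs; candidate exons need BTZ > 2 RPM and a donor motif (AGGTAAG or
#' AGGTGAG) within 25 nt; the low-abundance exon filter uses iCLIP > 1 RPM
#' with RNA-seq < 0.5 RPM; expression calls use 10 reads per exon;
#' strongly-bound genes have log2 fold change > 3 at adjusted p < 0.05;
#' highly expressed means > 40 CPM; exon profiles use 100 bins.
#'
#' @param flank flank size (nt) for positional scores and peak merging.
#' @param n_perm permutations of the within-segment null.
#' @param fdr_threshold peak significance: FDR strictly below this.
#' @param kmer_window half-width (nt) of the 5mer counting window.
#' @param kmer_norm_window half-width (nt) of the normalization region.
#' @param top_k_motifs motifs kept in ranked summaries.
#' @param candidate_btz_rpm BTZ RPM required for a candidate exon call.
#' @param candidate_motifs donor motifs accepted for candidate exons.
#' @param candidate_proximity maximum donor-motif distance (nt) downstream.
#' @param table1_rpm iCLIP RPM threshold of the low-abundance exon filter.
#' @param table1_rnaseq_rpm RNA-seq RPM ceiling of that filter.
#' @param expressed_exon_reads reads per exon to call an exon expressed.
#' @param ejc_positive_reads BTZ events per expressed exon to call it
#'   EJC-positive.
#' @param strong_binding_log2fc log2 fold change above which a gene is
#'   strongly bound.
#' @param adj_p_threshold BH-adjusted p threshold for enrichment.
#' @param top_cpm_cutoff CPM above which an exon counts as highly expressed.
#' @param n_profile_bins bins of relative-length exon profiles.
#' @param rng_seed seed for the permutation and shuffle nulls.
#' @return named list of parameters.
#' @export
pipelineParams <- function(flank = 15L, n_perm = 100L, fdr_threshold = 0.05,
                           kmer_window = 40L, kmer_norm_window = 100L,
                           top_k_motifs = 20L, candidate_btz_rpm = 2.0,
                           candidate_motifs = c("AGGTAAG", "AGGTGAG"),
                           candidate_proximity = 25L,
                           table1_rpm = 1.0, table1_rnaseq_rpm = 0.5,
                           expressed_exon_reads = 10L,
                           ejc_positive_reads = 10L,
                           strong_binding_log2fc = 3.0,
                           adj_p_threshold = 0.05,
                           top_cpm_cutoff = 40,
                           n_profile_bins = 100L,
                           rng_seed = 1L) {
  p <- list(flank = as.integer(flank), n_perm = as.integer(n_perm),
            fdr_threshold = fdr_threshold,
            kmer_window = as.integer(kmer_window),
            kmer_norm_window = as.integer(kmer_norm_window),
            top_k_motifs = as.integer(top_k_motifs),
            candidate_btz_rpm = candidate_btz_rpm,
            candidate_motifs = candidate_motifs,
            candidate_proximity = as.integer(candidate_proximity),
            table1_rpm = table1_rpm, table1_rnaseq_rpm = table1_rnaseq_rpm,
            expressed_exon_reads = as.integer(expressed_exon_reads),
            ejc_positive_reads = as.integer(ejc_positive_reads),
            strong_binding_log2fc = strong_binding_log2fc,
            adj_p_threshold = adj_p_threshold,
            top_cpm_cutoff = top_cpm_cutoff,
            n_profile_bins = as.integer(n_profile_bins),
            rng_seed = as.integer(rng_seed))
  stopifnot(p$n_perm >= 1L, p$flank >= 0L, p$fdr_threshold > 0,
            p$candidate_btz_rpm > 0, p$table1_rpm > 0)
  p
}

# Windowed flank score for positions with counts, clipped to [segStart,
# segEnd]. Positions must be sorted and unique. O(n log n).
flankScores <- function(pos, cnt, flank) {
  cs <- cumsum(cnt)
  hi <- findInterval(pos + flank, pos)
  lo <- findInterval(pos - flank - 0.5, pos) + 1L
  cs[hi] - c(0, cs)[lo]
}

#' Flank-window scores of crosslink positions in one gene segment
#'
#' Every position carrying at least one unique event receives the sum of
#' unique events at positions within +/- flank nt (window clipped to the
#' segment).
#'
#' @param track a \code{\linkS4class{CrosslinkTrack}}.
#' @param segment a single-range \code{GRanges} (gene span, stranded).
#' @param flank window half-width (nt).
#' @return data.frame with \code{pos} (1-based), \code{count}, \code{score};
#'   empty for an empty segment.
#' @export
scorePositions <- function(track, segment, flank) {
  ev <- eventRanges(track)
  ev <- ev[IRanges::overlapsAny(ev, segment, ignore.strand = FALSE)]
  if (!length(ev))
    return(data.frame(pos = integer(0), count = integer(0),
                      score = numeric(0)))
  o <- order(start(ev))
  pos <- start(ev)[o]
  cnt <- as.numeric(mcols(ev)$count[o])
  data.frame(pos = pos, count = cnt,
             score = flankScores(pos, cnt, flank))
}

# One permutation-null FDR computation for a single segment.
# Returns scored positions with FDR, given observed pos/cnt, segment length
# and start. The null re-places all n events independently and uniformly
# over segment positions, n_perm times, drawing rp <- sample.int(L, n,
# replace = TRUE) per permutation (this exact draw order is part of the
# published behaviour so independent reimplementations can reproduce it
# seed-for-seed).
segmentFdr <- function(pos, cnt, segStart, segLen, params, seed) {
  score <- flankScores(pos, cnt, params$flank)
  n <- sum(cnt)
  permScores <- withSeed(seed, {
    out <- vector("list", params$n_perm)
    for (i in seq_len(params$n_perm)) {
      rp <- sort.int(sample.int(segLen, n, replace = TRUE))
      r <- rle(rp)
      out[[i]] <- flankScores(r$values, r$lengths, params$flank)
    }
    out
  })
  allPerm <- sort.int(unlist(permScores))
  nPerm <- length(allPerm)
  uq <- sort(unique(score))
  obsGe <- length(score) - findInterval(uq - 0.5, sort.int(score))
  permGe <- nPerm - findInterval(uq - 0.5, allPerm)
  fdrByScore <- pmin(1, (permGe / params$n_perm) / obsGe)
  fdr <- fdrByScore[match(score, uq)]
  data.frame(pos = pos, count = cnt, score = score, fdr = fdr)
}

#' Permutation FDR of crosslink positions within one gene segment
#'
#' For each of \code{n_perm} permutations the segment's total unique events
#' are re-placed independently and uniformly over segment positions and
#' flank scores recomputed. The FDR of an observed score s is
#' min(1, mean permuted positions with score >= s / observed positions with
#' score >= s); each position inherits the FDR of its score. Deterministic
#' given \code{params$rng_seed} (the stream is derived from the seed and the
#' segment's coordinates).
#'
#' @param track a \code{\linkS4class{CrosslinkTrack}}.
#' @param segment single-range stranded \code{GRanges}.
#' @param params \code{\link{pipelineParams}}.
#' @return data.frame with \code{pos}, \code{count}, \code{score},
#'   \code{fdr}.
#' @export
permutationFdr <- function(track, segment, params = pipelineParams()) {
  sp <- scorePositions(track, segment, params$flank)
  if (!nrow(sp)) return(cbind(sp, fdr = numeric(0)))
  seed <- deriveSeed(params$rng_seed,
                     paste0(as.character(seqnames(segment)), ":",
                            start(segment), "-", end(segment),
                            as.character(strand(segment))))
  segmentFdr(sp$pos, sp$count, start(segment), width(segment), params, seed)
}

# Merge significant positions within <= flank nt into peaks.
clusterSegmentPeaks <- function(sig, strandChar, params) {
  if (!nrow(sig)) return(NULL)
  o <- order(sig$pos)
  sig <- sig[o, , drop = FALSE]
  brk <- c(0, cumsum(diff(sig$pos) > params$flank))
  out <- lapply(split(seq_len(nrow(sig)), brk), function(i) {
    m <- sig[i, , drop = FALSE]
    best <- which(m$count == max(m$count))
    summit <- if (strandChar == "-") max(m$pos[best]) else min(m$pos[best])
    data.frame(start = min(m$pos), end = max(m$pos), summit = summit,
               score = m$score[m$pos == summit][1L],
               fdr = min(m$fdr), count = sum(m$count))
  })
  do.call(rbind, out)
}

#' Cluster significant positions into peaks
#'
#' Significant positions on the same segment within <= flank nt of each
#' other merge into one peak. The summit is the member position with the
#' maximum unique event count (ties resolved toward the 5' end in transcript
#' orientation); the peak interval spans the member positions.
#'
#' @param sig data.frame from \code{\link{permutationFdr}} restricted to
#'   significant positions.
#' @param segment the segment the positions live on (for chrom/strand).
#' @param params \code{\link{pipelineParams}}.
#' @return \code{GRanges} of peaks with \code{summit} (0-based),
#'   \code{score}, \code{fdr}, \code{count} metadata.
#' @export
clusterPeaks <- function(sig, segment, params = pipelineParams()) {
  st <- as.character(strand(segment))
  df <- clusterSegmentPeaks(sig, st, params)
  if (is.null(df))
    return(GRanges(seqinfo = seqinfo(segment)))
  gr <- GRanges(as.character(seqnames(segment)),
                IRanges(df$start, df$end), strand = st,
                seqinfo = seqinfo(segment))
  mcols(gr)$summit <- df$summit - 1L  # 0-based report
  mcols(gr)$score <- df$score
  mcols(gr)$fdr <- df$fdr
  mcols(gr)$count <- df$count
  gr
}

#' Call peaks for one library over all gene segments
#'
#' Runs the within-segment permutation null on every gene span (intergenic
#' events are not peak-called) and clusters positions with FDR strictly
#' below the threshold into peaks.
#'
#' @param track a \code{\linkS4class{CrosslinkTrack}} (replicates pooled
#'   beforehand with \code{\link{poolTracks}} if desired).
#' @param ann a \code{\linkS4class{GenomeAnnotation}}.
#' @param params \code{\link{pipelineParams}}.
#' @param protein label stored in the result.
#' @return a \code{\linkS4class{PeakSet}}.
#' @export
callPeaks <- function(track, ann, params = pipelineParams(),
                      protein = libraryId(track)) {
  g <- genes(ann)
  ev <- eventRanges(track)
  res <- list()
  hits <- GenomicRanges::findOverlaps(ev, g, ignore.strand = FALSE)
  byGene <- split(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))
  for (gi in names(byGene)) {
    seg <- g[as.integer(gi)]
    sub <- ev[byGene[[gi]]]
    o <- order(start(sub))
    pos <- start(sub)[o]; cnt <- as.numeric(mcols(sub)$count[o])
    seed <- deriveSeed(params$rng_seed,
                       paste0(as.character(seqnames(seg)), ":", start(seg),
                              "-", end(seg), as.character(strand(seg))))
    sc <- segmentFdr(pos, cnt, start(seg), width(seg), params, seed)
    sig <- sc[sc$fdr < params$fdr_threshold, , drop = FALSE]
    pk <- clusterPeaks(sig, seg, params)
    if (length(pk)) res[[length(res) + 1L]] <- pk
  }
  pk <- if (length(res)) do.call(c, res) else GRanges(seqinfo = seqinfo(g))
  if (!length(pk)) {
    mcols(pk)$summit <- integer(0); mcols(pk)$score <- numeric(0)
    mcols(pk)$fdr <- numeric(0); mcols(pk)$count <- numeric(0)
  }
  methods::new("PeakSet", peaks = GenomicRanges::sort(pk, ignore.strand = TRUE),
               protein = protein, params = params)
}

#' Midpoint of peaks (motif anchor)
#'
#' The midpoint of a peak [start, end) in 0-based half-open coordinates is
#' floor((start + end - 1) / 2); for even-length peaks this is the left of
#' the two central positions.
#'
#' @param peakGr \code{GRanges} of peaks (or a \code{PeakSet}).
#' @return integer vector of 0-based midpoints.
#' @export
peakMidpoint <- function(peakGr) {
  if (methods::is(peakGr, "PeakSet")) peakGr <- peaks(peakGr)
  floor((start(peakGr) + end(peakGr)) / 2) - 1L
}

#' Export peaks as BED6+2
#'
#' Columns: chrom, start, end, name (protein:index), score (= events in
#' peak), strand, flank score, FDR.
#'
#' @param ps a \code{\linkS4class{PeakSet}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writePeakBed <- function(ps, path) {
  pk <- peaks(ps)
  df <- data.frame(as.character(seqnames(pk)), bed0Start(pk), bed0End(pk),
                   sprintf("%s:%d", proteinName(ps), seq_along(pk)),
                   mcols(pk)$count, as.character(strand(pk)),
                   mcols(pk)$score, signif(mcols(pk)$fdr, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
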
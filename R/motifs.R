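#' @include AllClasses.R utils.R peakcalling.R
NULL

# Fetch transcript-orientation sequence windows centered on 0-based
# midpoints: window covers transcript offsets -half..+half plus 2 nt of
# margin on both sides so every 5mer centered inside the window is intact.
# Windows truncated by contig edges are N-padded to keep offsets aligned.
fetchCenteredWindows <- function(genome, chrom, strandChar, mid0, half) {
  w <- half + 2L
  res <- character(length(mid0))
  truncated <- 0L
  for (ci in unique(chrom)) {
    chromStr <- as.character(genome[[ci]])
    L <- nchar(chromStr)
    sel <- which(chrom == ci)
    s <- mid0[sel] + 1L - w
    e <- mid0[sel] + 1L + w
    cs <- pmax(s, 1L); ce <- pmin(e, L)
    seqs <- substring(chromStr, cs, ce)
    padL <- strrep("N", pmax(0L, 1L - s))
    padR <- strrep("N", pmax(0L, e - L))
    res[sel] <- paste0(padL, seqs, padR)
    truncated <- truncated + sum(s < 1L | e > L)
  }
  minus <- strandChar == "-"
  if (any(minus)) res[minus] <- reverseComplement(res[minus])
  attr(res, "truncated") <- truncated
  res
}

# Tally 5mers of a set of windows into a kmer x offset count matrix.
# Windows have length 2*half+5; column j corresponds to center offset
# j - half - 1.
tallyKmerOffsets <- function(windows, half) {
  nOff <- 2L * half + 1L
  M <- matrix(0L, nrow = 1024L, ncol = nOff)
  for (j in seq_len(nOff)) {
    km <- substring(windows, j, j + 4L)
    idx <- kmerIndex(km)
    idx <- idx[!is.na(idx)]
    if (length(idx)) M[, j] <- M[, j] + tabulate(idx, 1024L)
  }
  M
}

#' Count 5mers around peak midpoints
#'
#' Every 5mer whose center lies within +/- \code{kmer_window} nt of a peak
#' midpoint increments its observed count; positional occurrences are
#' tallied over +/- \code{kmer_norm_window}. Sequence is fetched on the
#' transcribed strand (reverse-complemented for minus-strand peaks); windows
#' truncated at contig edges are N-padded and counted in the
#' \code{truncated} attribute.
#'
#' @param peakGr peaks (\code{GRanges} or \code{\linkS4class{PeakSet}}).
#' @param genome \code{DNAStringSet}.
#' @param params \code{\link{pipelineParams}}.
#' @return list: \code{observed} named counts per 5mer, \code{positional}
#'   1024 x (2 kmer_norm_window + 1) matrix, \code{offsets}.
#' @export
countKmers <- function(peakGr, genome, params = pipelineParams()) {
  if (methods::is(peakGr, "PeakSet")) peakGr <- peaks(peakGr)
  half <- params$kmer_norm_window
  mid0 <- peakMidpoint(peakGr)
  win <- fetchCenteredWindows(genome, as.character(seqnames(peakGr)),
                              as.character(strand(peakGr)), mid0, half)
  M <- tallyKmerOffsets(win, half)
  offsets <- seq(-half, half)
  inWin <- abs(offsets) <= params$kmer_window
  km <- allKmers()
  rownames(M) <- km
  list(observed = stats::setNames(rowSums(M[, inWin, drop = FALSE]), km),
       positional = M, offsets = as.integer(offsets),
       truncated = attr(win, "truncated"))
}

#' Shuffled null for 5mer counts
#'
#' Re-draws every peak midpoint uniformly within its gene segment
#' \code{n_perm} times and recounts 5mers in the +/- kmer_window region,
#' giving a null mean and SD per 5mer; the mean per-offset count over the
#' +/- kmer_norm_window region supplies the normalization denominator for
#' positional profiles. Deterministic given \code{seed}.
#'
#' @param peakGr peaks (\code{GRanges} or \code{\linkS4class{PeakSet}}).
#' @param ann a \code{\linkS4class{GenomeAnnotation}} (gene segments).
#' @param genome \code{DNAStringSet}.
#' @param params \code{\link{pipelineParams}}.
#' @param seed RNG seed; defaults to \code{params$rng_seed}.
#' @return list: \code{null_mean}, \code{null_sd} (per 5mer, window
#'   counts), \code{region_rate} (per 5mer mean per-offset null count over
#'   the normalization region).
#' @export
shuffleNull <- function(peakGr, ann, genome, params = pipelineParams(),
                        seed = params$rng_seed) {
  if (methods::is(peakGr, "PeakSet")) peakGr <- peaks(peakGr)
  g <- genes(ann)
  mid0 <- peakMidpoint(peakGr)
  midGr <- GRanges(seqnames(peakGr), IRanges(mid0 + 1L, mid0 + 1L),
                   strand = strand(peakGr))
  hit <- GenomicRanges::findOverlaps(midGr, g, ignore.strand = FALSE,
                                     select = "first")
  hit[is.na(hit)] <- GenomicRanges::nearest(midGr, g)[is.na(hit)]
  segStart <- start(g)[hit]; segLen <- width(g)[hit]
  half <- params$kmer_norm_window
  offsets <- seq(-half, half)
  inWin <- abs(offsets) <= params$kmer_window
  nK <- 1024L
  winCounts <- matrix(0, nrow = params$n_perm, ncol = nK)
  regCounts <- matrix(0, nrow = params$n_perm, ncol = nK)
  chrom <- as.character(seqnames(peakGr))
  strandChar <- as.character(strand(peakGr))
  withSeed(seed, {
    for (i in seq_len(params$n_perm)) {
      newMid0 <- segStart + floor(runif(length(peakGr)) * segLen) - 1L
      win <- fetchCenteredWindows(genome, chrom, strandChar, newMid0, half)
      M <- tallyKmerOffsets(win, half)
      winCounts[i, ] <- rowSums(M[, inWin, drop = FALSE])
      regCounts[i, ] <- rowSums(M)
    }
  })
  km <- allKmers()
  nm <- colMeans(winCounts)
  nsd <- if (params$n_perm > 1L) apply(winCounts, 2L, stats::sd) else
    rep(NA_real_, nK)
  list(null_mean = stats::setNames(nm, km),
       null_sd = stats::setNames(nsd, km),
       region_rate = stats::setNames(colMeans(regCounts) / length(offsets),
                                     km))
}

#' Positional 5mer enrichment around peaks
#'
#' Combines \code{\link{countKmers}} and \code{\link{shuffleNull}} into a
#' \code{\linkS4class{KmerProfileSet}}: per 5mer the observed window count,
#' shuffle null mean/SD, Z score ((obs - mean)/SD; 0 with a degenerate flag
#' when the SD is unavailable), GT/non-GT class, and the positional
#' occurrence vector normalized by the mean random per-offset score over the
#' normalization region (pseudo-count 0.5 for empty nulls).
#'
#' @param peakGr peaks (\code{GRanges} or \code{\linkS4class{PeakSet}}).
#' @param ann a \code{\linkS4class{GenomeAnnotation}}.
#' @param genome \code{DNAStringSet}.
#' @param params \code{\link{pipelineParams}}.
#' @param seed RNG seed for the shuffles.
#' @return a \code{\linkS4class{KmerProfileSet}}.
#' @export
kmerEnrichment <- function(peakGr, ann, genome, params = pipelineParams(),
                           seed = params$rng_seed) {
  obs <- countKmers(peakGr, genome, params)
  nul <- shuffleNull(peakGr, ann, genome, params, seed)
  km <- allKmers()
  degenerate <- is.na(nul$null_sd) | nul$null_sd == 0
  z <- ifelse(degenerate, 0,
              (obs$observed - nul$null_mean) / nul$null_sd)
  denom <- ifelse(nul$region_rate > 0, nul$region_rate, 0.5)
  normalized <- obs$positional / denom
  stats <- data.frame(kmer = km, observed = as.numeric(obs$observed),
                      null_mean = as.numeric(nul$null_mean),
                      null_sd = as.numeric(nul$null_sd),
                      z = as.numeric(z),
                      class = ifelse(grepl("GT", km, fixed = TRUE),
                                     "GT", "non-GT"),
                      degenerate = degenerate,
                      stringsAsFactors = FALSE)
  methods::new("KmerProfileSet", stats = stats,
               positional = obs$positional, normalized = normalized,
               offsets = obs$offsets, params = params)
}

#' Top enriched 5mers
#'
#' Ranks 5mers by Z score (descending), breaking ties by observed count and
#' then lexicographically. \code{k} larger than the number of 5mers returns
#' all.
#'
#' @param kps a \code{\linkS4class{KmerProfileSet}} (or its stats frame).
#' @param k how many motifs.
#' @return the top rows of the stats data.frame, ranked.
#' @export
topMotifs <- function(kps, k = 20L) {
  st <- if (methods::is(kps, "KmerProfileSet")) kmerStats(kps) else kps
  o <- order(-st$z, -st$observed, st$kmer)
  st[o[seq_len(min(k, nrow(st)))], , drop = FALSE]
}

#' Mean positional profile of a motif class among the top motifs
#'
#' Averages the normalized positional vectors of the top-k 5mers belonging
#' to the class ("GT" = contains the dinucleotide GT; "non-GT" otherwise).
#'
#' @param kps a \code{\linkS4class{KmerProfileSet}}.
#' @param class "GT" or "non-GT".
#' @param k top motifs considered (default from params).
#' @return numeric vector over offsets (named); zero-length with a warning
#'   when the class is absent from the top set.
#' @export
classProfiles <- function(kps, class = c("GT", "non-GT"), k = NULL) {
  class <- match.arg(class)
  if (is.null(k)) k <- kps@params$top_k_motifs %||% 20L
  top <- topMotifs(kps, k)
  sel <- top$kmer[top$class == class]
  if (!length(sel)) {
    warning("no ", class, " 5mers among the top ", k, " motifs")
    return(stats::setNames(numeric(0), character(0)))
  }
  m <- positionalMatrix(kps, normalized = TRUE)
  rownames(m) <- kmerStats(kps)$kmer
  prof <- colMeans(m[sel, , drop = FALSE])
  stats::setNames(prof, kmerOffsets(kps))
}

#' Positional frequency of an exact motif around peak midpoints
#'
#' Frequency (fraction of peaks) of exact matches of \code{motif} by the
#' offset of the motif start relative to the peak midpoint, in transcript
#' orientation.
#'
#' @param peakGr peaks (\code{GRanges} or \code{\linkS4class{PeakSet}}).
#' @param genome \code{DNAStringSet}.
#' @param motif motif string (e.g. "AGGTAAG").
#' @param range integer length-2, offset range of the motif start.
#' @return named numeric vector of match frequencies per offset.
#' @export
donorMotifProfile <- function(peakGr, genome, motif = "AGGTAAG",
                              range = c(-100L, 100L)) {
  if (methods::is(peakGr, "PeakSet")) peakGr <- peaks(peakGr)
  mid0 <- peakMidpoint(peakGr)
  len <- nchar(motif)
  # window spanning motif starts range[1]..range[2]: transcript offsets
  # range[1] .. range[2]+len-1; reuse the centered fetcher with a symmetric
  # half covering both extremes
  half <- max(abs(range[1L]), abs(range[2L] + len - 1L))
  win <- fetchCenteredWindows(genome, as.character(seqnames(peakGr)),
                              as.character(strand(peakGr)), mid0, half)
  offs <- seq(range[1L], range[2L])
  out <- numeric(length(offs))
  center <- half + 3L  # string index of transcript offset 0
  for (i in seq_along(offs)) {
    s <- center + offs[i]
    out[i] <- mean(substring(win, s, s + len - 1L) == motif)
  }
  stats::setNames(out, offs)
}

# Suffix/prefix overlap length between two kmers (largest, >= minOv).
kmerOverlap <- function(a, b, minOv) {
  for (ov in seq(nchar(a) - 1L, minOv)) {
    if (substring(a, nchar(a) - ov + 1L, nchar(a)) == substring(b, 1L, ov))
      return(ov)
  }
  0L
}

#' Assemble overlapping 5mers into a consensus string
#'
#' Greedy maximal-overlap merge with minimum overlap 4 nt for 5mers.
#' Returns the shortest superstring when the 5mers form a unique overlap
#' chain; otherwise the input is returned unchanged with attribute
#' \code{flag = TRUE}.
#'
#' @param kmers character vector of equal-length kmers.
#' @param min_overlap minimum accepted overlap (default length - 1).
#' @return consensus string, or the input (flagged) when no unique chain
#'   exists.
#' @export
assembleOverlappingKmers <- function(kmers,
                                     min_overlap = nchar(kmers[1L]) - 1L) {
  kmers <- unique(kmers)
  n <- length(kmers)
  if (n == 1L) return(kmers)
  ov <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) ov[i, j] <- kmerOverlap(kmers[i], kmers[j], min_overlap)
  }
  hasEdge <- ov >= min_overlap
  outdeg <- rowSums(hasEdge); indeg <- colSums(hasEdge)
  starts <- which(indeg == 0L)
  flagged <- function() structure(kmers, flag = TRUE)
  if (any(outdeg > 1L) || any(indeg > 1L) || length(starts) != 1L)
    return(flagged())
  chain <- starts
  while (TRUE) {
    nxt <- which(hasEdge[chain[length(chain)], ])
    if (!length(nxt)) break
    if (nxt %in% chain) return(flagged())  # cycle
    chain <- c(chain, nxt)
  }
  if (length(chain) != n) return(flagged())
  res <- kmers[chain[1L]]
  for (i in seq_len(n - 1L)) {
    o <- ov[chain[i], chain[i + 1L]]
    res <- paste0(res, substring(kmers[chain[i + 1L]], o + 1L))
  }
  res
}

#' Write 5mer enrichment statistics as TSV
#' @param kps a \code{\linkS4class{KmerProfileSet}}.
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
writeKmerStats <- function(kps, path) {
  utils::write.table(kmerStats(kps), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
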
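#' @include AllClasses.R utils.R crosslinks.R peakcalling.R
NULL

# Raw unique event counts of a track summed over intervals.
intervalCounts <- function(track, intervals) {
  ev <- eventRanges(track)
  hits <- GenomicRanges::findOverlaps(intervals, ev, ignore.strand = FALSE)
  out <- rep(0, length(intervals))
  if (length(hits)) {
    agg <- rowsum(as.numeric(mcols(ev)$count[S4Vectors::subjectHits(hits)]),
                  S4Vectors::queryHits(hits))
    out[as.integer(rownames(agg))] <- agg[, 1L]
  }
  out
}

# RPM averaged over replicate tracks (a single track is a list of one).
meanRpm <- function(tracks, intervals) {
  if (methods::is(tracks, "CrosslinkTrack")) tracks <- list(tracks)
  rowMeans(do.call(cbind, lapply(tracks, rpm, interval = intervals)))
}

#' Merge per-protein peaks into high-confidence EJC deposition sites
#'
#' Peaks from different proteins overlapping by at least 1 nt (same strand)
#' merge transitively into one site; sites supported by fewer than two
#' distinct proteins are dropped, and sites overlapping any GFP background
#' peak are removed (optionally, a count-ratio filter against a GFP track).
#' The site summit is the position with the maximum pooled unique event
#' count among supporter tracks (ties toward the transcript 5' end).
#'
#' @param peaksets named list (>= 2) of \code{\linkS4class{PeakSet}}, one
#'   per protein.
#' @param gfp GFP control: a \code{\linkS4class{PeakSet}} (default filter:
#'   remove sites overlapping any GFP peak) or a
#'   \code{\linkS4class{CrosslinkTrack}} with \code{gfp_ratio} (remove sites
#'   whose GFP events exceed that fraction of the best supporter count).
#'   \code{NULL} disables the filter.
#' @param tracks optional named list of \code{\linkS4class{CrosslinkTrack}}
#'   per protein for per-protein site counts and summits.
#' @param params \code{\link{pipelineParams}}.
#' @param gfp_ratio fraction for the count-ratio mode.
#' @param btz name of the EJC-position-defining protein.
#' @return \code{GRanges} of disjoint sites with metadata: \code{supporters}
#'   (CharacterList), \code{n_supporters}, \code{contains_btz},
#'   \code{summit} (0-based), per-protein \code{count_<protein>} and
#'   \code{gfp_count} when tracks are supplied; attribute
#'   \code{gfp_removed} counts filtered sites.
#' @export
mergeHighConfidence <- function(peaksets, gfp = NULL, tracks = NULL,
                                params = pipelineParams(), gfp_ratio = 0.5,
                                btz = "BTZ") {
  if (length(peaksets) < 2L)
    stop(">=2 proteins required for high-confidence site merging")
  if (is.null(names(peaksets)))
    names(peaksets) <- vapply(peaksets, proteinName, character(1))
  pool <- list()
  for (nm in names(peaksets)) {
    pk <- peaks(peaksets[[nm]])
    if (!length(pk)) next
    mcols(pk) <- NULL
    mcols(pk)$protein <- nm
    pool[[nm]] <- pk
  }
  pool <- unname(pool)
  if (!length(pool)) {
    empty <- peaks(peaksets[[1L]])[0]
    mcols(empty) <- NULL
    mcols(empty)$supporters <- IRanges::CharacterList()
    mcols(empty)$n_supporters <- integer(0)
    mcols(empty)$contains_btz <- logical(0)
    attr(empty, "gfp_removed") <- 0L
    return(empty)
  }
  allPk <- do.call(c, pool)
  # min.gapwidth = 0: abutting peaks do not overlap by >= 1 nt
  sites <- GenomicRanges::reduce(allPk, ignore.strand = FALSE,
                                 min.gapwidth = 0L)
  hits <- GenomicRanges::findOverlaps(sites, allPk, ignore.strand = FALSE)
  supp <- lapply(split(mcols(allPk)$protein[S4Vectors::subjectHits(hits)],
                       S4Vectors::queryHits(hits)), unique)
  suppList <- rep(list(character(0)), length(sites))
  suppList[as.integer(names(supp))] <- supp
  keep <- lengths(suppList) >= 2L
  sites <- sites[keep]; suppList <- suppList[keep]

  gfpRemoved <- 0L
  if (!is.null(gfp)) {
    if (methods::is(gfp, "PeakSet")) {
      bad <- IRanges::overlapsAny(sites, peaks(gfp), ignore.strand = FALSE)
    } else if (methods::is(gfp, "CrosslinkTrack")) {
      gfpCnt <- intervalCounts(gfp, sites)
      best <- if (!is.null(tracks)) {
        do.call(pmax, lapply(tracks, intervalCounts, intervals = sites))
      } else rep(Inf, length(sites))
      bad <- gfpCnt >= gfp_ratio * best
    } else stop("gfp must be a PeakSet, a CrosslinkTrack, or NULL")
    gfpRemoved <- sum(bad)
    sites <- sites[!bad]; suppList <- suppList[!bad]
  }

  mcols(sites)$supporters <- IRanges::CharacterList(suppList)
  mcols(sites)$n_supporters <- lengths(suppList)
  mcols(sites)$contains_btz <- vapply(suppList, function(s) btz %in% s,
                                      logical(1))
  if (!is.null(tracks)) {
    for (nm in names(tracks))
      mcols(sites)[[paste0("count_", nm)]] <- intervalCounts(tracks[[nm]],
                                                             sites)
    pooled <- poolTracks(unname(tracks))
    ev <- eventRanges(pooled)
    summit <- rep(NA_integer_, length(sites))
    h <- GenomicRanges::findOverlaps(sites, ev, ignore.strand = FALSE)
    bySite <- split(S4Vectors::subjectHits(h), S4Vectors::queryHits(h))
    for (k in names(bySite)) {
      i <- as.integer(k)
      sub <- ev[bySite[[k]]]
      cnt <- mcols(sub)$count
      best <- which(cnt == max(cnt))
      pos <- start(sub)[best]
      summit[i] <- if (as.character(strand(sites))[i] == "-")
        max(pos) else min(pos)
    }
    mcols(sites)$summit <- summit - 1L  # 0-based
  }
  if (!is.null(gfp) && methods::is(gfp, "CrosslinkTrack"))
    mcols(sites)$gfp_count <- intervalCounts(gfp, sites)
  attr(sites, "gfp_removed") <- gfpRemoved
  sites
}

#' BTZ marking statistics of high-confidence sites
#'
#' @param sites result of \code{\link{mergeHighConfidence}}.
#' @return list: \code{n_sites}, \code{n_with_btz}, \code{fraction}.
#' @export
btzMarkingStats <- function(sites) {
  if (!length(sites)) stop("no high-confidence sites")
  n <- length(sites)
  nb <- sum(mcols(sites)$contains_btz)
  list(n_sites = n, n_with_btz = nb, fraction = nb / n)
}

#' Exon profile of multi-protein sites lacking BTZ
#'
#' Merges peaks of the non-BTZ EJC proteins into co-bound sites (>= 2
#' supporters), removes sites overlapping any BTZ peak, and profiles the
#' remaining site midpoints across exons in relative-length bins. An empty
#' site set gives a flat zero profile.
#'
#' @param peaksets named list of \code{\linkS4class{PeakSet}} excluding BTZ
#'   (e.g. eIF4A3, UPF3B, RNPS1).
#' @param btzPeaks the BTZ \code{\linkS4class{PeakSet}}.
#' @param exons exon \code{GRanges} (e.g. a category subset of
#'   \code{\link{classifyExons}}).
#' @param params \code{\link{pipelineParams}}.
#' @return list: \code{profile} (mean per-bin site density),
#'   \code{n_sites}.
#' @export
nonBtzSiteProfile <- function(peaksets, btzPeaks, exons,
                              params = pipelineParams()) {
  sites <- mergeHighConfidence(peaksets, gfp = NULL, params = params)
  if (length(sites)) {
    bad <- IRanges::overlapsAny(sites, peaks(btzPeaks), ignore.strand = FALSE)
    sites <- sites[!bad]
  }
  nb <- params$n_profile_bins
  if (!length(sites))
    return(list(profile = numeric(nb), n_sites = 0L))
  mid0 <- peakMidpoint(sites)
  ev <- GRanges(seqnames(sites), IRanges(mid0 + 1L, mid0 + 1L),
                strand = strand(sites))
  mcols(ev)$count <- 1L
  tr <- newCrosslinkTrack("nonBTZ_sites", ev)
  prof <- exonMetaprofile(tr, exons, params, scale_rpm = FALSE)
  list(profile = prof$mean, n_sites = length(sites))
}

# First downstream (transcript orientation) match of any motif within
# proximity nt of the interval end. Returns list(motif, offset) or NULL.
downstreamDonorMatch <- function(gr, genome, motifs, proximity) {
  st <- as.character(strand(gr))
  chromStr <- as.character(genome[[as.character(seqnames(gr))]])
  L <- nchar(chromStr)
  len <- max(nchar(motifs))
  if (st == "+") {
    s <- end(gr) + 1L
    e <- min(L, end(gr) + proximity + len)
    if (s > L) return(NULL)
    sq <- substring(chromStr, s, e)
  } else {
    e <- start(gr) - 1L
    s <- max(1L, start(gr) - proximity - len)
    if (e < 1L) return(NULL)
    sq <- reverseComplement(substring(chromStr, s, e))
  }
  best <- NULL
  for (m in motifs) {
    hit <- regexpr(m, sq, fixed = TRUE)
    if (hit > 0L) {
      off <- as.integer(hit) - 1L  # nt downstream of the site end
      if (off <= proximity && (is.null(best) || off < best$offset))
        best <- list(motif = m, offset = off)
    }
  }
  best
}

#' Discover candidate (non-annotated) exons from EJC binding
#'
#' A BTZ peak is called a candidate exon when it (1) overlaps no annotated
#' exon, (2) has a BTZ signal above \code{candidate_btz_rpm} RPM
#' (replicates averaged) confirmed by at least one other overlapping EJC
#' protein peak, and (3) has a canonical splice donor motif (AGGTAAG or
#' AGGTGAG) starting at most \code{candidate_proximity} nt downstream
#' (3', transcript orientation) of the peak end.
#'
#' @param btzTracks \code{\linkS4class{CrosslinkTrack}} or list of replicate
#'   tracks for BTZ.
#' @param btzPeaks the BTZ \code{\linkS4class{PeakSet}}.
#' @param otherPeaksets named list of \code{\linkS4class{PeakSet}} of the
#'   other EJC proteins.
#' @param ann a \code{\linkS4class{GenomeAnnotation}}.
#' @param genome \code{DNAStringSet}.
#' @param params \code{\link{pipelineParams}}.
#' @return \code{GRanges} of candidate calls with metadata \code{btz_rpm},
#'   \code{supporter}, \code{motif}, \code{motif_offset}.
#' @export
findCandidateExons <- function(btzTracks, btzPeaks, otherPeaksets, ann,
                               genome, params = pipelineParams()) {
  pk <- peaks(btzPeaks)
  exAll <- unlist(exonsByTranscript(ann), use.names = FALSE)
  out <- GRanges(seqinfo = seqinfo(genes(ann)))
  mcols(out)$btz_rpm <- numeric(0); mcols(out)$supporter <- character(0)
  mcols(out)$motif <- character(0); mcols(out)$motif_offset <- integer(0)
  if (!length(pk)) return(out)
  unann <- !IRanges::overlapsAny(pk, exAll, ignore.strand = FALSE)
  pk <- pk[unann]
  if (!length(pk)) return(out)
  rpmv <- meanRpm(btzTracks, pk)
  pass <- rpmv > params$candidate_btz_rpm
  pk <- pk[pass]; rpmv <- rpmv[pass]
  if (!length(pk)) return(out)
  suppName <- rep(NA_character_, length(pk))
  for (nm in names(otherPeaksets)) {
    hit <- IRanges::overlapsAny(pk, peaks(otherPeaksets[[nm]]),
                                ignore.strand = FALSE)
    suppName[is.na(suppName) & hit] <- nm
  }
  pk <- pk[!is.na(suppName)]; rpmv <- rpmv[!is.na(suppName)]
  suppName <- suppName[!is.na(suppName)]
  if (!length(pk)) return(out)
  keep <- logical(length(pk)); motif <- character(length(pk))
  moff <- integer(length(pk))
  for (i in seq_along(pk)) {
    m <- downstreamDonorMatch(pk[i], genome, params$candidate_motifs,
                              params$candidate_proximity)
    if (!is.null(m)) { keep[i] <- TRUE; motif[i] <- m$motif; moff[i] <- m$offset }
  }
  res <- pk[keep]
  mcols(res) <- NULL
  mcols(res)$btz_rpm <- rpmv[keep]
  mcols(res)$supporter <- suppName[keep]
  mcols(res)$motif <- motif[keep]
  mcols(res)$motif_offset <- moff[keep]
  res
}

#' Low-abundance exon filter (iCLIP-high, RNA-seq-low)
#'
#' Counts, per exon category, exons with BTZ signal above \code{table1_rpm}
#' RPM, at least one other EJC protein above the same threshold, and
#' RNA-seq strictly below \code{table1_rnaseq_rpm} RPM.
#'
#' @param catalog exon catalog from \code{\link{classifyExons}}.
#' @param btzTracks BTZ track(s) (replicates averaged).
#' @param otherTracks named list of track(s) per other EJC protein.
#' @param rnaseqTracks RNA-seq track(s).
#' @param params \code{\link{pipelineParams}}.
#' @return data.frame per category: \code{n_pass}, \code{n_total},
#'   \code{pct} (of all annotated exons of that category).
#' @export
table1Filter <- function(catalog, btzTracks, otherTracks, rnaseqTracks,
                         params = pipelineParams()) {
  btzR <- meanRpm(btzTracks, catalog)
  otherR <- do.call(cbind, lapply(otherTracks, function(t)
    meanRpm(t, catalog)))
  rnaR <- meanRpm(rnaseqTracks, catalog)
  pass <- btzR > params$table1_rpm &
    apply(otherR > params$table1_rpm, 1L, any) &
    rnaR < params$table1_rnaseq_rpm
  cat <- mcols(catalog)$category
  cats <- c("five_prime_terminal", "constitutive", "variant", "alt_donor",
            "alt_acceptor", "alt_both", "three_prime_terminal")
  data.frame(category = cats,
             n_pass = vapply(cats, function(cc) sum(pass[cat == cc]),
                             numeric(1)),
             n_total = vapply(cats, function(cc) sum(cat == cc), numeric(1)),
             pct = vapply(cats, function(cc) {
               n <- sum(cat == cc)
               if (n == 0L) NA_real_ else 100 * sum(pass[cat == cc]) / n
             }, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Expressed and EJC-marked exon counts
#'
#' An exon is expressed when it carries at least
#' \code{expressed_exon_reads} raw RNA-seq reads, and EJC-positive when it
#' is expressed and carries at least \code{ejc_positive_reads} BTZ crosslink
#' events (both thresholds inclusive).
#'
#' @param catalog exon catalog (\code{GRanges}).
#' @param rnaseqTrack RNA-seq \code{\linkS4class{CrosslinkTrack}}.
#' @param btzTrack BTZ \code{\linkS4class{CrosslinkTrack}}.
#' @param params \code{\link{pipelineParams}}.
#' @return list: \code{n_expressed}, \code{n_ejc_positive}, and the
#'   per-exon logical vectors \code{expressed}, \code{ejc_positive}.
#' @export
expressedAndMarkedExons <- function(catalog, rnaseqTrack, btzTrack,
                                    params = pipelineParams()) {
  rna <- intervalCounts(rnaseqTrack, catalog)
  btz <- intervalCounts(btzTrack, catalog)
  expressed <- rna >= params$expressed_exon_reads
  positive <- expressed & btz >= params$ejc_positive_reads
  list(n_expressed = sum(expressed), n_ejc_positive = sum(positive),
       expressed = expressed, ejc_positive = positive)
}

#' Write high-confidence sites as BED6 plus supporter column
#' @param sites result of \code{\link{mergeHighConfidence}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSitesBed <- function(sites, path) {
  supp <- vapply(mcols(sites)$supporters, paste, character(1), collapse = ",")
  df <- data.frame(as.character(seqnames(sites)), bed0Start(sites),
                   bed0End(sites), sprintf("site:%d", seq_along(sites)),
                   mcols(sites)$n_supporters, as.character(strand(sites)),
                   supp)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
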
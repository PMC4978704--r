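#' @include AllClasses.R utils.R
NULL

REGION_LABELS <- c("orf", "five_prime_utr", "three_prime_utr",
                   "ncRNA", "intron", "intergenic")

#' Build the strand-specific position-to-region map
#'
#' Labels every strand-position of the genome with exactly one of
#' \code{five_prime_utr}, \code{orf}, \code{three_prime_utr}, \code{ncRNA},
#' \code{intron}, \code{intergenic}. Overlaps between isoforms or genes are
#' resolved with precedence orf > 5'UTR > 3'UTR > ncRNA > intron >
#' intergenic. UTRs are the CDS-flanking exon parts of coding transcripts;
#' exons of transcripts without a CDS contribute the ncRNA label; intron is
#' any position inside a gene span that no exon label claims. The map is
#' strand specific: antisense positions of a gene are intergenic unless an
#' antisense gene covers them.
#'
#' @param ann a \code{\linkS4class{GenomeAnnotation}}.
#' @return a \code{\linkS4class{RegionMap}}.
#' @export
buildRegionMap <- function(ann) {
  si <- seqinfo(genes(ann))
  G <- sum(as.numeric(seqlengths(si)))
  ebt <- exonsByTranscript(ann)
  cds <- cdsSpans(ann)
  empty <- GRanges(seqinfo = si)

  orf <- utr5 <- utr3 <- nc <- empty
  for (tid in names(ebt)) {
    ex <- ebt[[tid]]
    if (tid %in% names(cds)) {
      sp <- cds[tid]
      cs <- start(sp); ce <- end(sp)
      chrom <- as.character(seqnames(ex))[1L]
      st <- as.character(strand(ex))[1L]
      orfPart <- GenomicRanges::intersect(ex, sp, ignore.strand = FALSE)
      orf <- c(orf, orfPart)
      L <- seqlengths(si)[[chrom]]
      if (cs > 1L) {
        upstream <- GenomicRanges::intersect(
          ex, GRanges(chrom, IRanges(1L, cs - 1L), strand = st, seqinfo = si))
      } else upstream <- empty
      if (ce < L) {
        downstream <- GenomicRanges::intersect(
          ex, GRanges(chrom, IRanges(ce + 1L, L), strand = st, seqinfo = si))
      } else downstream <- empty
      if (st == "-") { tmp <- upstream; upstream <- downstream; downstream <- tmp }
      utr5 <- c(utr5, upstream)
      utr3 <- c(utr3, downstream)
    } else {
      nc <- c(nc, ex)
    }
  }
  geneSpans <- genes(ann)
  mcols(geneSpans) <- NULL

  acc <- empty
  lay <- list()
  pieces <- list(orf = orf, five_prime_utr = utr5,
                 three_prime_utr = utr3, ncRNA = nc, intron = geneSpans)
  for (nm in names(pieces)) {
    r <- GenomicRanges::reduce(pieces[[nm]], ignore.strand = FALSE)
    r <- GenomicRanges::setdiff(r, acc, ignore.strand = FALSE)
    lay[[nm]] <- r
    acc <- GenomicRanges::reduce(c(acc, r), ignore.strand = FALSE)
  }
  lens <- vapply(lay, function(g) sum(as.numeric(width(g))), numeric(1))
  lens[["intergenic"]] <- 2 * G - sum(lens)
  methods::new("RegionMap",
               regions = GRangesList(lay),
               lengths = lens[c("five_prime_utr", "orf", "three_prime_utr",
                                "ncRNA", "intron", "intergenic")],
               genomeLength = G)
}

#' Cumulative region lengths of a region map
#'
#' Returns nucleotides per region label; the values partition both strands of
#' the genome (they sum to twice the genome length). These are the
#' denominators of the peak enrichment factors (peaks per nt of region).
#'
#' @param rm a \code{\linkS4class{RegionMap}}.
#' @return named numeric vector of lengths (nt).
#' @export
cumulativeRegionLengths <- function(rm) rm@lengths

#' Look up the region label of strand-specific positions
#'
#' @param rm a \code{\linkS4class{RegionMap}}.
#' @param positions width-1 \code{GRanges} with strand.
#' @return character vector of labels, one per position.
#' @export
regionOfPositions <- function(rm, positions) {
  out <- rep("intergenic", length(positions))
  undecided <- rep(TRUE, length(positions))
  for (nm in names(rm@regions)) {
    hit <- IRanges::overlapsAny(positions, rm@regions[[nm]],
                                ignore.strand = FALSE)
    out[undecided & hit] <- nm
    undecided <- undecided & !hit
  }
  out
}

#' Classify distinct exons of protein-coding genes into seven categories
#'
#' Each distinct genomic exon of a protein-coding gene receives exactly one
#' category: \code{five_prime_terminal}, \code{constitutive}, \code{variant},
#' \code{alt_donor}, \code{alt_acceptor}, \code{alt_both}, or
#' \code{three_prime_terminal}. Terminal status in any isoform wins over the
#' internal categories, and 3' terminal wins over 5' terminal (relevant for
#' single-exon transcripts). Internal exons: identical boundaries in every
#' isoform of the gene gives constitutive; skipped by at least one isoform
#' with invariant boundaries gives variant; a donor boundary (exon 3' end in
#' transcript orientation) that varies among overlapping exon forms gives
#' alt_donor, a varying acceptor gives alt_acceptor, both give alt_both.
#'
#' @param ann a \code{\linkS4class{GenomeAnnotation}}.
#' @return \code{GRanges} of distinct exons with metadata columns
#'   \code{gene_id}, \code{category} and \code{exon_length}; the exon catalog.
#' @export
classifyExons <- function(ann) {
  g <- genes(ann)
  coding <- mcols(g)$gene_id[mcols(g)$biotype == "protein_coding"]
  tx <- transcriptTable(ann)
  ebt <- exonsByTranscript(ann)
  out <- list()
  for (gid in coding) {
    tids <- tx$transcript_id[tx$gene_id == gid]
    if (!length(tids)) next
    exl <- lapply(tids, function(t) ebt[[t]])
    st <- as.character(strand(exl[[1L]]))[1L]
    chrom <- as.character(seqnames(exl[[1L]]))[1L]

    key <- function(e) paste(start(e), end(e), sep = "-")
    rec <- list()  # distinct exon -> flags
    for (j in seq_along(exl)) {
      e <- exl[[j]]
      n <- length(e)
      # transcript orientation: first/last exon of the transcript
      firstIdx <- if (st == "+") 1L else n
      lastIdx <- if (st == "+") n else 1L
      ks <- key(e)
      for (i in seq_len(n)) {
        k <- ks[i]
        r <- rec[[k]]
        if (is.null(r)) r <- list(start = start(e)[i], end = end(e)[i],
                                  first = FALSE, last = FALSE, n_tx = 0L)
        if (n == 1L) { r$last <- TRUE } else {
          if (i == firstIdx) r$first <- TRUE
          if (i == lastIdx) r$last <- TRUE
        }
        r$n_tx <- r$n_tx + 1L
        rec[[k]] <- r
      }
    }
    starts <- vapply(rec, `[[`, numeric(1), "start")
    ends <- vapply(rec, `[[`, numeric(1), "end")
    isFirst <- vapply(rec, `[[`, logical(1), "first")
    isLast <- vapply(rec, `[[`, logical(1), "last")
    nTx <- vapply(rec, `[[`, numeric(1), "n_tx")

    cat <- rep(NA_character_, length(rec))
    cat[isLast] <- "three_prime_terminal"
    cat[isFirst & !isLast] <- "five_prime_terminal"

    internal <- which(is.na(cat))
    if (length(internal)) {
      ir <- IRanges(starts[internal], ends[internal])
      cl <- S4Vectors::subjectHits(IRanges::findOverlaps(
        ir, IRanges::reduce(ir)))
      for (grp in split(seq_along(internal), cl)) {
        idx <- internal[grp]
        if (length(idx) == 1L) {
          cat[idx] <- if (nTx[idx] == length(tids)) "constitutive" else "variant"
        } else {
          # transcript-orientation boundaries: donor = 3' end of the exon
          donors <- if (st == "+") ends[idx] else starts[idx]
          acceptors <- if (st == "+") starts[idx] else ends[idx]
          dv <- length(unique(donors)) > 1L
          av <- length(unique(acceptors)) > 1L
          cat[idx] <- if (dv && av) "alt_both"
                      else if (dv) "alt_donor"
                      else "alt_acceptor"
        }
      }
    }
    out[[gid]] <- data.frame(chrom = chrom, start = starts, end = ends,
                             strand = st, gene_id = gid, category = cat,
                             stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    res <- GRanges(seqinfo = seqinfo(g))
    mcols(res)$gene_id <- character(0)
    mcols(res)$category <- character(0)
    mcols(res)$exon_length <- integer(0)
    return(res)
  }
  df <- do.call(rbind, out)
  res <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand,
                 seqinfo = seqinfo(g))
  mcols(res)$gene_id <- df$gene_id
  mcols(res)$category <- df$category
  mcols(res)$exon_length <- width(res)
  GenomicRanges::sort(res, ignore.strand = TRUE)
}

#' Exon 3' ends that bear a downstream exon-exon junction
#'
#' Distinct genomic positions of the last nucleotide (transcript orientation)
#' of every exon followed by an intron in at least one transcript, i.e. the
#' splice-donor-bearing exon ends where canonical EJC deposition occurs
#' 20-24 nt upstream.
#'
#' @param ann a \code{\linkS4class{GenomeAnnotation}}.
#' @return width-1 \code{GRanges} with metadata column \code{gene_id}.
#' @export
junctionExonEnds <- function(ann) {
  tx <- transcriptTable(ann)
  ebt <- exonsByTranscript(ann)
  rows <- list()
  for (i in seq_len(nrow(tx))) {
    e <- ebt[[tx$transcript_id[i]]]
    n <- length(e)
    if (n < 2L) next
    st <- as.character(strand(e))[1L]
    # donor-bearing exons: all but the transcript-last one
    pos <- if (st == "+") end(e)[-n] else start(e)[-1L]
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = as.character(seqnames(e))[1L], pos = pos, strand = st,
      gene_id = tx$gene_id[i], stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    out <- GRanges(seqinfo = seqinfo(genes(ann)))
    mcols(out)$gene_id <- character(0)
    return(out)
  }
  df <- unique(do.call(rbind, rows))
  out <- GRanges(df$chrom, IRanges(df$pos, df$pos), strand = df$strand,
                 seqinfo = seqinfo(genes(ann)))
  mcols(out)$gene_id <- df$gene_id
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Test whether positions lie in the canonical window of any junction end
#'
#' TRUE for a position whose signed offset (transcript orientation) from at
#' least one junction-bearing exon 3' end falls inside \code{window}
#' (default the canonical EJC deposition window -24..-20). With alternative
#' donors an exon end may have several junction positions; the position is
#' canonical if it is canonical for any of them.
#'
#' @param positions width-1 \code{GRanges} with strand.
#' @param ann a \code{\linkS4class{GenomeAnnotation}} or precomputed
#'   \code{\link{junctionExonEnds}}.
#' @param window integer length-2 offset window (inclusive).
#' @return logical vector.
#' @export
inCanonicalWindow <- function(positions, ann, window = c(-24L, -20L)) {
  ends <- if (methods::is(ann, "GenomeAnnotation")) junctionExonEnds(ann) else ann
  if (!length(positions)) return(logical(0))
  # windows on the genome: transcript offsets window[1]..window[2] from each end
  minus <- as.character(strand(ends)) == "-"
  ws <- ifelse(minus, start(ends) - window[2L], start(ends) + window[1L])
  we <- ifelse(minus, start(ends) - window[1L], start(ends) + window[2L])
  wgr <- GRanges(seqnames(ends), IRanges(ws, we), strand = strand(ends))
  IRanges::overlapsAny(positions, wgr, ignore.strand = FALSE)
}

#' Signed offset of positions from the nearest junction-bearing exon 3' end
#'
#' Offsets are in transcript orientation: a crosslink at the canonical EJC
#' deposition window has offset in -24..-20. Position exactly at the exon 3'
#' end has offset 0.
#'
#' @param positions width-1 \code{GRanges} with strand.
#' @param ann a \code{\linkS4class{GenomeAnnotation}} (or precomputed ends
#'   from \code{junctionExonEnds}).
#' @return integer vector of signed offsets (NA when the chromosome/strand
#'   has no junction end).
#' @export
junctionOffsets <- function(positions, ann) {
  ends <- if (methods::is(ann, "GenomeAnnotation")) junctionExonEnds(ann) else ann
  out <- rep(NA_integer_, length(positions))
  if (!length(ends) || !length(positions)) return(out)
  key <- paste(as.character(seqnames(ends)), as.character(strand(ends)))
  pkey <- paste(as.character(seqnames(positions)),
                as.character(strand(positions)))
  for (k in unique(pkey)) {
    ei <- which(key == k)
    pi <- which(pkey == k)
    if (!length(ei)) next
    epos <- start(ends)[ei]
    ppos <- start(positions)[pi]
    minus <- grepl(" -$", k)
    for (j in seq_along(pi)) {
      d <- if (minus) epos - ppos[j] else ppos[j] - epos
      out[pi[j]] <- d[which.min(abs(d))]
    }
  }
  out
}
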
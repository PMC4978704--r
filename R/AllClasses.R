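#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame Rle
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges GRangesList seqnames strand start end width
#' @importFrom GenomeInfoDb seqlengths seqlevels Seqinfo seqinfo
NULL

#' Gene models for a genome
#'
#' Holds genes, transcripts and their exons (plus optional per-transcript CDS
#' spans) with 0-based half-open internal coordinates. This is the single
#' source of gene structure for region maps, exon classification and all
#' downstream counting.
#'
#' @slot genes \code{GRanges} of gene spans with metadata columns
#'   \code{gene_id} and \code{biotype}.
#' @slot transcripts \code{data.frame} with columns \code{transcript_id} and
#'   \code{gene_id}.
#' @slot exonsByTx named \code{GRangesList}, one element per transcript, exons
#'   sorted in genomic order and non-overlapping within a transcript.
#' @slot cdsByTx \code{GRanges} of CDS genomic spans, one range per coding
#'   transcript, named by transcript_id.
#'
#' @details Coordinates are stored 0-based half-open (BED convention); GTF
#' input/output converts to and from 1-based inclusive. Chromosome lengths
#' live in the \code{seqinfo} of \code{genes}.
#'
#' @export
setClass("GenomeAnnotation",
  representation(
    genes = "GRanges",
    transcripts = "data.frame",
    exonsByTx = "GRangesList",
    cdsByTx = "GRanges"
  )
)

setValidity("GenomeAnnotation", function(object) {
  msg <- character()
  gr <- object@genes
  if (!all(c("gene_id", "biotype") %in% colnames(mcols(gr))))
    msg <- c(msg, "genes must carry gene_id and biotype metadata columns")
  if (!all(c("transcript_id", "gene_id") %in% colnames(object@transcripts)))
    msg <- c(msg, "transcripts must have transcript_id and gene_id columns")
  if (!setequal(names(object@exonsByTx), object@transcripts$transcript_id))
    msg <- c(msg, "exonsByTx names must match transcript ids")
  sl <- seqlengths(gr)
  if (any(is.na(sl)))
    msg <- c(msg, "chromosome lengths must be set in seqinfo")
  for (tx in names(object@exonsByTx)) {
    ex <- object@exonsByTx[[tx]]
    if (length(ex) > 1L) {
      s <- start(ex); e <- end(ex)
      if (is.unsorted(s) || any(s[-1L] < e[-length(e)]))
        msg <- c(msg, sprintf("exons of transcript %s overlap or are unsorted", tx))
    }
    if (length(ex) && (any(start(ex) < 0L) ||
        any(end(ex) > sl[as.character(seqnames(ex))])))
      msg <- c(msg, sprintf("exons of transcript %s exceed chromosome bounds", tx))
  }
  cds <- object@cdsByTx
  if (length(cds)) {
    for (i in seq_along(cds)) {
      tx <- names(cds)[i]
      ex <- object@exonsByTx[[tx]]
      if (is.null(ex)) { msg <- c(msg, sprintf("CDS for unknown transcript %s", tx)); next }
      if (start(cds)[i] < min(start(ex)) || end(cds)[i] > max(end(ex)))
        msg <- c(msg, sprintf("CDS span of %s outside its exon union", tx))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Strand-specific region labelling of a genome
#'
#' Every (chromosome, strand, position) carries exactly one label from
#' \code{five_prime_utr, orf, three_prime_utr, ncRNA, intron, intergenic},
#' assigned with precedence orf > 5'UTR > 3'UTR > ncRNA > intron > intergenic
#' across overlapping isoforms.
#'
#' @slot regions named \code{GRangesList} of the disjoint labelled intervals
#'   (intergenic implicit).
#' @slot lengths named numeric, cumulative nt per label across both strands;
#'   sums to twice the genome length.
#' @slot genomeLength total genome length in nt (one strand).
#' @export
setClass("RegionMap",
  representation(
    regions = "GRangesList",
    lengths = "numeric",
    genomeLength = "numeric"
  )
)

setValidity("RegionMap", function(object) {
  lbls <- c("five_prime_utr", "orf", "three_prime_utr", "ncRNA",
            "intron", "intergenic")
  msg <- character()
  if (!setequal(names(object@lengths), lbls))
    msg <- c(msg, "lengths must cover the six region labels")
  tot <- sum(object@lengths)
  if (abs(tot - 2 * object@genomeLength) > 1e-6)
    msg <- c(msg, "region lengths must partition both strands of the genome")
  if (length(msg)) msg else TRUE
})

#' Per-library crosslink event track
#'
#' Strand-aware unique crosslink-event counts at single-nucleotide
#' resolution for one iCLIP library, after UMI deduplication.
#'
#' @slot library_id library identifier (e.g. "BTZ_rep1").
#' @slot events width-1 \code{GRanges}, metadata column \code{count} = unique
#'   events at that (chrom, strand, position).
#' @slot totalUnique total unique events (equals \code{sum(count)}).
#' @slot totalRaw raw (pre-deduplication) event count; the ratio
#'   totalRaw/totalUnique is the overamplification rate.
#' @export
setClass("CrosslinkTrack",
  representation(
    library_id = "character",
    events = "GRanges",
    totalUnique = "numeric",
    totalRaw = "numeric"
  )
)

setValidity("CrosslinkTrack", function(object) {
  msg <- character()
  ev <- object@events
  if (length(ev) && !all(width(ev) == 1L))
    msg <- c(msg, "events must be width-1 positions")
  if (!"count" %in% colnames(mcols(ev)))
    msg <- c(msg, "events must carry a count metadata column")
  else {
    if (length(ev) && any(mcols(ev)$count <= 0))
      msg <- c(msg, "counts must be positive")
    if (abs(object@totalUnique - sum(mcols(ev)$count)) > 1e-9)
      msg <- c(msg, "totalUnique must equal the sum of counts")
  }
  if (object@totalRaw < object@totalUnique)
    msg <- c(msg, "totalRaw must be >= totalUnique")
  if (length(msg)) msg else TRUE
})

#' Significant crosslink clusters for one protein
#'
#' Peaks from permutation peak calling: intervals of significant positions
#' with their summit, flank-window score and permutation FDR.
#'
#' @slot peaks \code{GRanges} with metadata columns \code{summit} (0-based
#'   position), \code{score} (flank-window event score at the summit),
#'   \code{fdr}, and \code{count} (unique events inside the peak).
#' @slot protein protein/library label the peaks belong to.
#' @slot params the \code{pipelineParams} list used for calling.
#' @export
setClass("PeakSet",
  representation(
    peaks = "GRanges",
    protein = "character",
    params = "list"
  )
)

setValidity("PeakSet", function(object) {
  msg <- character()
  pk <- object@peaks
  need <- c("summit", "score", "fdr", "count")
  if (!all(need %in% colnames(mcols(pk))))
    msg <- c(msg, "peaks must carry summit, score, fdr and count columns")
  else if (length(pk)) {
    if (any(mcols(pk)$summit < start(pk) - 1L) ||
        any(mcols(pk)$summit > end(pk) - 1L))
      msg <- c(msg, "summit must lie inside [start, end)")
    if (any(mcols(pk)$fdr < 0 | mcols(pk)$fdr > 1))
      msg <- c(msg, "fdr must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Positional 5mer enrichment profiles
#'
#' Observed and shuffled-null counts, Z scores and normalized positional
#' occurrence vectors for all 1,024 5mers around peak midpoints.
#'
#' @slot stats \code{data.frame} with one row per 5mer: \code{kmer},
#'   \code{observed} (count in the +/- kmer_window region), \code{null_mean},
#'   \code{null_sd}, \code{z}, \code{class} ("GT" if the 5mer contains the
#'   dinucleotide GT, else "non-GT"), \code{degenerate} flag (TRUE when the
#'   null SD is unavailable and z is reported as 0).
#' @slot positional integer matrix 5mer x offset: occurrences of the 5mer
#'   centered at each offset in -kmer_norm_window..+kmer_norm_window.
#' @slot normalized numeric matrix, \code{positional} divided per 5mer by the
#'   mean random score over the +/- kmer_norm_window region.
#' @slot offsets the offset axis of the positional matrices.
#' @slot params calling parameters.
#' @export
setClass("KmerProfileSet",
  representation(
    stats = "data.frame",
    positional = "matrix",
    normalized = "matrix",
    offsets = "integer",
    params = "list"
  )
)

setValidity("KmerProfileSet", function(object) {
  msg <- character()
  if (nrow(object@stats) != nrow(object@positional))
    msg <- c(msg, "stats and positional matrix must agree in 5mer rows")
  if (ncol(object@positional) != length(object@offsets))
    msg <- c(msg, "positional columns must match the offset axis")
  if (any(object@positional < 0))
    msg <- c(msg, "positional counts must be nonnegative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GenomeAnnotation", function(object) {
  cat("GenomeAnnotation:", length(object@genes), "genes,",
      nrow(object@transcripts), "transcripts,",
      sum(lengths(object@exonsByTx)), "exon records\n")
  cat("  genome:", paste0(seqlevels(object@genes), collapse = ", "),
      "(", sum(seqlengths(object@genes)), "nt )\n")
})

setMethod("show", "RegionMap", function(object) {
  cat("RegionMap over", object@genomeLength, "nt genome (per strand)\n")
  print(round(object@lengths))
})

setMethod("show", "CrosslinkTrack", function(object) {
  cat("CrosslinkTrack", object@library_id, ":",
      length(object@events), "positions,",
      object@totalUnique, "unique /", object@totalRaw, "raw events",
      sprintf("(overamplification %.2f)\n",
              object@totalRaw / max(object@totalUnique, 1)))
})

setMethod("show", "PeakSet", function(object) {
  cat("PeakSet", object@protein, ":", length(object@peaks), "peaks\n")
})

setMethod("show", "KmerProfileSet", function(object) {
  n_gt <- sum(object@stats$class == "GT")
  cat("KmerProfileSet:", nrow(object@stats), "5mers (", n_gt, "GT-class ),",
      "offsets", min(object@offsets), "..", max(object@offsets), "\n")
})
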
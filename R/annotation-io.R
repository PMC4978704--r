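#' @include AllClasses.R utils.R
NULL

#' Read an Ensembl-dialect GTF into a GenomeAnnotation
#'
#' Parses gene/transcript/exon (and optional CDS) features and groups
#' transcripts under genes. GTF coordinates are 1-based inclusive; they are
#' held internally as standard \code{GRanges} and reported 0-based half-open
#' only at BED-convention boundaries.
#'
#' @param path GTF file.
#' @param chromLengths named integer vector of chromosome lengths, or a
#'   two-column TSV path (chrom, length). When missing, lengths default to
#'   the maximum annotated end per chromosome.
#' @return a \code{\linkS4class{GenomeAnnotation}}.
#' @export
readGTF <- function(path, chromLengths = NULL) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9L))
    stop("malformed GTF record at line ", body[which(nf != 9L)[1L]],
         ": expected 9 tab-separated fields, found ", nf[nf != 9L][1L])
  gr <- rtracklayer::import(path, format = "gtf")
  if (is.character(chromLengths) && length(chromLengths) == 1L)
    chromLengths <- readChromSizes(chromLengths)
  if (is.null(chromLengths)) {
    chromLengths <- vapply(split(end(gr), as.character(seqnames(gr))),
                           max, numeric(1))
  }
  buildGenomeAnnotation(gr, chromLengths)
}

#' Read a two-column chromosome sizes TSV
#'
#' @param path TSV with columns chrom and length (no header).
#' @return named integer vector.
#' @export
readChromSizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "integer"))
  stats::setNames(df$length, df$chrom)
}

# Assemble a GenomeAnnotation from an imported GTF GRanges.
buildGenomeAnnotation <- function(gr, chromLengths) {
  si <- GenomeInfoDb::Seqinfo(names(chromLengths),
                              seqlengths = as.integer(chromLengths))
  md <- mcols(gr)
  typ <- as.character(md$type)
  biotype <- if ("gene_biotype" %in% colnames(md)) {
    as.character(md$gene_biotype)
  } else rep("protein_coding", length(gr))

  ex <- gr[typ == "exon"]
  if (any(end(ex) > chromLengths[as.character(seqnames(ex))]) ||
      any(start(ex) < 1L))
    stop("exon outside chromosome bounds in GTF input")

  exTx <- as.character(mcols(ex)$transcript_id)
  exGene <- as.character(mcols(ex)$gene_id)
  o <- order(exTx, start(ex))
  ex <- ex[o]; exTx <- exTx[o]; exGene <- exGene[o]
  mcols(ex) <- NULL
  GenomeInfoDb::seqlevels(ex) <- names(chromLengths)
  GenomeInfoDb::seqinfo(ex) <- si
  exonsByTx <- GenomicRanges::split(ex, exTx)

  txTab <- unique(data.frame(transcript_id = exTx, gene_id = exGene,
                             stringsAsFactors = FALSE))

  cdsGr <- gr[typ == "CDS"]
  if (length(cdsGr)) {
    cdsTx <- as.character(mcols(cdsGr)$transcript_id)
    spans <- vapply(split(seq_along(cdsGr), cdsTx), function(i) {
      c(min(start(cdsGr)[i]), max(end(cdsGr)[i]))
    }, numeric(2))
    onetx <- vapply(split(as.character(seqnames(cdsGr)), cdsTx),
                    function(x) x[1L], character(1))
    onest <- vapply(split(as.character(strand(cdsGr)), cdsTx),
                    function(x) x[1L], character(1))
    cdsByTx <- GRanges(onetx, IRanges(spans[1L, ], spans[2L, ]),
                       strand = onest, seqinfo = si)
    names(cdsByTx) <- colnames(spans)
  } else {
    cdsByTx <- GRanges(seqinfo = si)
  }

  geneRows <- gr[typ == "gene"]
  if (length(geneRows)) {
    geneGr <- geneRows
    gid <- as.character(mcols(geneGr)$gene_id)
    gbt <- biotype[typ == "gene"]
    mcols(geneGr) <- NULL
  } else {
    # derive gene spans from exons
    sp <- split(seq_along(ex), exGene)
    gid <- names(sp)
    geneGr <- GRanges(
      vapply(sp, function(i) as.character(seqnames(ex))[i[1L]], character(1)),
      IRanges(vapply(sp, function(i) min(start(ex)[i]), numeric(1)),
              vapply(sp, function(i) max(end(ex)[i]), numeric(1))),
      strand = vapply(sp, function(i) as.character(strand(ex))[i[1L]],
                      character(1)))
    gbt <- rep("protein_coding", length(gid))
  }
  mcols(geneGr)$gene_id <- gid
  mcols(geneGr)$biotype <- gbt
  GenomeInfoDb::seqlevels(geneGr) <- names(chromLengths)
  GenomeInfoDb::seqinfo(geneGr) <- si

  methods::new("GenomeAnnotation",
               genes = geneGr,
               transcripts = txTab,
               exonsByTx = exonsByTx,
               cdsByTx = cdsByTx)
}

#' Write a GenomeAnnotation as GTF
#'
#' Emits gene, transcript, exon and CDS features with Ensembl-style
#' \code{gene_id}/\code{transcript_id} attributes. \code{readGTF} of the
#' output reproduces all intervals.
#'
#' @param ann a \code{\linkS4class{GenomeAnnotation}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeGTF <- function(ann, path) {
  rows <- list()
  g <- genes(ann)
  rows[[1]] <- data.frame(
    chrom = as.character(seqnames(g)), src = "ejclip", type = "gene",
    start = start(g), end = end(g), score = ".",
    strand = as.character(strand(g)), frame = ".",
    attr = sprintf('gene_id "%s"; gene_biotype "%s";',
                   mcols(g)$gene_id, mcols(g)$biotype),
    stringsAsFactors = FALSE)
  tx <- transcriptTable(ann)
  ebt <- exonsByTranscript(ann)
  cds <- cdsSpans(ann)
  gb <- stats::setNames(mcols(g)$biotype, mcols(g)$gene_id)
  out <- list(rows[[1]])
  for (i in seq_len(nrow(tx))) {
    tid <- tx$transcript_id[i]; gid <- tx$gene_id[i]
    ex <- ebt[[tid]]
    at <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                  gid, tid, gb[[gid]])
    out[[length(out) + 1L]] <- data.frame(
      chrom = as.character(seqnames(ex))[1L], src = "ejclip",
      type = "transcript", start = min(start(ex)), end = max(end(ex)),
      score = ".", strand = as.character(strand(ex))[1L], frame = ".",
      attr = at, stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      chrom = as.character(seqnames(ex)), src = "ejclip", type = "exon",
      start = start(ex), end = end(ex), score = ".",
      strand = as.character(strand(ex)), frame = ".",
      attr = at, stringsAsFactors = FALSE)
    if (tid %in% names(cds)) {
      cc <- cds[tid]
      out[[length(out) + 1L]] <- data.frame(
        chrom = as.character(seqnames(cc)), src = "ejclip", type = "CDS",
        start = start(cc), end = end(cc), score = ".",
        strand = as.character(strand(cc)), frame = "0",
        attr = at, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write chromosome sizes of an annotation as a two-column TSV
#' @param ann a \code{\linkS4class{GenomeAnnotation}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeChromSizes <- function(ann, path) {
  sl <- seqlengths(genes(ann))
  utils::write.table(data.frame(names(sl), unname(sl)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
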
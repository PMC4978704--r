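suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
  library(Biostrings)
})

# Build a GenomeAnnotation by hand. `txs` is a list of lists with fields
# gene, exons (matrix/list of 1-based [start, end]), strand, and optional
# cds = c(start, end); biotypes named by gene.
makeAnnotation <- function(txs, chromLen = 1000L, chrom = "chr1",
                           biotypes = NULL) {
  si <- GenomeInfoDb::Seqinfo(chrom, seqlengths = chromLen)
  exl <- list(); txTab <- list(); cdsList <- list()
  geneInfo <- list()
  for (nm in names(txs)) {
    t <- txs[[nm]]
    ex <- do.call(rbind, t$exons)
    gr <- GRanges(chrom, IRanges(ex[, 1L], ex[, 2L]), strand = t$strand,
                  seqinfo = si)
    exl[[nm]] <- sort(gr)
    txTab[[nm]] <- data.frame(transcript_id = nm, gene_id = t$gene,
                              stringsAsFactors = FALSE)
    if (!is.null(t$cds))
      cdsList[[nm]] <- GRanges(chrom, IRanges(t$cds[1L], t$cds[2L]),
                               strand = t$strand, seqinfo = si)
    g <- geneInfo[[t$gene]]
    rng <- c(min(ex[, 1L], g$start %||% Inf), max(ex[, 2L], g$end %||% -Inf))
    geneInfo[[t$gene]] <- list(start = rng[1L], end = rng[2L],
                               strand = t$strand)
  }
  gids <- names(geneInfo)
  geneGr <- GRanges(chrom,
                    IRanges(vapply(geneInfo, `[[`, numeric(1), "start"),
                            vapply(geneInfo, `[[`, numeric(1), "end")),
                    strand = vapply(geneInfo, `[[`, character(1), "strand"),
                    seqinfo = si)
  mcols(geneGr)$gene_id <- gids
  mcols(geneGr)$biotype <- if (is.null(biotypes))
    rep("protein_coding", length(gids)) else unname(biotypes[gids])
  cds <- if (length(cdsList)) {
    out <- do.call(c, unname(cdsList)); names(out) <- names(cdsList); out
  } else GRanges(seqinfo = si)
  new("GenomeAnnotation", genes = geneGr,
      transcripts = do.call(rbind, unname(txTab)),
      exonsByTx = GRangesList(exl), cdsByTx = cds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Track from a data.frame of (pos [1-based], count, strand).
makeTrack <- function(df, chrom = "chr1", chromLen = 1000L,
                      library_id = "lib", totalRaw = NULL) {
  si <- GenomeInfoDb::Seqinfo(chrom, seqlengths = chromLen)
  ev <- GRanges(rep(chrom, nrow(df)), IRanges(df$pos, df$pos),
                strand = df$strand %||% rep("+", nrow(df)), seqinfo = si)
  mcols(ev)$count <- df$count
  newCrosslinkTrack(library_id, ev, totalRaw = totalRaw)
}

# Events with UMIs for dedup tests.
makeUmiEvents <- function(pos, umis, strand = "+", chrom = "chr1",
                          chromLen = 1000L) {
  si <- GenomeInfoDb::Seqinfo(chrom, seqlengths = chromLen)
  ev <- GRanges(chrom, IRanges(pos, pos), strand = strand, seqinfo = si)
  mcols(ev)$umi <- umis
  ev
}

# One shared small simulation per test run (memoized; ~2 s to build).
.fixtureCache <- new.env(parent = emptyenv())

smallSim <- function() {
  if (is.null(.fixtureCache$sim)) {
    cfg <- simulationConfig(seed = 101, n_genes = 20L)
    .fixtureCache$cfg <- cfg
    .fixtureCache$sim <- generateGenomeAnnotation(cfg)
  }
  list(cfg = .fixtureCache$cfg, sim = .fixtureCache$sim)
}

smallBtzTrack <- function() {
  if (is.null(.fixtureCache$btz)) {
    s <- smallSim()
    .fixtureCache$btz <- dedupUmis(simulateIclip(s$cfg, s$sim, "BTZ"),
                                   "BTZ")
  }
  .fixtureCache$btz
}

smallBtzPeaks <- function() {
  if (is.null(.fixtureCache$btzPeaks)) {
    s <- smallSim()
    .fixtureCache$btzPeaks <- callPeaks(smallBtzTrack(), s$sim$annotation,
                                        pipelineParams(rng_seed = 101),
                                        protein = "BTZ")
  }
  .fixtureCache$btzPeaks
}

# Full-EJC fixture: tracks and peak sets for all four EJC proteins on the
# shared small simulation (memoized).
ejcFixture <- function() {
  if (is.null(.fixtureCache$ejc)) {
    s <- smallSim()
    params <- pipelineParams(rng_seed = 101L)
    prots <- c("BTZ", "eIF4A3", "UPF3B", "RNPS1")
    tracks <- list(BTZ = smallBtzTrack())
    ps <- list(BTZ = smallBtzPeaks())
    for (p in prots[-1L]) {
      tracks[[p]] <- dedupUmis(simulateIclip(s$cfg, s$sim, p), p)
      ps[[p]] <- callPeaks(tracks[[p]], s$sim$annotation, params,
                           protein = p)
    }
    gfpPs <- callPeaks(dedupUmis(simulateIclip(s$cfg, s$sim, "GFP"), "GFP"),
                       s$sim$annotation, params, protein = "GFP")
    .fixtureCache$ejc <- list(tracks = tracks, peaksets = ps,
                              gfpPeaks = gfpPs, params = params)
  }
  .fixtureCache$ejc
}

# Width-1 GRanges of 0-based summit positions of sites/peaks.
summitPositions <- function(gr) {
  GRanges(seqnames(gr), IRanges(mcols(gr)$summit + 1L, mcols(gr)$summit + 1L),
          strand = strand(gr), seqinfo = seqinfo(gr))
}
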
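#' @include AllClasses.R utils.R annotation.R
NULL

#' Configuration for the synthetic transcriptome and iCLIP simulator
#'
#' Returns a validated configuration list describing the simulated genome
#' (gene/isoform plans, exon and intron lengths, planted splice-donor
#' consensus), the per-protein crosslink deposition models, PCR duplication
#' with random barcodes (UMIs), RNA-seq depth, and the EJC-depleted TOP-like
#' gene class. All randomness downstream is derived from \code{seed}; one RNG
#' stream per library is derived from (seed, library label) so adding a
#' library never perturbs the others.
#'
#' @param seed integer master seed.
#' @param n_genes number of genes to simulate.
#' @param exon_length_range,intron_length_range ranges (nt) for internal
#'   exon and intron lengths.
#' @param alt_shift_range range (nt) of the boundary shift of alternative
#'   donor/acceptor exon forms (minimum 8 so shifted donor consensus copies
#'   never collide).
#' @param gene_plan named counts of internal exon categories realized in each
#'   multi-isoform coding gene.
#' @param fraction_multi_isoform fraction of coding genes carrying a second
#'   isoform (the others realize constitutive internals only).
#' @param n_ncRNA,n_intronless counts of non-coding and intronless genes.
#' @param donor_consensus string planted across every exon-intron junction:
#'   last 2 exon nt + first 5 intron nt.
#' @param binding_site_motif optional 5mer planted over the canonical
#'   deposition window (offsets -24..-20) of every junction-bearing exon
#'   end, emulating the weak sequence preference observed at EJC binding
#'   sites; \code{NULL} disables it.
#' @param junction_occupancy fraction of junction-bearing exon 3' ends that
#'   actually receive EJC deposition (drawn once per genome and recorded in
#'   the truth).
#' @param abundance_meanlog,abundance_sdlog log-normal gene abundance.
#' @param isoform_split relative abundance of isoform 1 vs isoform 2.
#' @param top_fraction fraction of coding genes flagged TOP-like (ribosomal
#'   protein mRNA-like), with EJC deposition scaled by \code{top_multiplier}.
#' @param top_multiplier EJC deposition multiplier (<1) for TOP-like genes.
#' @param proteins named list of deposition models; each element is a list
#'   with \code{type} in \code{"EJC","PTB","GFP"} and, for EJC-like,
#'   \code{offsets}/\code{weights} (discrete crosslink offset from the exon
#'   3' end, default -24..-20) and \code{non_ejc_fraction} of signal placed
#'   at protein-specific non-EJC sites.
#' @param signal_to_noise ratio of deposition-model events to uniform
#'   background events in EJC- and PTB-like libraries.
#' @param n_reads unique crosslink events per simulated library.
#' @param duplication_rate geometric PCR duplication probability; expected
#'   raw/unique ratio is 1/(1-rate).
#' @param umi_length random-barcode length (nt).
#' @param rnaseq_depth expected RNA-seq read starts per exonic nt for a gene
#'   of mean abundance.
#' @param n_non_ejc_sites number of protein-specific non-EJC sites used when
#'   \code{non_ejc_fraction} > 0.
#' @return a \code{SimulationConfig} list.
#' @export
simulationConfig <- function(seed = 1L,
                             n_genes = 50L,
                             exon_length_range = c(90L, 240L),
                             intron_length_range = c(250L, 700L),
                             alt_shift_range = c(12L, 36L),
                             gene_plan = c(constitutive = 2L, variant = 1L,
                                           alt_donor = 1L, alt_acceptor = 1L,
                                           alt_both = 1L),
                             fraction_multi_isoform = 0.6,
                             n_ncRNA = max(1L, round(0.06 * n_genes)),
                             n_intronless = max(1L, round(0.04 * n_genes)),
                             donor_consensus = "AGGTAAG",
                             binding_site_motif = "GAAGA",
                             junction_occupancy = 1,
                             abundance_meanlog = log(10), abundance_sdlog = 0.8,
                             isoform_split = c(2, 1) / 3,
                             top_fraction = 0.1, top_multiplier = 0.1,
                             proteins = NULL,
                             signal_to_noise = 4,
                             n_reads = 20000L,
                             duplication_rate = 0.3,
                             umi_length = 9L,
                             rnaseq_depth = 2,
                             n_non_ejc_sites = 40L) {
  if (is.null(proteins)) {
    ejc <- function(frac = 0) list(type = "EJC", offsets = -24:-20,
                                   weights = c(0.3, 0.25, 0.2, 0.15, 0.1),
                                   non_ejc_fraction = frac)
    proteins <- list(BTZ = ejc(0), eIF4A3 = ejc(0.1), UPF3B = ejc(0.1),
                     RNPS1 = ejc(0.15), PTB = list(type = "PTB"),
                     GFP = list(type = "GFP"))
  }
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              exon_length_range = exon_length_range,
              intron_length_range = intron_length_range,
              alt_shift_range = alt_shift_range,
              gene_plan = gene_plan,
              fraction_multi_isoform = fraction_multi_isoform,
              n_ncRNA = as.integer(n_ncRNA),
              n_intronless = as.integer(n_intronless),
              donor_consensus = donor_consensus,
              binding_site_motif = binding_site_motif,
              junction_occupancy = junction_occupancy,
              abundance_meanlog = abundance_meanlog,
              abundance_sdlog = abundance_sdlog,
              isoform_split = isoform_split / sum(isoform_split),
              top_fraction = top_fraction, top_multiplier = top_multiplier,
              proteins = proteins, signal_to_noise = signal_to_noise,
              n_reads = as.integer(n_reads),
              duplication_rate = duplication_rate,
              umi_length = as.integer(umi_length),
              rnaseq_depth = rnaseq_depth,
              n_non_ejc_sites = as.integer(n_non_ejc_sites))
  validateSimulationConfig(cfg)
  structure(cfg, class = "SimulationConfig")
}

validateSimulationConfig <- function(cfg) {
  probs <- c(cfg$fraction_multi_isoform, cfg$top_fraction,
             cfg$top_multiplier, cfg$duplication_rate,
             cfg$junction_occupancy,
             unlist(lapply(cfg$proteins, function(p) p$non_ejc_fraction)))
  if (any(probs < 0 | probs > 1))
    stop("config error: all probabilities must lie in [0, 1]")
  if (cfg$alt_shift_range[1L] < 8L)
    stop("config error: alt_shift_range minimum must be >= 8 nt")
  if (cfg$exon_length_range[1L] < 2L * max(cfg$alt_shift_range) + 10L)
    stop("config error: exons too short for the requested boundary shifts")
  if (cfg$intron_length_range[1L] < max(cfg$alt_shift_range) +
      nchar(cfg$donor_consensus) + 40L)
    stop("config error: introns too short for shifted donors plus tracts")
  if (cfg$exon_length_range[1L] < 30L)
    stop("config error: exon minimum must cover the deposition window")
  if (nchar(cfg$donor_consensus) != 7L)
    stop("config error: donor consensus must be 7 nt (2 exon + 5 intron)")
  for (nm in names(cfg$proteins)) {
    p <- cfg$proteins[[nm]]
    if (!p$type %in% c("EJC", "PTB", "GFP"))
      stop("config error: unknown protein type for ", nm)
    if (p$type == "EJC" && length(p$offsets) != length(p$weights))
      stop("config error: offsets/weights mismatch for ", nm)
  }
  invisible(TRUE)
}

randomBases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Build one gene in transcript-local plus orientation; returns local exon
# tables per isoform, CDS spans, donor junction positions, pyrimidine
# tracts, and the local sequence with donor consensus planted.
buildLocalGene <- function(cfg, kind, multi) {
  rexon <- function(n) sample(cfg$exon_length_range[1L]:cfg$exon_length_range[2L], n, replace = TRUE)
  rintr <- function(n) sample(cfg$intron_length_range[1L]:cfg$intron_length_range[2L], n, replace = TRUE)
  rshift <- function() sample(cfg$alt_shift_range[1L]:cfg$alt_shift_range[2L], 1L)

  if (kind == "intronless") {
    w <- rexon(1L)
    seq <- randomBases(w)
    q <- floor(w / 4)
    return(list(len = w,
                iso = list(data.frame(start = 1L, end = w, cat = "single")),
                cds = list(c(1L + q, w - q)),
                donors = integer(0), tracts = NULL, seq = seq))
  }
  cats <- if (kind == "ncRNA" || !multi) {
    rep("constitutive", sum(cfg$gene_plan))
  } else {
    sample(rep(names(cfg$gene_plan), cfg$gene_plan))
  }
  nInt <- length(cats)
  widths <- rexon(nInt + 2L)
  introns <- rintr(nInt + 1L)
  starts <- integer(nInt + 2L); ends <- integer(nInt + 2L)
  pos <- 1L
  for (i in seq_len(nInt + 2L)) {
    starts[i] <- pos; ends[i] <- pos + widths[i] - 1L
    pos <- ends[i] + 1L + if (i <= nInt + 1L) introns[i] else 0L
  }
  glen <- ends[nInt + 2L]
  seq <- randomBases(glen)

  exCat <- c("five_prime_terminal", cats, "three_prime_terminal")
  iso1 <- data.frame(start = starts, end = ends, cat = exCat,
                     stringsAsFactors = FALSE)
  donors <- ends[seq_len(nInt + 1L)]  # every junction-bearing exon end

  iso <- list(iso1)
  if (multi && kind == "coding") {
    keep <- rep(TRUE, nrow(iso1))
    s2 <- starts; e2 <- ends
    for (i in seq_len(nInt) + 1L) {
      cc <- exCat[i]
      if (cc == "variant") keep[i] <- FALSE
      if (cc %in% c("alt_donor", "alt_both")) {
        d <- rshift(); e2[i] <- ends[i] + d
        donors <- c(donors, e2[i])
      }
      if (cc %in% c("alt_acceptor", "alt_both")) {
        d <- rshift(); s2[i] <- starts[i] + d
      }
    }
    iso2 <- data.frame(start = s2[keep], end = e2[keep], cat = exCat[keep],
                       stringsAsFactors = FALSE)
    iso <- c(iso, list(iso2))
  }
  # weak binding-site motif over the deposition window, then the donor
  # consensus (last 2 exon nt + first 5 intron nt); consensus wins where a
  # shifted donor's window overlaps it
  if (!is.null(cfg$binding_site_motif)) {
    for (d in donors) substr(seq, d - 24L, d - 20L) <- cfg$binding_site_motif
  }
  for (d in donors) substr(seq, d - 1L, d + 5L) <- cfg$donor_consensus
  # plant a pyrimidine tract inside each isoform-1 intron, clear of donors
  tracts <- NULL
  if (kind == "coding") {
    tl <- 30L
    tr <- lapply(seq_len(nInt + 1L), function(i) {
      lo <- ends[i] + 12L + max(cfg$alt_shift_range)
      hi <- starts[i + 1L] - 1L - tl
      if (hi <= lo) return(NULL)
      s <- sample(lo:hi, 1L)
      c(s, s + tl - 1L)
    })
    tr <- tr[!vapply(tr, is.null, logical(1))]
    for (t in tr) {
      substr(seq, t[1L], t[2L]) <-
        paste(sample(c("C", "T"), tl, replace = TRUE), collapse = "")
    }
    tracts <- tr
  }
  cdsOf <- function(df) {
    internal <- df$cat %in% c("constitutive", "variant", "alt_donor",
                              "alt_acceptor", "alt_both")
    c(min(df$start[internal]) + 10L, max(df$end[internal]) - 10L)
  }
  cds <- if (kind == "coding") lapply(iso, cdsOf) else NULL
  list(len = glen, iso = iso, cds = cds, donors = sort(unique(donors)),
       tracts = tracts, seq = seq)
}

#' Generate a synthetic genome, annotation and ground truth
#'
#' Builds a single-chromosome genome with coding (single- and multi-isoform),
#' non-coding and intronless genes on alternating strands. Every exon-intron
#' junction carries the donor consensus (last 2 exon nt + first 5 intron nt =
#' AGGTAAG by default); multi-isoform genes realize variant, alternative
#' donor, alternative acceptor and alt-both internal exons, so all seven exon
#' categories occur. Coding introns carry planted pyrimidine tracts (the
#' PTB-like binding substrate). A fraction of coding genes is flagged
#' TOP-like with depleted EJC deposition. Deterministic given the config
#' seed.
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @return list with \code{genome} (\code{DNAStringSet}), \code{annotation}
#'   (\code{\linkS4class{GenomeAnnotation}}) and \code{truth} (list: gene
#'   table with class flags and abundance, deposition windows, donor
#'   junction ends, pyrimidine tracts, per-protein non-EJC sites).
#' @export
generateGenomeAnnotation <- function(cfg) {
  withSeed(deriveSeed(cfg$seed, "genome"), {
    n <- cfg$n_genes
    kinds <- c(rep("ncRNA", cfg$n_ncRNA), rep("intronless", cfg$n_intronless))
    kinds <- c(kinds, rep("coding", max(0L, n - length(kinds))))[seq_len(n)]
    kinds <- sample(kinds)
    multi <- runif(n) < cfg$fraction_multi_isoform
    strands <- rep(c("+", "-"), length.out = n)
    abundance <- stats::rlnorm(n, cfg$abundance_meanlog, cfg$abundance_sdlog)
    isCoding <- kinds == "coding"
    top <- rep(FALSE, n)
    top[isCoding] <- runif(sum(isCoding)) < cfg$top_fraction

    segs <- character(2L * n + 1L)
    segs[1L] <- randomBases(sample(500:1500, 1L))
    offset <- nchar(segs[1L])
    geneRows <- list(); txRows <- list(); exRows <- list(); cdsRows <- list()
    junctionRows <- list(); tractRows <- list()
    for (g in seq_len(n)) {
      loc <- buildLocalGene(cfg, kinds[g], multi[g])
      st <- strands[g]
      gid <- sprintf("G%03d", g)
      seqg <- loc$seq
      flip <- function(s, e) c(loc$len - e + 1L, loc$len - s + 1L)
      if (st == "-") seqg <- reverseComplement(seqg)
      toGenomic <- function(s, e) {
        if (st == "-") { f <- flip(s, e); s <- f[1L]; e <- f[2L] }
        c(offset + s, offset + e)
      }
      geneRows[[g]] <- data.frame(gene_id = gid, start = offset + 1L,
                                  end = offset + loc$len, strand = st,
                                  biotype = if (kinds[g] == "ncRNA") "ncRNA" else "protein_coding",
                                  kind = kinds[g], top_like = top[g],
                                  abundance = abundance[g],
                                  multi_iso = length(loc$iso) > 1L,
                                  stringsAsFactors = FALSE)
      for (j in seq_along(loc$iso)) {
        tid <- sprintf("%s.T%d", gid, j)
        txRows[[length(txRows) + 1L]] <- data.frame(
          transcript_id = tid, gene_id = gid, stringsAsFactors = FALSE)
        df <- loc$iso[[j]]
        gi <- t(mapply(toGenomic, df$start, df$end))
        exRows[[length(exRows) + 1L]] <- data.frame(
          transcript_id = tid, gene_id = gid, start = gi[, 1L],
          end = gi[, 2L], strand = st, stringsAsFactors = FALSE)
        if (!is.null(loc$cds)) {
          ci <- toGenomic(loc$cds[[j]][1L], loc$cds[[j]][2L])
          cdsRows[[length(cdsRows) + 1L]] <- data.frame(
            transcript_id = tid, start = ci[1L], end = ci[2L], strand = st,
            stringsAsFactors = FALSE)
        }
      }
      if (length(loc$donors)) {
        dg <- vapply(loc$donors, function(d) toGenomic(d, d)[1L], numeric(1))
        junctionRows[[length(junctionRows) + 1L]] <- data.frame(
          gene_id = gid, pos = dg, strand = st, top_like = top[g],
          abundance = abundance[g], stringsAsFactors = FALSE)
      }
      if (!is.null(loc$tracts) && length(loc$tracts)) {
        tg <- t(vapply(loc$tracts, function(t) toGenomic(t[1L], t[2L]),
                       numeric(2)))
        tractRows[[length(tractRows) + 1L]] <- data.frame(
          gene_id = gid, start = tg[, 1L], end = tg[, 2L], strand = st,
          abundance = abundance[g], stringsAsFactors = FALSE)
      }
      segs[2L * g] <- seqg
      gap <- randomBases(sample(500:1500, 1L))
      segs[2L * g + 1L] <- gap
      offset <- offset + loc$len + nchar(gap)
    }
    chromSeq <- paste(segs, collapse = "")
    chromLen <- nchar(chromSeq)
    genome <- Biostrings::DNAStringSet(chromSeq)
    names(genome) <- "chrSim"
    si <- GenomeInfoDb::Seqinfo("chrSim", seqlengths = chromLen)

    geneDf <- do.call(rbind, geneRows)
    geneGr <- GRanges("chrSim", IRanges(geneDf$start, geneDf$end),
                      strand = geneDf$strand, seqinfo = si)
    mcols(geneGr)$gene_id <- geneDf$gene_id
    mcols(geneGr)$biotype <- geneDf$biotype
    exDf <- do.call(rbind, exRows)
    exGr <- GRanges("chrSim", IRanges(exDf$start, exDf$end),
                    strand = exDf$strand, seqinfo = si)
    o <- order(exDf$transcript_id, exDf$start)
    exonsByTx <- GenomicRanges::split(exGr[o], exDf$transcript_id[o])
    cdsDf <- do.call(rbind, cdsRows)
    cdsGr <- if (!is.null(cdsDf)) {
      gr <- GRanges("chrSim", IRanges(cdsDf$start, cdsDf$end),
                    strand = cdsDf$strand, seqinfo = si)
      names(gr) <- cdsDf$transcript_id
      gr
    } else GRanges(seqinfo = si)
    ann <- methods::new("GenomeAnnotation", genes = geneGr,
                        transcripts = do.call(rbind, txRows),
                        exonsByTx = exonsByTx, cdsByTx = cdsGr)

    juncDf <- do.call(rbind, junctionRows)
    junctions <- GRanges("chrSim", IRanges(juncDf$pos, juncDf$pos),
                         strand = juncDf$strand, seqinfo = si)
    mcols(junctions)$gene_id <- juncDf$gene_id
    mcols(junctions)$top_like <- juncDf$top_like
    mcols(junctions)$abundance <- juncDf$abundance
    mcols(junctions)$occupied <- runif(length(junctions)) < cfg$junction_occupancy
    # canonical deposition windows: offsets -24..-20 from the exon 3' end
    win <- GRanges("chrSim",
                   IRanges(ifelse(juncDf$strand == "+", juncDf$pos - 24L,
                                  juncDf$pos + 20L),
                           ifelse(juncDf$strand == "+", juncDf$pos - 20L,
                                  juncDf$pos + 24L)),
                   strand = juncDf$strand, seqinfo = si)
    mcols(win)$gene_id <- juncDf$gene_id
    mcols(win)$occupied <- mcols(junctions)$occupied
    win <- win[mcols(win)$occupied]
    tractDf <- do.call(rbind, tractRows)
    tracts <- if (!is.null(tractDf)) {
      gr <- GRanges("chrSim", IRanges(tractDf$start, tractDf$end),
                    strand = tractDf$strand, seqinfo = si)
      mcols(gr)$gene_id <- tractDf$gene_id
      mcols(gr)$abundance <- tractDf$abundance
      gr
    } else GRanges(seqinfo = si)

    # protein-specific non-EJC sites: 5'-biased exonic positions
    nonEjc <- list()
    exAll <- unlist(exonsByTx, use.names = FALSE)
    for (nm in names(cfg$proteins)) {
      p <- cfg$proteins[[nm]]
      if (!identical(p$type, "EJC") || !p$non_ejc_fraction) next
      i <- sample(length(exAll), cfg$n_non_ejc_sites, replace = TRUE)
      w <- width(exAll)[i]
      off <- floor(runif(length(i)) * pmax(1, floor(w / 2)))
      pos <- ifelse(as.character(strand(exAll))[i] == "+",
                    start(exAll)[i] + off, end(exAll)[i] - off)
      gr <- GRanges("chrSim", IRanges(pos, pos),
                    strand = strand(exAll)[i], seqinfo = si)
      nonEjc[[nm]] <- sort(gr)
    }
    truth <- list(genes = geneDf, junctions = junctions,
                  depositionWindows = win, tracts = tracts,
                  nonEjcSites = nonEjc)
    list(genome = genome, annotation = ann, truth = truth)
  })
}

sampleGeneSpanPositions <- function(geneGr, n) {
  w <- as.numeric(width(geneGr))
  gi <- sample(length(geneGr), n, replace = TRUE, prob = w)
  pos <- start(geneGr)[gi] + floor(runif(n) * w[gi])
  GRanges(seqnames(geneGr)[gi], IRanges(pos, pos),
          strand = strand(geneGr)[gi], seqinfo = seqinfo(geneGr))
}

#' Simulate a raw iCLIP crosslink library with UMIs and PCR duplicates
#'
#' Draws unique crosslink events from the protein's deposition model
#' (EJC-like: 20-24 nt upstream of junction-bearing exon 3' ends, weighted
#' by gene abundance and the TOP-like depletion multiplier; PTB-like: inside
#' intronic pyrimidine tracts; GFP-like: uniform over transcribed gene
#' spans), mixes in uniform background at the configured signal:noise ratio,
#' then amplifies each unique event to a geometric number of PCR copies
#' sharing one random barcode. Events are emitted directly at the crosslink
#' nucleotide.
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @param sim result of \code{\link{generateGenomeAnnotation}}.
#' @param protein protein name; must be present in \code{cfg$proteins}.
#' @param replicate replicate number (selects an independent RNG stream).
#' @return width-1 \code{GRanges} of raw reads with metadata column
#'   \code{name} ("readid:UMI"); one row per PCR copy.
#' @export
simulateIclip <- function(cfg, sim, protein, replicate = 1L) {
  p <- cfg$proteins[[protein]]
  if (is.null(p)) stop("unknown protein name: ", protein)
  withSeed(deriveSeed(cfg$seed, paste0("iclip:", protein, ":", replicate)), {
    truth <- sim$truth
    geneGr <- genes(sim$annotation)
    nTot <- cfg$n_reads
    snr <- cfg$signal_to_noise
    nSig <- if (p$type == "GFP") 0L else round(nTot * snr / (1 + snr))
    nNoise <- nTot - nSig

    sig <- NULL
    if (nSig > 0L && p$type == "EJC") {
      nNon <- round(nSig * (p$non_ejc_fraction %||% 0))
      nCan <- nSig - nNon
      jn <- truth$junctions[mcols(truth$junctions)$occupied]
      wj <- mcols(jn)$abundance *
        ifelse(mcols(jn)$top_like, cfg$top_multiplier, 1)
      ji <- sample(length(jn), nCan, replace = TRUE, prob = wj)
      off <- sample(p$offsets, nCan, replace = TRUE, prob = p$weights)
      pos <- ifelse(as.character(strand(jn))[ji] == "+",
                    start(jn)[ji] + off, start(jn)[ji] - off)
      sig <- GRanges(seqnames(jn)[ji], IRanges(pos, pos),
                     strand = strand(jn)[ji], seqinfo = seqinfo(jn))
      if (nNon > 0L) {
        ns <- truth$nonEjcSites[[protein]]
        si_ <- sample(length(ns), nNon, replace = TRUE)
        sig <- c(sig, ns[si_])
      }
    } else if (nSig > 0L && p$type == "PTB") {
      tr <- truth$tracts
      ti <- sample(length(tr), nSig, replace = TRUE,
                   prob = mcols(tr)$abundance * width(tr))
      pos <- start(tr)[ti] + floor(runif(nSig) * width(tr)[ti])
      sig <- GRanges(seqnames(tr)[ti], IRanges(pos, pos),
                     strand = strand(tr)[ti], seqinfo = seqinfo(tr))
    }
    noise <- if (nNoise > 0L) sampleGeneSpanPositions(geneGr, nNoise) else NULL
    parts <- Filter(Negate(is.null), list(sig, noise))
    if (!length(parts)) stop("no events simulated")
    ev <- if (length(parts) == 2L) c(parts[[1L]], parts[[2L]]) else parts[[1L]]
    mcols(ev) <- NULL

    umis <- vapply(seq_along(ev), function(i)
      paste(sample(c("A", "C", "G", "T"), cfg$umi_length, replace = TRUE),
            collapse = ""), character(1))
    k <- 1L + stats::rgeom(length(ev), prob = 1 - cfg$duplication_rate)
    idx <- rep(seq_along(ev), k)
    raw <- ev[idx]
    mcols(raw)$name <- sprintf("r%07d:%s", seq_along(raw), umis[idx])
    attr(raw, "protein") <- protein
    sort(raw)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate strand-specific RNA-seq coverage
#'
#' Per-position RNA-seq read-start counts: Poisson with rate proportional to
#' summed isoform abundance over exonic positions (isoform 1 and 2 split by
#' \code{isoform_split}), zero in introns and intergenic space. Returned as
#' a \code{\linkS4class{CrosslinkTrack}} so the same counting, RPM and
#' profiling machinery applies.
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @param sim result of \code{\link{generateGenomeAnnotation}}.
#' @param replicate replicate number (independent RNG stream).
#' @return a \code{\linkS4class{CrosslinkTrack}} with library id
#'   \code{"RNAseq_rep<k>"}.
#' @export
simulateRnaseq <- function(cfg, sim, replicate = 1L) {
  withSeed(deriveSeed(cfg$seed, paste0("rnaseq:", replicate)), {
    ann <- sim$annotation
    truth <- sim$truth
    meanAb <- exp(cfg$abundance_meanlog + cfg$abundance_sdlog^2 / 2)
    tx <- transcriptTable(ann)
    ebt <- exonsByTranscript(ann)
    ab <- stats::setNames(truth$genes$abundance, truth$genes$gene_id)
    lamb <- list(); posl <- list(); strl <- list()
    for (gid in unique(tx$gene_id)) {
      tids <- tx$transcript_id[tx$gene_id == gid]
      share <- if (length(tids) > 1L) cfg$isoform_split else 1
      for (j in seq_along(tids)) {
        e <- ebt[[tids[j]]]
        pos <- unlist(lapply(seq_along(e),
                             function(i) start(e)[i]:end(e)[i]))
        lamb[[length(lamb) + 1L]] <-
          rep(cfg$rnaseq_depth * ab[[gid]] * share[j] / meanAb, length(pos))
        posl[[length(posl) + 1L]] <- pos
        strl[[length(strl) + 1L]] <-
          rep(as.character(strand(e))[1L], length(pos))
      }
    }
    pos <- unlist(posl); lam <- unlist(lamb); str <- unlist(strl)
    key <- paste(pos, str)
    agg <- rowsum(lam, key)
    parts <- strsplit(rownames(agg), " ", fixed = TRUE)
    upos <- as.integer(vapply(parts, `[[`, character(1), 1L))
    ustr <- vapply(parts, `[[`, character(1), 2L)
    cnt <- stats::rpois(length(upos), agg[, 1L])
    keep <- cnt > 0L
    ev <- GRanges("chrSim", IRanges(upos[keep], upos[keep]),
                  strand = ustr[keep], seqinfo = seqinfo(genes(ann)))
    mcols(ev)$count <- cnt[keep]
    newCrosslinkTrack(sprintf("RNAseq_rep%d", replicate), ev)
  })
}
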
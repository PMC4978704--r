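#' @include AllClasses.R simulate.R crosslinks.R peakcalling.R motifs.R sites.R profiles.R stats.R
NULL

pipelineStages <- c("simulate", "crosslinks", "peaks", "motifs", "sites",
                    "candidates", "profiles", "stats")

#' Run the analysis pipeline end to end on simulated data
#'
#' Chains the stages simulate (genome, annotation, per-protein raw iCLIP
#' BEDs with UMIs, RNA-seq), crosslinks (UMI deduplication, bedGraphs,
#' count matrix), peaks (per-protein permutation peak calling on pooled
#' replicates), motifs (5mer enrichment around BTZ peaks), sites
#' (high-confidence multi-protein sites, GFP-filtered), candidates
#' (non-annotated candidate exons), profiles (exon metaprofiles, region
#' distribution) and stats (differential binding stand-in vs PTB). Every
#' stage writes its artifacts under \code{outdir} plus a JSON manifest with
#' parameters, seeds and md5 checksums; re-running with an identical
#' configuration reproduces identical checksums.
#'
#' @param outdir output directory (created if needed).
#' @param config a \code{\link{simulationConfig}}.
#' @param params \code{\link{pipelineParams}}.
#' @param stages character vector of stages, or "all".
#' @param n_replicates iCLIP replicates per protein.
#' @return named list of artifact paths, invisibly.
#' @export
runPipeline <- function(outdir, config = simulationConfig(),
                        params = pipelineParams(), stages = "all",
                        n_replicates = 2L) {
  if (identical(stages, "all")) stages <- pipelineStages
  bad <- setdiff(stages, pipelineStages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  st <- new.env(parent = emptyenv())
  st$paths <- list()
  for (s in pipelineStages) {
    if (!s %in% stages) next
    fn <- get(paste0("stage_", s), mode = "function")
    fn(st, outdir, config, params, n_replicates)
  }
  invisible(st$paths)
}

writeManifest <- function(outdir, stage, files, config, params) {
  manifest <- list(stage = stage, seed = config$seed,
                   params = params[order(names(params))],
                   files = as.list(tools::md5sum(sort(unlist(files)))))
  path <- file.path(outdir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

needArtifact <- function(path, stage) {
  if (!all(file.exists(path)))
    stop("missing artifact ", paste(path[!file.exists(path)], collapse = ", "),
         ": run the '", stage, "' stage first")
  path
}

proteinLabels <- function(config) names(config$proteins)

stage_simulate <- function(st, outdir, config, params, n_replicates) {
  sim <- generateGenomeAnnotation(config)
  st$sim <- sim
  fa <- file.path(outdir, "genome.fa")
  Biostrings::writeXStringSet(sim$genome, fa)
  gtf <- file.path(outdir, "annotation.gtf")
  writeGTF(sim$annotation, gtf)
  sizes <- file.path(outdir, "chrom.sizes")
  writeChromSizes(sim$annotation, sizes)
  files <- list(fa, gtf, sizes)
  for (prot in proteinLabels(config)) {
    for (r in seq_len(n_replicates)) {
      raw <- simulateIclip(config, sim, prot, replicate = r)
      p <- file.path(outdir, sprintf("%s_rep%d.raw.bed", prot, r))
      writeCrosslinkBed(raw, p)
      files[[length(files) + 1L]] <- p
    }
  }
  rna <- simulateRnaseq(config, sim)
  st$rnaseq <- rna
  files <- c(files, as.list(writeBedgraph(rna, file.path(outdir, "rnaseq"))))
  truthTsv <- file.path(outdir, "truth_genes.tsv")
  utils::write.table(sim$truth$genes, truthTsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  win <- sim$truth$depositionWindows
  winBed <- file.path(outdir, "truth_deposition_windows.bed")
  utils::write.table(
    data.frame(as.character(seqnames(win)), bed0Start(win), bed0End(win),
               mcols(win)$gene_id, 0L, as.character(strand(win))),
    winBed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  files <- c(files, list(truthTsv, winBed))
  st$paths$simulate <- unlist(files)
  writeManifest(outdir, "simulate", files, config, params)
}

loadAnnotation <- function(st, outdir) {
  if (is.null(st$ann)) {
    gtf <- needArtifact(file.path(outdir, "annotation.gtf"), "simulate")
    sizes <- needArtifact(file.path(outdir, "chrom.sizes"), "simulate")
    st$ann <- readGTF(gtf, chromLengths = sizes)
  }
  st$ann
}

loadGenome <- function(st, outdir) {
  if (is.null(st$genome)) {
    fa <- needArtifact(file.path(outdir, "genome.fa"), "simulate")
    st$genome <- Biostrings::readDNAStringSet(fa)
    names(st$genome) <- sub(" .*", "", names(st$genome))
  }
  st$genome
}

stage_crosslinks <- function(st, outdir, config, params, n_replicates) {
  ann <- loadAnnotation(st, outdir)
  si <- seqinfo(genes(ann))
  tracks <- list()
  files <- list()
  counts <- list()
  for (prot in proteinLabels(config)) {
    for (r in seq_len(n_replicates)) {
      lab <- sprintf("%s_rep%d", prot, r)
      raw <- readCrosslinkBed(
        needArtifact(file.path(outdir, paste0(lab, ".raw.bed")), "simulate"),
        seqinfo = si)
      tr <- dedupUmis(raw, library_id = lab)
      tracks[[lab]] <- tr
      files <- c(files,
                 as.list(writeBedgraph(tr, file.path(outdir, lab))))
      counts[[lab]] <- countPerGene(tr, ann)
    }
  }
  st$tracks <- tracks
  cm <- file.path(outdir, "gene_counts.tsv")
  writeCountMatrix(counts, cm)
  files[[length(files) + 1L]] <- cm
  st$paths$crosslinks <- unlist(files)
  writeManifest(outdir, "crosslinks", files, config, params)
}

loadTracks <- function(st, outdir, config, n_replicates) {
  if (is.null(st$tracks)) {
    tracks <- list()
    for (prot in proteinLabels(config)) {
      for (r in seq_len(n_replicates)) {
        lab <- sprintf("%s_rep%d", prot, r)
        needArtifact(file.path(outdir, paste0(lab, ".plus.bedgraph")),
                     "crosslinks")
        tracks[[lab]] <- readBedgraph(file.path(outdir, lab),
                                      library_id = lab)
      }
    }
    st$tracks <- tracks
  }
  st$tracks
}

pooledProteinTracks <- function(st, outdir, config, n_replicates) {
  if (is.null(st$pooled)) {
    tracks <- loadTracks(st, outdir, config, n_replicates)
    pooled <- list()
    for (prot in proteinLabels(config)) {
      reps <- tracks[grep(paste0("^", prot, "_rep"), names(tracks))]
      pooled[[prot]] <- poolTracks(reps, library_id = prot)
    }
    st$pooled <- pooled
  }
  st$pooled
}

stage_peaks <- function(st, outdir, config, params, n_replicates) {
  ann <- loadAnnotation(st, outdir)
  pooled <- pooledProteinTracks(st, outdir, config, n_replicates)
  st$peaksets <- list()
  files <- list()
  for (prot in names(pooled)) {
    ps <- callPeaks(pooled[[prot]], ann, params, protein = prot)
    st$peaksets[[prot]] <- ps
    p <- file.path(outdir, paste0(prot, ".peaks.bed"))
    writePeakBed(ps, p)
    files[[length(files) + 1L]] <- p
  }
  st$paths$peaks <- unlist(files)
  writeManifest(outdir, "peaks", files, config, params)
}

loadPeaksets <- function(st, outdir, config, params) {
  if (is.null(st$peaksets)) {
    st$peaksets <- list()
    for (prot in proteinLabels(config)) {
      p <- needArtifact(file.path(outdir, paste0(prot, ".peaks.bed")),
                        "peaks")
      df <- tryCatch(utils::read.table(p, sep = "\t"), error = function(e) NULL)
      gr <- if (is.null(df)) GRanges() else {
        g <- GRanges(df[[1L]], IRanges(df[[2L]] + 1L, df[[3L]]),
                     strand = df[[6L]])
        mcols(g)$count <- df[[5L]]; mcols(g)$score <- df[[7L]]
        mcols(g)$fdr <- df[[8L]]
        mcols(g)$summit <- peakMidpoint(g)
        g
      }
      if (!length(gr)) {
        mcols(gr)$summit <- integer(0); mcols(gr)$score <- numeric(0)
        mcols(gr)$fdr <- numeric(0); mcols(gr)$count <- numeric(0)
      }
      st$peaksets[[prot]] <- methods::new("PeakSet", peaks = gr,
                                          protein = prot, params = params)
    }
  }
  st$peaksets
}

stage_motifs <- function(st, outdir, config, params, n_replicates) {
  ann <- loadAnnotation(st, outdir)
  genome <- loadGenome(st, outdir)
  ps <- loadPeaksets(st, outdir, config, params)
  files <- list()
  for (prot in intersect(c("BTZ", "PTB"), names(ps))) {
    if (!length(peaks(ps[[prot]]))) next
    kps <- kmerEnrichment(ps[[prot]], ann, genome, params)
    p <- file.path(outdir, paste0(prot, ".5mers.tsv"))
    writeKmerStats(kps, p)
    files[[length(files) + 1L]] <- p
    if (prot == "BTZ") st$kmersBTZ <- kps
  }
  st$paths$motifs <- unlist(files)
  writeManifest(outdir, "motifs", files, config, params)
}

stage_sites <- function(st, outdir, config, params, n_replicates) {
  ps <- loadPeaksets(st, outdir, config, params)
  pooled <- pooledProteinTracks(st, outdir, config, n_replicates)
  ejcProts <- names(which(vapply(config$proteins, function(p)
    identical(p$type, "EJC"), logical(1))))
  sites <- mergeHighConfidence(ps[ejcProts], gfp = ps[["GFP"]],
                               tracks = pooled[ejcProts], params = params)
  st$sites <- sites
  bed <- file.path(outdir, "highconf_sites.bed")
  writeSitesBed(sites, bed)
  stats <- if (length(sites)) btzMarkingStats(sites) else
    list(n_sites = 0L, n_with_btz = 0L, fraction = NA_real_)
  js <- file.path(outdir, "btz_marking.json")
  jsonlite::write_json(stats, js, auto_unbox = TRUE, pretty = TRUE)
  st$paths$sites <- c(bed, js)
  writeManifest(outdir, "sites", list(bed, js), config, params)
}

stage_candidates <- function(st, outdir, config, params, n_replicates) {
  ann <- loadAnnotation(st, outdir)
  genome <- loadGenome(st, outdir)
  ps <- loadPeaksets(st, outdir, config, params)
  pooled <- pooledProteinTracks(st, outdir, config, n_replicates)
  others <- intersect(c("eIF4A3", "UPF3B", "RNPS1"), names(ps))
  cand <- findCandidateExons(pooled[["BTZ"]], ps[["BTZ"]], ps[others],
                             ann, genome, params)
  df <- data.frame(chrom = as.character(seqnames(cand)),
                   start = bed0Start(cand), end = bed0End(cand),
                   strand = as.character(strand(cand)),
                   btz_rpm = mcols(cand)$btz_rpm,
                   supporter = mcols(cand)$supporter,
                   motif = mcols(cand)$motif,
                   motif_offset = mcols(cand)$motif_offset)
  p <- file.path(outdir, "candidate_exons.tsv")
  utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  st$candidates <- cand
  st$paths$candidates <- p
  writeManifest(outdir, "candidates", list(p), config, params)
}

stage_profiles <- function(st, outdir, config, params, n_replicates) {
  ann <- loadAnnotation(st, outdir)
  pooled <- pooledProteinTracks(st, outdir, config, n_replicates)
  ps <- loadPeaksets(st, outdir, config, params)
  catalog <- classifyExons(ann)
  const <- catalog[mcols(catalog)$category == "constitutive"]
  files <- list()
  prof <- do.call(cbind, lapply(names(pooled), function(prot)
    exonMetaprofile(pooled[[prot]], const, params)$mean))
  colnames(prof) <- names(pooled)
  p1 <- file.path(outdir, "constitutive_exon_profiles.tsv")
  utils::write.table(data.frame(bin = seq_len(nrow(prof)), prof), p1,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files[[1L]] <- p1
  rmap <- buildRegionMap(ann)
  dist <- do.call(rbind, lapply(names(ps), function(prot) {
    if (!length(peaks(ps[[prot]]))) return(NULL)
    cbind(protein = prot, regionDistribution(ps[[prot]], rmap))
  }))
  p2 <- file.path(outdir, "peak_region_distribution.tsv")
  utils::write.table(dist, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  files[[2L]] <- p2
  st$paths$profiles <- unlist(files)
  writeManifest(outdir, "profiles", files, config, params)
}

stage_stats <- function(st, outdir, config, params, n_replicates) {
  cm <- needArtifact(file.path(outdir, "gene_counts.tsv"), "crosslinks")
  df <- utils::read.table(cm, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  groupA <- grep("^BTZ_rep", colnames(m), value = TRUE)
  groupB <- grep("^PTB_rep", colnames(m), value = TRUE)
  res <- differentialBindingStandin(m, groupA, groupB, params)
  p <- file.path(outdir, "differential_binding_BTZ_vs_PTB.tsv")
  utils::write.table(cbind(gene_id = rownames(res), res), p, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  st$paths$stats <- p
  writeManifest(outdir, "stats", list(p), config, params)
}
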
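mkPeakSet <- function(protein, ivls, strand = "+", chromLen = 1000L) {
  si <- GenomeInfoDb::Seqinfo("chr1", seqlengths = chromLen)
  n <- length(ivls)
  gr <- if (n) {
    g <- GRanges(rep("chr1", n),
                 IRanges(vapply(ivls, `[[`, numeric(1), 1L),
                         vapply(ivls, `[[`, numeric(1), 2L)),
                 strand = strand, seqinfo = si)
    mcols(g)$summit <- floor((start(g) + end(g)) / 2) - 1L
    mcols(g)$score <- 5; mcols(g)$fdr <- 0.01
    mcols(g)$count <- 5
    g
  } else {
    g <- GRanges(seqinfo = si)
    mcols(g)$summit <- integer(0); mcols(g)$score <- numeric(0)
    mcols(g)$fdr <- numeric(0); mcols(g)$count <- numeric(0)
    g
  }
  new("PeakSet", peaks = gr, protein = protein, params = pipelineParams())
}

test_that("sites require a 1 nt overlap between different proteins", {
  # 0-based [100,110) and [109,120) overlap by 1 nt -> one site [100,120)
  ps <- list(BTZ = mkPeakSet("BTZ", list(c(101L, 110L))),
             eIF4A3 = mkPeakSet("eIF4A3", list(c(110L, 120L))))
  sites <- mergeHighConfidence(ps)
  expect_equal(length(sites), 1L)
  expect_equal(start(sites) - 1L, 100L)
  expect_equal(end(sites), 120L)
  expect_setequal(unlist(mcols(sites)$supporters), c("BTZ", "eIF4A3"))
  expect_true(mcols(sites)$contains_btz)

  # abutting peaks ([100,110) then [110,120)) do not overlap
  ps2 <- list(BTZ = mkPeakSet("BTZ", list(c(101L, 110L))),
              eIF4A3 = mkPeakSet("eIF4A3", list(c(111L, 120L))))
  expect_equal(length(mergeHighConfidence(ps2)), 0L)

  # a single protein cannot define high-confidence sites
  expect_error(mergeHighConfidence(ps[1L]), ">=2 proteins")
})

test_that("sites overlapping GFP peaks are removed and counted", {
  ps <- list(BTZ = mkPeakSet("BTZ", list(c(101L, 110L), c(501L, 510L))),
             eIF4A3 = mkPeakSet("eIF4A3", list(c(105L, 115L), c(505L, 512L))))
  gfp <- mkPeakSet("GFP", list(c(500L, 520L)))
  sites <- mergeHighConfidence(ps, gfp = gfp)
  expect_equal(length(sites), 1L)
  expect_equal(start(sites), 101L)
  expect_equal(attr(sites, "gfp_removed"), 1L)
})

test_that("merged sites are pairwise disjoint and cover their member peaks", {
  s <- smallSim()
  params <- pipelineParams(rng_seed = 101L)
  tracks <- list(BTZ = smallBtzTrack(),
                 eIF4A3 = dedupUmis(simulateIclip(s$cfg, s$sim, "eIF4A3"),
                                    "eIF4A3"))
  ps <- list(BTZ = smallBtzPeaks(),
             eIF4A3 = callPeaks(tracks$eIF4A3, s$sim$annotation, params,
                                protein = "eIF4A3"))
  sites <- mergeHighConfidence(ps, tracks = tracks, params = params)
  expect_gt(length(sites), 10L)
  # disjoint per strand
  for (st in c("+", "-")) {
    ss <- sites[strand(sites) == st]
    expect_equal(length(GenomicRanges::reduce(ss)), length(ss))
  }
  # every supporter's peaks overlapping a site are covered by it
  hits <- GenomicRanges::findOverlaps(peaks(ps$BTZ), sites,
                                      ignore.strand = FALSE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  expect_true(all(start(sites)[sh] <= start(peaks(ps$BTZ))[qh]))
  expect_true(all(end(sites)[sh] >= end(peaks(ps$BTZ))[qh]))
})

test_that("BTZ marking statistics report the supported fraction", {
  ps <- list(BTZ = mkPeakSet("BTZ", list(c(101L, 110L))),
             eIF4A3 = mkPeakSet("eIF4A3", list(c(105L, 115L), c(301L, 310L))),
             UPF3B = mkPeakSet("UPF3B", list(c(305L, 312L))))
  sites <- mergeHighConfidence(ps)
  st <- btzMarkingStats(sites)
  expect_equal(st$n_sites, 2L)
  expect_equal(st$n_with_btz, 1L)
  expect_equal(st$fraction, 0.5)
  expect_error(btzMarkingStats(sites[0]), "no high-confidence sites")
})

test_that("full-EJC simulations leave BTZ on nearly all sites", {
  fx <- ejcFixture()
  sites <- mergeHighConfidence(fx$peaksets, gfp = fx$gfpPeaks,
                               tracks = fx$tracks, params = fx$params)
  expect_gte(btzMarkingStats(sites)$fraction, 0.9)
})

test_that("non-BTZ co-peaks without BTZ lack the 3'-end exon signal", {
  # planted case: two proteins co-bind the 5' quarter of an exon
  ps <- list(eIF4A3 = mkPeakSet("eIF4A3", list(c(211L, 220L))),
             UPF3B = mkPeakSet("UPF3B", list(c(215L, 224L))))
  btz <- mkPeakSet("BTZ", list(c(601L, 610L)))
  exons <- GRanges("chr1", IRanges(201L, 300L), strand = "+")
  res <- nonBtzSiteProfile(ps, btz, exons, pipelineParams())
  expect_equal(res$n_sites, 1L)
  expect_gt(which.max(res$profile), 0L)
  expect_lte(which.max(res$profile), 25L)  # 5'-shifted maximum
  # empty set -> flat zero
  res0 <- nonBtzSiteProfile(
    list(eIF4A3 = mkPeakSet("eIF4A3", list()),
         UPF3B = mkPeakSet("UPF3B", list())), btz, exons, pipelineParams())
  expect_equal(res0$n_sites, 0L)
  expect_true(all(res0$profile == 0))
})

test_that("candidate exons demand all three conditions", {
  # unannotated BTZ peak, supported, with a donor motif 10 nt downstream
  base <- strrep("C", 1000L)
  substr(base, 521L, 527L) <- "AGGTAAG"  # starts 10 nt after peak end 510
  genome <- Biostrings::DNAStringSet(base); names(genome) <- "chr1"
  ann <- makeAnnotation(list(
    t1 = list(gene = "g1", strand = "+",
              exons = list(c(1L, 100L), c(801L, 900L)), cds = c(51L, 850L))))
  btzTrack <- makeTrack(data.frame(pos = c(505L, rep(50L, 7L)),
                                   count = c(3L, rep(1L, 7L))))
  btzPk <- mkPeakSet("BTZ", list(c(501L, 510L)))
  upf <- list(UPF3B = mkPeakSet("UPF3B", list(c(505L, 515L))))
  params <- pipelineParams()
  cand <- findCandidateExons(btzTrack, btzPk, upf, ann, genome, params)
  expect_equal(length(cand), 1L)
  expect_equal(mcols(cand)$motif, "AGGTAAG")
  expect_equal(mcols(cand)$motif_offset, 10L)
  expect_equal(mcols(cand)$supporter, "UPF3B")
  expect_gt(mcols(cand)$btz_rpm, params$candidate_btz_rpm)

  # motif 30 nt downstream -> rejected
  base2 <- strrep("C", 1000L)
  substr(base2, 541L, 547L) <- "AGGTAAG"
  genome2 <- Biostrings::DNAStringSet(base2); names(genome2) <- "chr1"
  expect_equal(length(findCandidateExons(btzTrack, btzPk, upf, ann,
                                         genome2, params)), 0L)

  # peak overlapping an annotated exon by 1 nt -> rejected
  btzPk2 <- mkPeakSet("BTZ", list(c(100L, 510L)))
  expect_equal(length(findCandidateExons(btzTrack, btzPk2, upf, ann,
                                         genome, params)), 0L)

  # no supporting second protein -> rejected
  none <- list(UPF3B = mkPeakSet("UPF3B", list(c(801L, 820L))))
  expect_equal(length(findCandidateExons(btzTrack, btzPk, none, ann,
                                         genome, params)), 0L)
})

test_that("candidate calls on simulated data never intersect annotated exons", {
  s <- smallSim()
  fx <- ejcFixture()
  ps <- fx$peaksets
  tracks <- fx$tracks
  cand <- findCandidateExons(tracks$BTZ, ps$BTZ,
                             ps[c("eIF4A3", "UPF3B", "RNPS1")],
                             s$sim$annotation, s$sim$genome,
                             pipelineParams())
  exAll <- unlist(exonsByTranscript(s$sim$annotation), use.names = FALSE)
  expect_false(any(IRanges::overlapsAny(cand, exAll, ignore.strand = FALSE)))
})

test_that("the low-abundance exon filter applies strict thresholds", {
  # 1e6-event libraries so counts equal RPM
  catalog <- GRanges("chr1", IRanges(c(101L, 301L), c(200L, 400L)),
                     strand = "+")
  mcols(catalog)$category <- c("constitutive", "variant")
  mkT <- function(pos, count) {
    makeTrack(data.frame(pos = c(pos, 900L),
                         count = c(count, 1e6 - sum(count))))
  }
  btz <- mkT(150L, 1.5)      # exon 1: BTZ 1.5 RPM
  eif <- mkT(160L, 1.2)      # exon 1: eIF4A3 1.2 RPM
  rnaLow <- mkT(170L, 0.3)   # exon 1: RNA-seq 0.3 RPM
  t1 <- table1Filter(catalog, btz, list(eIF4A3 = eif), rnaLow,
                     pipelineParams())
  expect_equal(t1$n_pass[t1$category == "constitutive"], 1)
  expect_equal(t1$pct[t1$category == "constitutive"], 100)
  expect_equal(t1$n_pass[t1$category == "variant"], 0)

  # RNA-seq exactly 0.5 RPM fails the strict < threshold
  rnaEdge <- mkT(170L, 0.5)
  t2 <- table1Filter(catalog, btz, list(eIF4A3 = eif), rnaEdge,
                     pipelineParams())
  expect_equal(t2$n_pass[t2$category == "constitutive"], 0)

  # BTZ alone (others zero) fails
  eifZero <- mkT(750L, 1.2)  # signal outside the exon
  t3 <- table1Filter(catalog, btz, list(eIF4A3 = eifZero), rnaLow,
                     pipelineParams())
  expect_equal(sum(t3$n_pass), 0)
})

test_that("expression and EJC marking thresholds are inclusive at 10 reads", {
  catalog <- GRanges("chr1", IRanges(c(101L, 301L), c(200L, 400L)),
                     strand = "+")
  rna <- makeTrack(data.frame(pos = c(150L, 350L), count = c(10L, 9L)))
  btz <- makeTrack(data.frame(pos = c(160L, 360L), count = c(9L, 50L)))
  res <- expressedAndMarkedExons(catalog, rna, btz, pipelineParams())
  expect_equal(res$expressed, c(TRUE, FALSE))   # 10 reads counts, 9 not
  expect_equal(res$ejc_positive, c(FALSE, FALSE))  # 9 BTZ events miss
  btz2 <- makeTrack(data.frame(pos = 160L, count = 10L))
  res2 <- expressedAndMarkedExons(catalog, rna, btz2, pipelineParams())
  expect_equal(res2$n_ejc_positive, 1L)
})

test_that("recovered expressed/marked counts track the simulation truth", {
  s <- smallSim()
  rna <- simulateRnaseq(s$cfg, s$sim)
  catalog <- classifyExons(s$sim$annotation)
  res <- expressedAndMarkedExons(catalog, rna, smallBtzTrack(),
                                 pipelineParams())
  # expressed exons dominate (log-normal abundances, depth 2/nt);
  # EJC-positive only where junction deposition exists
  expect_gt(res$n_expressed / length(catalog), 0.6)
  expect_gt(res$n_ejc_positive, 0L)
  expect_lte(res$n_ejc_positive, res$n_expressed)
  # no 3'-terminal exon of a single-junction gene can exceed its truth:
  # EJC-positive exons must carry >= 10 BTZ events in truth windows or noise
  expect_lt(res$n_ejc_positive, length(catalog))
})
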
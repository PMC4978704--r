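test_that("exon binning maps offsets by the floor rule and conserves counts", {
  # exon of length 200, event at transcript offset 176 (0-based; -24 from
  # the 3' end), 100 bins -> bin floor(176*100/200) = 88 (0-based)
  exon <- GRanges("chr1", IRanges(101L, 300L), strand = "+")
  tr <- makeTrack(data.frame(pos = 101L + 176L, count = 1L))
  em <- exonMatrix(tr, exon, pipelineParams(), scale_rpm = FALSE)
  expect_equal(which(em$matrix[1L, ] > 0) - 1L, 88L)
  expect_equal(sum(em$matrix), 1)

  # same exon on the minus strand: offset measured from the genomic end
  exonM <- GRanges("chr1", IRanges(101L, 300L), strand = "-")
  trM <- makeTrack(data.frame(pos = 300L - 176L, count = 1L, strand = "-"))
  emM <- exonMatrix(trM, exonM, pipelineParams(), scale_rpm = FALSE)
  expect_equal(which(emM$matrix[1L, ] > 0) - 1L, 88L)
})

test_that("binning conserves totals for arbitrary exons and events", {
  set.seed(7)
  for (rep in 1:5) {
    starts <- cumsum(sample(150:400, 6L))
    w <- sample(31:350, 6L)
    exons <- GRanges("chr1", IRanges(starts, starts + w - 1L),
                     strand = sample(c("+", "-"), 6L, replace = TRUE))
    pos <- unlist(lapply(seq_along(exons), function(i)
      sample(start(exons)[i]:end(exons)[i], 10L, replace = TRUE)))
    df <- data.frame(pos = pos,
                     count = sample(1:4, length(pos), replace = TRUE),
                     strand = rep(as.character(strand(exons)), each = 10L))
    key <- paste(df$pos, df$strand)
    agg <- rowsum(df$count, key)
    first <- !duplicated(key)
    tr <- makeTrack(data.frame(pos = df$pos[first],
                               count = agg[key[first], 1L],
                               strand = df$strand[first]),
                    chromLen = 5000L)
    em <- exonMatrix(tr, exons, pipelineParams(), scale_rpm = FALSE)
    hits <- GenomicRanges::findOverlaps(em$exons, eventRanges(tr),
                                        ignore.strand = FALSE)
    perExon <- vapply(seq_along(em$exons), function(i)
      sum(S4Vectors::mcols(eventRanges(tr))$count[
        S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]]),
      numeric(1))
    expect_equal(unname(rowSums(em$matrix)), perExon)
  }
})

test_that("uniform coverage yields a flat metaprofile", {
  exon <- GRanges("chr1", IRanges(101L, 300L), strand = "+")
  tr <- makeTrack(data.frame(pos = 101:300, count = 1L))
  prof <- exonMetaprofile(tr, exon, pipelineParams(), scale_rpm = FALSE)
  expect_true(all(prof$mean == prof$mean[1L]))
})

test_that("rows are ordered by absolute exon length across signals", {
  exons <- GRanges("chr1", IRanges(c(101L, 401L, 601L),
                                   c(350L, 500L, 640L)), strand = "+")
  tr <- makeTrack(data.frame(pos = c(150L, 450L, 620L), count = 1:3))
  em <- exonMatrix(tr, exons, pipelineParams(), scale_rpm = FALSE)
  expect_equal(width(em$exons), sort(width(exons)))
  expect_equal(unname(rowSums(em$matrix)), c(3, 2, 1))
})

test_that("junction metaplots place planted signal at its offset", {
  ann <- makeAnnotation(list(
    t1 = list(gene = "g1", strand = "+",
              exons = list(c(1L, 100L), c(201L, 300L)), cds = c(51L, 250L))))
  # all events exactly at offset -24 from the junction end (pos 100)
  tr <- makeTrack(data.frame(pos = 76L, count = 10L))
  prof <- junctionMetaplot(tr, ann, offsets = -50:10, scale_rpm = FALSE)
  expect_equal(unname(which(prof > 0)), which(-50:10 == -24L))
})

test_that("EJC simulations put the junction argmax in the deposition window and the exon maximum near the 3' end", {
  s <- smallSim()
  tr <- smallBtzTrack()
  prof <- junctionMetaplot(tr, s$sim$annotation, offsets = -50:10)
  am <- as.integer(names(which.max(prof)))
  expect_gte(am, -24L); expect_lte(am, -20L)
  cat <- classifyExons(s$sim$annotation)
  const <- cat[S4Vectors::mcols(cat)$category == "constitutive"]
  exProf <- exonMetaprofile(tr, const, pipelineParams())
  expect_gt(which.max(exProf$mean), 85L)  # maximum within the last 15 bins
  term <- cat[S4Vectors::mcols(cat)$category == "three_prime_terminal"]
  termProf <- exonMetaprofile(tr, term, pipelineParams())
  # 3' terminal exons bear no junction: their 3'-end signal is much weaker
  expect_lt(max(termProf$mean[86:100]), max(exProf$mean[86:100]) / 2)
})

test_that("GFP simulations give a flat junction metaplot", {
  s <- smallSim()
  gfp <- dedupUmis(simulateIclip(s$cfg, s$sim, "GFP"), "GFP")
  prof <- junctionMetaplot(gfp, s$sim$annotation, offsets = -50:10)
  expect_lt(max(prof), 2 * stats::median(prof) + 1e-9)
})

test_that("ranking by RNA-seq minus iCLIP difference is stable and labels categories", {
  m <- matrix(1, nrow = 4L, ncol = 10L)
  res <- rankExonsByDifference(m, m)
  expect_true(all(res$diff == 0))
  expect_equal(attr(res, "order"), 1:4)  # stable order on ties
  # one exon with RNA-seq >> iCLIP ranks first as category 1
  rna <- m; rna[3L, ] <- 50
  res2 <- rankExonsByDifference(m, rna)
  expect_equal(attr(res2, "order")[1L], 3L)
  expect_equal(res2$category[3L], 1L)
})

test_that("EJC-depleted gene classes land in the abundant-but-weak category", {
  cfg <- simulationConfig(seed = 31, n_genes = 30L, top_fraction = 0.3,
                          top_multiplier = 0.1, n_reads = 30000L)
  sim <- generateGenomeAnnotation(cfg)
  btz <- dedupUmis(simulateIclip(cfg, sim, "BTZ"), "BTZ")
  rna <- simulateRnaseq(cfg, sim)
  cat <- classifyExons(sim$annotation)
  const <- cat[S4Vectors::mcols(cat)$category == "constitutive"]
  icl <- exonMatrix(btz, const, pipelineParams())
  rnm <- exonMatrix(rna, const, pipelineParams())
  res <- rankExonsByDifference(icl, rnm)
  gtop <- stats::setNames(sim$truth$genes$top_like, sim$truth$genes$gene_id)
  topRows <- gtop[S4Vectors::mcols(icl$exons)$gene_id]
  rnaMeans <- rowMeans(rnm$matrix)
  expressedTop <- topRows & rnaMeans > stats::median(rnaMeans[rnaMeans > 0])
  expect_gte(mean(res$category[expressedTop] == 1L), 0.7)
})

test_that("log2 fold differences follow the pseudo-counted maxima", {
  exon <- GRanges("chr1", IRanges(101L, 300L), strand = "+")
  # equal maxima -> 0
  a <- makeTrack(data.frame(pos = 150L, count = 100L))
  res0 <- log2FoldDifference(a, a, exon, pipelineParams())
  expect_equal(res0$per_exon$lfc, 0)
  # iCLIP max 8x the RNA-seq max, both >> pseudo-count: about 3.0
  icl <- makeTrack(data.frame(pos = c(150L, 900L), count = c(800L, 200L)))
  rna <- makeTrack(data.frame(pos = c(150L, 900L), count = c(100L, 900L)))
  res <- log2FoldDifference(icl, rna, exon, pipelineParams())
  # bins are RPM-scaled (library size 1000 each): 8e5 vs 1e5 RPM maxima
  expect_equal(res$per_exon$lfc, log2((8e5 + 0.5) / (1e5 + 0.5)),
               tolerance = 1e-12)
  expect_lt(abs(res$per_exon$lfc - 3), 0.01)
})

test_that("variant exons with doubled deposition show a higher per-category aggregate", {
  s <- smallSim()
  cfg <- s$cfg; sim <- s$sim
  btz <- smallBtzTrack()
  rna <- simulateRnaseq(cfg, sim)
  cat <- classifyExons(sim$annotation)
  keep <- S4Vectors::mcols(cat)$category %in% c("constitutive", "variant")
  res <- log2FoldDifference(btz, rna, cat[keep], pipelineParams())
  agg <- res$aggregate
  # variant exons sit on the minor isoform: same per-junction deposition but
  # lower RNA-seq, so iCLIP/RNA-seq ratios exceed the constitutive ones
  expect_gt(agg$median[agg$category == "variant"],
            agg$median[agg$category == "constitutive"])
})

test_that("region distribution percentages sum to 100 and enrichment divides by length", {
  rm <- smallSim()
  rmap <- buildRegionMap(rm$sim$annotation)
  ps <- smallBtzPeaks()
  dist <- regionDistribution(ps, rmap)
  expect_equal(sum(dist$pct), 100, tolerance = 1e-9)
  expect_equal(dist$enrichment, dist$n_peaks / dist$cumulative_length)
  # EJC peaks sit overwhelmingly in exonic (mostly ORF) territory
  expect_equal(dist$region[which.max(dist$n_peaks)], "orf")
})

test_that("PTB-like peaks concentrate in introns", {
  s <- smallSim()
  ptb <- dedupUmis(simulateIclip(s$cfg, s$sim, "PTB"), "PTB")
  ps <- callPeaks(ptb, s$sim$annotation, pipelineParams(rng_seed = 101L),
                  protein = "PTB")
  rmap <- buildRegionMap(s$sim$annotation)
  dist <- regionDistribution(ps, rmap)
  expect_equal(dist$region[which.max(dist$pct)], "intron")
})

test_that("hand-built region enrichment arithmetic", {
  # 10 peaks in a 1,000 nt ORF vs 10 peaks in a 10,000 nt 3' UTR
  ann <- makeAnnotation(list(
    t1 = list(gene = "g1", strand = "+", exons = list(c(1L, 12000L)),
              cds = c(501L, 1500L))), chromLen = 20000L)
  rmap <- buildRegionMap(ann)
  mk <- function(pos) {
    g <- GRanges(rep("chr1", length(pos)), IRanges(pos, pos), strand = "+")
    S4Vectors::mcols(g)$summit <- pos - 1L
    g
  }
  pk <- mk(c(seq(600L, by = 10L, length.out = 10L),
             seq(2000L, by = 900L, length.out = 10L)))
  dist <- regionDistribution(pk, rmap)
  expect_equal(dist$enrichment[dist$region == "orf"], 10 / 1000)
  expect_equal(dist$enrichment[dist$region == "three_prime_utr"], 10 / 10500)
})

test_that("strand mirroring leaves exon profiles unchanged", {
  exon <- GRanges("chr1", IRanges(101L, 300L), strand = "+")
  tr <- makeTrack(data.frame(pos = c(120L, 280L), count = c(2L, 5L)))
  p1 <- exonMetaprofile(tr, exon, pipelineParams(), scale_rpm = FALSE)
  # mirror: flip coordinates around the chromosome midpoint and the strand
  L <- 1000L
  exonM <- GRanges("chr1", IRanges(L + 1L - 300L, L + 1L - 101L),
                   strand = "-")
  trM <- makeTrack(data.frame(pos = L + 1L - c(120L, 280L),
                              count = c(2L, 5L), strand = "-"))
  p2 <- exonMetaprofile(trM, exonM, pipelineParams(), scale_rpm = FALSE)
  expect_equal(p2$mean, p1$mean)
})
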
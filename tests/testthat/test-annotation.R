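test_that("GTF import converts 1-based inclusive to internal intervals and groups transcripts", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\tgene\t101\t300\t.\t+\t.\tgene_id "g1"; gene_biotype "protein_coding";',
    'chr1\tsrc\ttranscript\t101\t300\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t251\t300\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\ttranscript\t101\t300\t.\t+\t.\tgene_id "g1"; transcript_id "t2";',
    'chr1\tsrc\texon\t101\t300\t.\t+\t.\tgene_id "g1"; transcript_id "t2";'
  ), gtf)
  ann <- readGTF(gtf, chromLengths = c(chr1 = 1000L))
  expect_equal(length(genes(ann)), 1L)
  expect_equal(nrow(transcriptTable(ann)), 2L)
  e <- exonsByTranscript(ann)[["t1"]]
  # GTF 101-200 is 0-based half-open [100, 200)
  expect_equal(start(e) - 1L, c(100L, 250L))
  expect_equal(end(e), c(200L, 300L))
})

test_that("GTF round trip reproduces intervals field by field", {
  s <- smallSim()
  gtf <- tempfile(fileext = ".gtf")
  writeGTF(s$sim$annotation, gtf)
  sl <- GenomeInfoDb::seqlengths(genes(s$sim$annotation))
  ann2 <- readGTF(gtf, chromLengths = sl)
  a1 <- s$sim$annotation
  expect_setequal(mcols(genes(ann2))$gene_id, mcols(genes(a1))$gene_id)
  for (tid in transcriptTable(a1)$transcript_id) {
    e1 <- exonsByTranscript(a1)[[tid]]
    e2 <- exonsByTranscript(ann2)[[tid]]
    expect_equal(start(e1), start(e2), info = tid)
    expect_equal(end(e1), end(e2), info = tid)
    expect_equal(as.character(strand(e1)), as.character(strand(e2)))
  }
  expect_equal(sort(names(cdsSpans(a1))), sort(names(cdsSpans(ann2))))
  for (tid in names(cdsSpans(a1))) {
    expect_equal(start(cdsSpans(a1)[tid]), start(cdsSpans(ann2)[tid]))
    expect_equal(end(cdsSpans(a1)[tid]), end(cdsSpans(ann2)[tid]))
  }
})

test_that("malformed GTF records raise a parse error naming the line", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    "chr1\tbroken line"
  ), gtf)
  expect_error(readGTF(gtf, chromLengths = c(chr1 = 1000L)), "line 2")
})

test_that("exons beyond chromosome bounds fail validation", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(
    'chr1\tsrc\texon\t101\t1200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    gtf)
  expect_error(readGTF(gtf, chromLengths = c(chr1 = 1000L)), "bounds")
})

test_that("region map labels the hand-enumerated single-transcript example", {
  # transcript exons [0,100) and [200,300), CDS [50,250) (0-based half-open)
  ann <- makeAnnotation(list(
    t1 = list(gene = "g1", strand = "+",
              exons = list(c(1L, 100L), c(201L, 300L)),
              cds = c(51L, 250L))))
  rmap <- buildRegionMap(ann)
  probe <- function(pos0) {
    regionOfPositions(rmap, GRanges("chr1", IRanges(pos0 + 1L, pos0 + 1L),
                                    strand = "+"))
  }
  expect_equal(probe(0L), "five_prime_utr")
  expect_equal(probe(49L), "five_prime_utr")
  expect_equal(probe(50L), "orf")
  expect_equal(probe(99L), "orf")
  expect_equal(probe(100L), "intron")
  expect_equal(probe(199L), "intron")
  expect_equal(probe(200L), "orf")
  expect_equal(probe(249L), "orf")
  expect_equal(probe(250L), "three_prime_utr")
  expect_equal(probe(299L), "three_prime_utr")
  lens <- cumulativeRegionLengths(rmap)
  expect_equal(unname(lens[["orf"]]), 100)
  expect_equal(unname(lens[["five_prime_utr"]]), 50)
  expect_equal(unname(lens[["three_prime_utr"]]), 50)
  expect_equal(unname(lens[["intron"]]), 100)
  expect_equal(unname(lens[["intergenic"]]), 2 * 1000 - 300)
  # antisense strand of the gene is intergenic
  expect_equal(regionOfPositions(rmap, GRanges("chr1", IRanges(60, 60),
                                               strand = "-")), "intergenic")
})

test_that("empty annotation maps everything to intergenic", {
  si <- GenomeInfoDb::Seqinfo("chr1", seqlengths = 1000L)
  g <- GRanges(seqinfo = si)
  mcols(g)$gene_id <- character(0); mcols(g)$biotype <- character(0)
  ann <- new("GenomeAnnotation", genes = g,
             transcripts = data.frame(transcript_id = character(0),
                                      gene_id = character(0)),
             exonsByTx = GRangesList(), cdsByTx = GRanges(seqinfo = si))
  lens <- cumulativeRegionLengths(buildRegionMap(ann))
  expect_equal(unname(lens[["intergenic"]]), 2000)
  expect_equal(sum(lens[names(lens) != "intergenic"]), 0)
})

test_that("ORF precedence wins over intron across overlapping isoforms", {
  ann <- makeAnnotation(list(
    t1 = list(gene = "g1", strand = "+",
              exons = list(c(1L, 100L), c(201L, 300L)), cds = c(51L, 250L)),
    t2 = list(gene = "g1", strand = "+",
              exons = list(c(1L, 300L)), cds = c(51L, 250L))))
  rmap <- buildRegionMap(ann)
  # position 150 (1-based) is intronic in t1 but CDS-exonic in t2
  expect_equal(regionOfPositions(rmap, GRanges("chr1", IRanges(150, 150),
                                               strand = "+")), "orf")
})

test_that("region lengths partition both strands for simulated annotations", {
  s <- smallSim()
  rmap <- buildRegionMap(s$sim$annotation)
  lens <- cumulativeRegionLengths(rmap)
  G <- sum(as.numeric(GenomeInfoDb::seqlengths(genes(s$sim$annotation))))
  expect_equal(sum(lens), 2 * G)
  expect_true(all(lens >= 0))
})

test_that("exon categories follow the isoform rule table", {
  # T1 = A,B,C and T2 = A,C with identical A and C
  ann <- makeAnnotation(list(
    T1 = list(gene = "g1", strand = "+",
              exons = list(c(1L, 100L), c(201L, 300L), c(401L, 500L)),
              cds = c(51L, 450L)),
    T2 = list(gene = "g1", strand = "+",
              exons = list(c(1L, 100L), c(401L, 500L)), cds = c(51L, 450L))))
  cat <- classifyExons(ann)
  getCat <- function(s1) mcols(cat)$category[start(cat) == s1]
  expect_equal(getCat(1L), "five_prime_terminal")
  expect_equal(getCat(201L), "variant")
  expect_equal(getCat(401L), "three_prime_terminal")
})

test_that("a varying donor boundary gives alt_donor on both forms", {
  # internal exon [200,300) in T1 vs [200,320) in T2 (plus strand):
  # acceptors identical, donors differ
  ann <- makeAnnotation(list(
    T1 = list(gene = "g1", strand = "+",
              exons = list(c(1L, 100L), c(201L, 300L), c(401L, 500L)),
              cds = c(51L, 450L)),
    T2 = list(gene = "g1", strand = "+",
              exons = list(c(1L, 100L), c(201L, 320L), c(401L, 500L)),
              cds = c(51L, 450L))))
  cat <- classifyExons(ann)
  alt <- cat[start(cat) == 201L]
  expect_equal(length(alt), 2L)
  expect_equal(unique(mcols(alt)$category), "alt_donor")
})

test_that("a varying acceptor on the minus strand is alt_acceptor", {
  # on the minus strand the acceptor is the genomic end boundary
  ann <- makeAnnotation(list(
    T1 = list(gene = "g1", strand = "-",
              exons = list(c(1L, 100L), c(201L, 300L), c(401L, 500L)),
              cds = c(51L, 450L)),
    T2 = list(gene = "g1", strand = "-",
              exons = list(c(1L, 100L), c(201L, 320L), c(401L, 500L)),
              cds = c(51L, 450L))))
  cat <- classifyExons(ann)
  alt <- cat[start(cat) == 201L]
  expect_equal(unique(mcols(alt)$category), "alt_acceptor")
})

test_that("single-isoform internal exons are constitutive and single-exon transcripts 3' terminal", {
  ann <- makeAnnotation(list(
    T1 = list(gene = "g1", strand = "+",
              exons = list(c(1L, 100L), c(201L, 300L), c(401L, 500L)),
              cds = c(51L, 450L)),
    S1 = list(gene = "g2", strand = "+", exons = list(c(601L, 700L)),
              cds = c(621L, 680L))))
  cat <- classifyExons(ann)
  expect_equal(mcols(cat)$category[start(cat) == 201L], "constitutive")
  expect_equal(mcols(cat)$category[start(cat) == 601L],
               "three_prime_terminal")
})

test_that("classification is invariant to transcript input order", {
  mk <- function(order) {
    txs <- list(
      T1 = list(gene = "g1", strand = "+",
                exons = list(c(1L, 100L), c(201L, 300L), c(401L, 500L)),
                cds = c(51L, 450L)),
      T2 = list(gene = "g1", strand = "+",
                exons = list(c(1L, 100L), c(401L, 500L)), cds = c(51L, 450L)))
    classifyExons(makeAnnotation(txs[order]))
  }
  a <- mk(c(1L, 2L)); b <- mk(c(2L, 1L))
  expect_equal(start(a), start(b))
  expect_equal(mcols(a)$category, mcols(b)$category)
})

test_that("constitutive exons appear with identical boundaries in every isoform (brute force)", {
  s <- smallSim()
  ann <- s$sim$annotation
  cat <- classifyExons(ann)
  const <- cat[mcols(cat)$category == "constitutive"]
  tx <- transcriptTable(ann)
  for (i in seq_len(min(length(const), 50L))) {
    gid <- mcols(const)$gene_id[i]
    tids <- tx$transcript_id[tx$gene_id == gid]
    inAll <- vapply(tids, function(t) {
      e <- exonsByTranscript(ann)[[t]]
      any(start(e) == start(const)[i] & end(e) == end(const)[i])
    }, logical(1))
    expect_true(all(inAll), info = paste(gid, start(const)[i]))
  }
})

test_that("junction offsets are measured in transcript orientation", {
  ann <- makeAnnotation(list(
    t1 = list(gene = "g1", strand = "+",
              exons = list(c(1L, 100L), c(201L, 300L)), cds = c(51L, 250L)),
    t2 = list(gene = "g2", strand = "-",
              exons = list(c(401L, 500L), c(601L, 700L)), cds = c(451L, 650L))))
  je <- junctionExonEnds(ann)
  expect_equal(start(je[strand(je) == "+"]), 100L)
  expect_equal(start(je[strand(je) == "-"]), 601L)  # minus: genomic start
  plusPos <- GRanges("chr1", IRanges(80, 80), strand = "+")
  expect_equal(junctionOffsets(plusPos, ann), -20L)
  minusPos <- GRanges("chr1", IRanges(621, 621), strand = "-")
  expect_equal(junctionOffsets(minusPos, ann), -20L)
})
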
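#' @include AllClasses.R
NULL

# All 1,024 5mers in a fixed (lexicographic) order; row order of every
# positional matrix in the package.
allKmers <- function(k = 5L) {
  bases <- c("A", "C", "G", "T")
  do.call(paste0, rev(expand.grid(rep(list(bases), k),
                                  stringsAsFactors = FALSE)))
}

# Map 5mer strings to 1-based indices in allKmers() order via base-4 digits.
# Strings containing characters outside ACGT map to NA.
kmerIndex <- function(kmers, k = 5L) {
  code <- chartr("ACGT", "0123", kmers)
  bad <- grepl("[^0-3]", code)
  idx <- strtoi(code, base = 4L) + 1L
  idx[bad | nchar(kmers) != k] <- NA_integer_
  idx
}

reverseComplement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Derive a child RNG seed from a base seed and a label so that adding one
# library never perturbs the streams of the others. Kept below 2^31.
deriveSeed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(as.character(label)))
    h <- (h * 131 + ch) %% 1977326743
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

# Run an expression under a private RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# 0-based half-open <-> GRanges (1-based closed) converters. The package
# stores intervals as standard GRanges; BED-convention coordinates appear
# only at I/O boundaries and in single-position reports.
grFromBed0 <- function(chrom, start0, end0, strand = "*", seqinfo = NULL) {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start0 + 1L, end0),
                         strand = strand, seqinfo = seqinfo)
}

bed0Start <- function(gr) GenomicRanges::start(gr) - 1L
bed0End <- function(gr) GenomicRanges::end(gr)

#' Construct a crosslink track from positional counts
#'
#' @param library_id library label.
#' @param events width-1 \code{GRanges} with a \code{count} metadata column.
#' @param totalRaw raw event count before deduplication; defaults to the
#'   unique total.
#' @return a \code{\linkS4class{CrosslinkTrack}}.
#' @export
newCrosslinkTrack <- function(library_id, events, totalRaw = NULL) {
  events <- GenomicRanges::sort(events)
  tu <- if (length(events)) sum(S4Vectors::mcols(events)$count) else 0
  methods::new("CrosslinkTrack", library_id = library_id, events = events,
               totalUnique = as.numeric(tu),
               totalRaw = as.numeric(if (is.null(totalRaw)) tu else totalRaw))
}
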
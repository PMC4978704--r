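#' @include AllClasses.R
NULL

#' Accessors for ejclip S4 containers
#'
#' Small accessor generics: slot access stays behind functions so internal
#' representation can evolve.
#'
#' @param x an ejclip S4 object.
#' @return the slot content (see each method).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
#' @rdname accessors
#' @export
setMethod("genes", "GenomeAnnotation", function(x) x@genes)

#' @rdname accessors
#' @export
setGeneric("transcriptTable", function(x) standardGeneric("transcriptTable"))
#' @rdname accessors
#' @export
setMethod("transcriptTable", "GenomeAnnotation", function(x) x@transcripts)

#' @rdname accessors
#' @export
setGeneric("exonsByTranscript", function(x) standardGeneric("exonsByTranscript"))
#' @rdname accessors
#' @export
setMethod("exonsByTranscript", "GenomeAnnotation", function(x) x@exonsByTx)

#' @rdname accessors
#' @export
setGeneric("cdsSpans", function(x) standardGeneric("cdsSpans"))
#' @rdname accessors
#' @export
setMethod("cdsSpans", "GenomeAnnotation", function(x) x@cdsByTx)

#' @rdname accessors
#' @export
setGeneric("regionRanges", function(x) standardGeneric("regionRanges"))
#' @rdname accessors
#' @export
setMethod("regionRanges", "RegionMap", function(x) x@regions)

#' @rdname accessors
#' @export
setGeneric("libraryId", function(x) standardGeneric("libraryId"))
#' @rdname accessors
#' @export
setMethod("libraryId", "CrosslinkTrack", function(x) x@library_id)

#' @rdname accessors
#' @export
setGeneric("eventRanges", function(x) standardGeneric("eventRanges"))
#' @rdname accessors
#' @export
setMethod("eventRanges", "CrosslinkTrack", function(x) x@events)

#' @rdname accessors
#' @export
setGeneric("totalUnique", function(x) standardGeneric("totalUnique"))
#' @rdname accessors
#' @export
setMethod("totalUnique", "CrosslinkTrack", function(x) x@totalUnique)

#' @rdname accessors
#' @export
setGeneric("totalRaw", function(x) standardGeneric("totalRaw"))
#' @rdname accessors
#' @export
setMethod("totalRaw", "CrosslinkTrack", function(x) x@totalRaw)

#' @rdname accessors
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))
#' @rdname accessors
#' @export
setMethod("peaks", "PeakSet", function(x) x@peaks)

#' @rdname accessors
#' @export
setGeneric("proteinName", function(x) standardGeneric("proteinName"))
#' @rdname accessors
#' @export
setMethod("proteinName", "PeakSet", function(x) x@protein)

#' @rdname accessors
#' @export
setGeneric("kmerStats", function(x) standardGeneric("kmerStats"))
#' @rdname accessors
#' @export
setMethod("kmerStats", "KmerProfileSet", function(x) x@stats)

#' @rdname accessors
#' @export
setGeneric("positionalMatrix", function(x, normalized = FALSE)
  standardGeneric("positionalMatrix"))
#' @rdname accessors
#' @param normalized return the null-normalized matrix instead of raw counts.
#' @export
setMethod("positionalMatrix", "KmerProfileSet", function(x, normalized = FALSE) {
  if (normalized) x@normalized else x@positional
})

#' @rdname accessors
#' @export
setGeneric("kmerOffsets", function(x) standardGeneric("kmerOffsets"))
#' @rdname accessors
#' @export
setMethod("kmerOffsets", "KmerProfileSet", function(x) x@offsets)
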
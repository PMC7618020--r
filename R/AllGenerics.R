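#' Accessors for MEG containers
#'
#' Small accessor generics for [MegRecording-class] and [EpochSet-class]
#' objects; prefer these over direct slot access.
#'
#' @param object a [MegRecording-class] or [EpochSet-class].
#' @return \code{sfreq}: sampling rate in Hz; \code{nChannels},
#'   \code{nSamples}, \code{nEpochs}: counts; \code{channelNames}: character
#'   vector; \code{recData}: the raw numeric matrix / array;
#'   \code{keptMask}: logical per-epoch flags; \code{rejectionLog}: per-epoch
#'   diagnostics data.frame.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sfreq", function(object) standardGeneric("sfreq"))

#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("recData", function(object) standardGeneric("recData"))

#' @rdname accessors
#' @export
setGeneric("nEpochs", function(object) standardGeneric("nEpochs"))

#' @rdname accessors
#' @export
setGeneric("keptMask", function(object) standardGeneric("keptMask"))

#' @rdname accessors
#' @export
setGeneric("rejectionLog", function(object) standardGeneric("rejectionLog"))

## MegRecording methods -------------------------------------------------------

#' @rdname accessors
setMethod("sfreq", "MegRecording", function(object) object@sfreq)

#' @rdname accessors
setMethod("nChannels", "MegRecording", function(object) nrow(object@data))

#' @rdname accessors
setMethod("nSamples", "MegRecording", function(object) ncol(object@data))

#' @rdname accessors
setMethod("channelNames", "MegRecording", function(object) object@channelNames)

#' @rdname accessors
setMethod("recData", "MegRecording", function(object) object@data)

setMethod("show", "MegRecording", function(object) {
  cat(sprintf(
    "MegRecording: %d channels x %d samples @ %g Hz (%.1f s)\n",
    nChannels(object), nSamples(object), sfreq(object),
    nSamples(object) / sfreq(object)))
  cat(sprintf("  channel types: %s\n",
              paste(unique(object@channelTypes), collapse = ", ")))
})

## EpochSet methods -----------------------------------------------------------

#' @rdname accessors
setMethod("sfreq", "EpochSet", function(object) object@sfreq)

#' @rdname accessors
setMethod("nEpochs", "EpochSet", function(object) dim(object@epochs)[1L])

#' @rdname accessors
setMethod("nChannels", "EpochSet", function(object) dim(object@epochs)[2L])

#' @rdname accessors
setMethod("nSamples", "EpochSet", function(object) dim(object@epochs)[3L])

#' @rdname accessors
setMethod("channelNames", "EpochSet", function(object) object@channelNames)

#' @rdname accessors
setMethod("recData", "EpochSet", function(object) object@epochs)

#' @rdname accessors
setMethod("keptMask", "EpochSet", function(object) object@keptMask)

#' @rdname accessors
setMethod("rejectionLog", "EpochSet", function(object) object@rejectionLog)

setMethod("show", "EpochSet", function(object) {
  cat(sprintf(
    "EpochSet: %d epochs (%d kept) x %d channels x %d samples @ %g Hz\n",
    nEpochs(object), sum(object@keptMask), nChannels(object),
    nSamples(object), sfreq(object)))
})
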
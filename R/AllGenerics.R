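# Accessors and show methods.

#' @rdname SensorChunk-class
#' @param object,x A `SensorChunk`.
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))
#' @rdname SensorChunk-class
#' @export
setMethod("modality", "SensorChunk", function(x) x@modality)

#' @rdname SensorChunk-class
#' @export
setGeneric("startUTC", function(x) standardGeneric("startUTC"))
#' @rdname SensorChunk-class
#' @export
setMethod("startUTC", "SensorChunk", function(x) x@startUTC)

#' @rdname SensorChunk-class
#' @export
setGeneric("endUTC", function(x) standardGeneric("endUTC"))
#' @rdname SensorChunk-class
#' @export
setMethod("endUTC", "SensorChunk", function(x) x@endUTC)

#' @rdname SensorChunk-class
#' @export
setGeneric("chunkSamples", function(x) standardGeneric("chunkSamples"))
#' @rdname SensorChunk-class
#' @export
setMethod("chunkSamples", "SensorChunk", function(x) x@samples)

#' @rdname SensorChunk-class
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))
#' @rdname SensorChunk-class
#' @export
setMethod("missingMask", "SensorChunk", function(x) x@missingMask)

#' Number of samples held by a chunk
#' @param x A `SensorChunk`.
#' @return Integer sample (row) count.
#' @export
chunkLength <- function(x) {
  s <- if (methods::is(x, "SensorChunk")) x@samples else x
  if (is.matrix(s)) nrow(s) else length(s)
}

setMethod("show", "SensorChunk", function(object) {
  cat(sprintf("SensorChunk [%s] %d samples @ %g Hz, %.2f s, %d padded\n",
              object@modality, chunkLength(object), object@nominalRate,
              (object@endUTC - object@startUTC) / 1000,
              sum(object@missingMask)))
})

#' @rdname Recording-class
#' @param x A `Recording`.
#' @param modality Optional modality filter.
#' @export
setGeneric("chunks", function(x, modality = NULL) standardGeneric("chunks"))
#' @rdname Recording-class
#' @export
setMethod("chunks", "Recording", function(x, modality = NULL) {
  if (is.null(modality)) x@chunks
  else Filter(function(c) c@modality == modality, x@chunks)
})

#' @rdname Recording-class
#' @export
setGeneric("firmwareVersion", function(x) standardGeneric("firmwareVersion"))
#' @rdname Recording-class
#' @export
setMethod("firmwareVersion", "Recording", function(x) x@firmwareVersion)

#' @rdname Recording-class
#' @export
setGeneric("deviceId", function(x) standardGeneric("deviceId"))
#' @rdname Recording-class
#' @export
setMethod("deviceId", "Recording", function(x) x@deviceId)

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording <%s> firmware %s\n", object@deviceId,
              object@firmwareVersion))
  for (m in MODALITIES) {
    ch <- chunks(object, m)
    if (length(ch))
      cat(sprintf("  %-5s %d chunks, %d samples\n", m, length(ch),
                  sum(vapply(ch, chunkLength, 1L))))
  }
})

#' @rdname IBISeries-class
#' @param x An `IBISeries`.
#' @export
setGeneric("beatTimes", function(x) standardGeneric("beatTimes"))
#' @rdname IBISeries-class
#' @export
setMethod("beatTimes", "IBISeries", function(x) x@beatTimes)

#' @rdname IBISeries-class
#' @export
setGeneric("ibiMs", function(x) standardGeneric("ibiMs"))
#' @rdname IBISeries-class
#' @export
setMethod("ibiMs", "IBISeries", function(x) x@ibiMs)

#' @rdname IBISeries-class
#' @export
setGeneric("ibiFlags", function(x) standardGeneric("ibiFlags"))
#' @rdname IBISeries-class
#' @export
setMethod("ibiFlags", "IBISeries", function(x) x@flags)

#' @rdname IBISeries-class
#' @export
setGeneric("ibiSession", function(x) standardGeneric("ibiSession"))
#' @rdname IBISeries-class
#' @export
setMethod("ibiSession", "IBISeries", function(x) x@session)

#' @rdname IBISeries-class
#' @export
setGeneric("editedFraction", function(x) standardGeneric("editedFraction"))
#' @rdname IBISeries-class
#' @export
setMethod("editedFraction", "IBISeries", function(x) x@editedFraction)

#' @rdname IBISeries-class
#' @export
setGeneric("isUnusable", function(x) standardGeneric("isUnusable"))
#' @rdname IBISeries-class
#' @export
setMethod("isUnusable", "IBISeries", function(x) x@unusable)

setMethod("show", "IBISeries", function(object) {
  n <- length(object@ibiMs)
  cat(sprintf("IBISeries: %d intervals over %.1f s", n,
              if (n) diff(range(object@beatTimes)) else 0))
  if (object@editedFraction > 0)
    cat(sprintf(", %.1f%% edited", 100 * object@editedFraction))
  if (object@unusable) cat(" [UNUSABLE]")
  cat("\n")
  if (n) {
    tb <- table(object@flags)
    cat("  flags:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  }
})

#' @rdname RSAResult-class
#' @param x An `RSAResult`.
#' @export
setGeneric("epochValues", function(x) standardGeneric("epochValues"))
#' @rdname RSAResult-class
#' @export
setMethod("epochValues", "RSAResult", function(x) x@epochValues)

#' @rdname RSAResult-class
#' @export
setGeneric("taskMean", function(x) standardGeneric("taskMean"))
#' @rdname RSAResult-class
#' @export
setMethod("taskMean", "RSAResult", function(x) x@taskMean)

#' @rdname RSAResult-class
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))
#' @rdname RSAResult-class
#' @export
setMethod("nEpochs", "RSAResult", function(x) x@nEpochs)

setMethod("show", "RSAResult", function(object) {
  cat(sprintf("RSAResult: task mean %.3f ln(ms^2) over %d epochs (band %.2f-%.2f Hz)\n",
              object@taskMean, object@nEpochs, object@band[1], object@band[2]))
})
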
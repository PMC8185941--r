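#' @name accessors
#' @title Accessors for PDL1score classes
#'
#' @description Slot accessors: `annotations()` returns the ground-truth
#' point annotations of a synthetic tile; `regionMask()` its region label
#' mask; `truthScore()` its exact [SlideScore-class]; `maskLabels()` and
#' `scaleFactor()` the label matrix and scale of a [RegionMask-class];
#' `tps()`, `ips()`, `category()`, `cellCounts()` the clinical quantities
#' of a [SlideScore-class]; `icc()` and `kappas()` the reliability
#' statistics of a [ConcordanceReport-class].
#'
#' @param object an object of the documented class.
#' @return the corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("annotations", function(object) standardGeneric("annotations"))
#' @rdname accessors
#' @export
setGeneric("regionMask", function(object) standardGeneric("regionMask"))
#' @rdname accessors
#' @export
setGeneric("truthScore", function(object) standardGeneric("truthScore"))
#' @rdname accessors
#' @export
setGeneric("maskLabels", function(object) standardGeneric("maskLabels"))
#' @rdname accessors
#' @export
setGeneric("scaleFactor", function(object) standardGeneric("scaleFactor"))
#' @rdname accessors
#' @export
setGeneric("tps", function(object) standardGeneric("tps"))
#' @rdname accessors
#' @export
setGeneric("ips", function(object) standardGeneric("ips"))
#' @rdname accessors
#' @export
setGeneric("category", function(object) standardGeneric("category"))
#' @rdname accessors
#' @export
setGeneric("cellCounts", function(object) standardGeneric("cellCounts"))
#' @rdname accessors
#' @export
setGeneric("icc", function(object) standardGeneric("icc"))
#' @rdname accessors
#' @export
setGeneric("kappas", function(object) standardGeneric("kappas"))

#' @rdname accessors
setMethod("annotations", "SynthTile", function(object) object@annotations)
#' @rdname accessors
setMethod("regionMask", "SynthTile", function(object) object@regionMask)
#' @rdname accessors
setMethod("truthScore", "SynthTile", function(object) object@truth)
#' @rdname accessors
setMethod("maskLabels", "RegionMask", function(object) object@labels)
#' @rdname accessors
setMethod("scaleFactor", "RegionMask", function(object) object@scaleFactor)
#' @rdname accessors
setMethod("tps", "SlideScore", function(object) object@tps)
#' @rdname accessors
setMethod("ips", "SlideScore", function(object) object@ips)
#' @rdname accessors
setMethod("category", "SlideScore", function(object) object@category)
#' @rdname accessors
setMethod("cellCounts", "SlideScore", function(object) {
  c(nTCPos = object@nTCPos, nTCNeg = object@nTCNeg,
    nIC = object@nIC, nICPos = object@nICPos)
})
#' @rdname accessors
setMethod("icc", "ConcordanceReport", function(object) object@icc)
#' @rdname accessors
setMethod("kappas", "ConcordanceReport", function(object) object@kappa)

setMethod("show", "SlideScore", function(object) {
  cat("SlideScore\n")
  cat(sprintf("  TC(+): %d  TC(-): %d  IC: %d (PD-L1+: %d)\n",
              object@nTCPos, object@nTCNeg, object@nIC, object@nICPos))
  if (object@amenable) {
    cat(sprintf("  TPS: %.2f%%  category: %s\n", object@tps, object@category))
  } else {
    cat("  TPS: not amenable (no tumor cells)\n")
  }
  if (is.na(object@ips)) cat("  IPS: undefined (no intratumoral ICs)\n")
  else cat(sprintf("  IPS: %.2f%%\n", object@ips))
})

setMethod("show", "SynthTile", function(object) {
  d <- dim(object@image)
  cat(sprintf("SynthTile %d x %d px, %d annotated cells\n",
              d[2], d[1], nrow(object@annotations)))
  tab <- table(factor(object@annotations$cls, levels = CELL_CLASSES))
  cat("  ", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  cat(sprintf("  planned TPS %.1f / realized %.2f\n",
              object@spec@plannedTPS,
              if (object@truth@amenable) object@truth@tps else NA_real_))
})

setMethod("show", "RegionMask", function(object) {
  tab <- table(factor(object@labels, levels = REGION_LABELS,
                      labels = names(REGION_LABELS)))
  cat(sprintf("RegionMask %d x %d (scale factor %g)\n",
              ncol(object@labels), nrow(object@labels), object@scaleFactor))
  print(round(tab / length(object@labels), 3))
})

setMethod("show", "IHCNet", function(object) {
  np <- sum(vapply(object@weights, length, 1L))
  cat(sprintf("IHCNet <%s>: %d classes, base width %d, depth %d, %d parameters%s\n",
              object@kind, object@config$nClasses, object@config$baseWidth,
              object@config$depth, np,
              if (object@trained) " (trained)" else " (untrained)"))
})

setMethod("show", "ConcordanceReport", function(object) {
  cat(sprintf("ConcordanceReport (n = %d)\n", object@n))
  cat(sprintf("  ICC(2,1): %.3f [%.3f, %.3f]\n",
              object@icc, object@iccCI[1], object@iccCI[2]))
  cat(sprintf("  Pearson: %.3f  Spearman: %.3f\n",
              object@pearson, object@spearman))
  cat("  Fleiss' kappa by cutoff:\n")
  for (nm in names(object@kappa))
    cat(sprintf("    >= %s%%: %.3f\n", nm, object@kappa[[nm]]))
})
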
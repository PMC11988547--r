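#' @title Accessor generics
#' @description Accessors for the package's S4 containers.
#' @param object an S4 object from this package.
#' @param ... passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("patients", function(object, ...) standardGeneric("patients"))

#' @rdname accessors
#' @export
setGeneric("measures", function(object, ...) standardGeneric("measures"))

#' @rdname accessors
#' @export
setGeneric("keptNuclei", function(object, ...) standardGeneric("keptNuclei"))

#' @rdname accessors
#' @export
setGeneric("labelMatrix", function(object, ...) standardGeneric("labelMatrix"))

#' @rdname accessors
#' @export
setGeneric("designMatrix", function(object, ...) standardGeneric("designMatrix"))

#' @rdname accessors
#' @export
setGeneric("taskLabels", function(object, ...) standardGeneric("taskLabels"))

#' @rdname accessors
#' @export
setGeneric("partition", function(object, ...) standardGeneric("partition"))

#' @rdname accessors
#' @export
setGeneric("lossHistory", function(object, ...) standardGeneric("lossHistory"))

#' @rdname accessors
#' @export
setGeneric("evalResults", function(object, ...) standardGeneric("evalResults"))

## Methods --------------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("patients", "SyntheticCohort", function(object, ...) object@patients)

#' @rdname accessors
#' @export
setMethod("measures", "NucleusSet", function(object, ...) object@measures)

#' @rdname accessors
#' @export
setMethod("keptNuclei", "NucleusSet", function(object, ...) {
  if (anyNA(object@kept)) {
    validationError("instances have not been filtered yet; run filterInstances()")
  }
  object@measures[object@kept, , drop = FALSE]
})

#' @rdname accessors
#' @export
setMethod("labelMatrix", "NucleusSet", function(object, ...) object@labels)

#' @rdname accessors
#' @param subset optional partition name ("train", "validation", "test").
#' @export
setMethod("designMatrix", "AssembledDataset", function(object, subset = NULL, ...) {
  d <- object@data
  if (!is.null(subset)) {
    d <- d[object@partition[d$patient_id] == subset, , drop = FALSE]
  }
  as.matrix(d[, object@featureColumns, drop = FALSE])
})

#' @rdname accessors
#' @export
setMethod("taskLabels", "AssembledDataset", function(object, subset = NULL, ...) {
  d <- object@data
  if (!is.null(subset)) {
    d <- d[object@partition[d$patient_id] == subset, , drop = FALSE]
  }
  d$.label
})

#' @rdname accessors
#' @export
setMethod("partition", "AssembledDataset", function(object, ...) object@partition)

#' @rdname accessors
#' @export
setMethod("lossHistory", "UNetSegmenter", function(object, ...) object@lossHistory)

#' @rdname accessors
#' @export
setMethod("evalResults", "EvalReport", function(object, ...) object@results)

## show -----------------------------------------------------------------------

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", object@nPatientsClass1, "LUAD +",
      object@nPatientsClass2, "LUSC patients\n")
  cat("  nuclei/patient ~ NB(mean =", object@nucleiMean,
      ", size =", object@nucleiDispersion, "), tile", object@tileSize, "px\n")
  cat("  class effects:",
      paste(names(object@classEffect), signif(object@classEffect, 3),
            sep = "=", collapse = ", "), "\n")
  cat("  genes:", length(object@genes), "; seed:", object@seed, "\n")
})

setMethod("show", "SyntheticCohort", function(object) {
  tab <- table(object@patients$subtype)
  cat("SyntheticCohort:", nrow(object@patients), "patients (",
      paste(names(tab), tab, sep = ":", collapse = ", "), ")\n")
  cat("  gene tables:", nrow(object@cnv), "genes x", ncol(object@cnv),
      "patients (cnv, snv, expression)\n")
})

setMethod("show", "NucleusSet", function(object) {
  cat("NucleusSet", object@tileId, "with", nrow(object@measures), "instances\n")
  if (!anyNA(object@kept)) {
    cat("  kept:", sum(object@kept), "| area thr:",
        signif(object@areaThreshold, 4), "| compactness thr:",
        signif(object@compactnessThreshold, 4), "\n")
  }
})

setMethod("show", "UNetSegmenter", function(object) {
  cfg <- object@config
  cat("UNetSegmenter: depth", cfg$depth, ", base channels", cfg$baseChannels, "\n")
  if (length(object@lossHistory)) {
    cat("  trained", length(object@lossHistory), "epochs; final loss",
        signif(tail(object@lossHistory, 1), 4), "\n")
  } else cat("  untrained\n")
})

setMethod("show", "AssembledDataset", function(object) {
  cat("AssembledDataset task =", object@task, ":", nrow(object@data), "rows,",
      length(object@featureColumns), "factor columns\n")
  cat("  patients:", length(object@partition), "(",
      paste(names(table(object@partition)), table(object@partition),
            sep = ":", collapse = ", "), ")\n")
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport task =", object@task, "\n")
  for (nm in names(object@results)) {
    r <- object@results[[nm]]
    if (is.null(r$metrics)) {
      cat(sprintf("  %-12s skipped: %s\n", nm, r$reason))
    } else {
      cat(sprintf("  %-12s acc %.4f  auc %.4f  f1 %.4f  (%.2fs fit)\n", nm,
                  r$metrics$accuracy, r$auc, r$metrics$f1, r$duration))
    }
  }
})

#' @importFrom utils tail
NULL
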
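#' The 27-gene NSCLC panel
#'
#' Gene symbols for the copy-number, somatic-variant and expression factor
#' tables: the genes recurrently mutated in both lung adenocarcinoma (LUAD)
#' and lung squamous cell carcinoma (LUSC) that the factor system is built
#' around. The default CNV factor panel uses the first 15 of these and the
#' default mRNA panel the first 26; both panels are arguments of
#' [assembleDataset()].
#'
#' @return Character vector of 27 HGNC symbols.
#' @export
#' @examples
#' nucleoGenePanel()
nucleoGenePanel <- function() {
  c("TP53", "MUC16", "CSMD3", "LRP1B", "FAT3", "KEAP1", "CDH10", "FAT4",
    "FAM135B", "CNTNAP2", "CTNND2", "CTNNA2", "FAT1", "KRAS", "PTPRD",
    "STK11", "SETBP1", "FAM47C", "ZNF521", "COL3A1", "KMT2D", "CDKN2A",
    "NFE2L2", "PIK3CA", "KMT2C", "PTEN", "NF1")
}

#' Names of the 20 per-nucleus features
#'
#' Fixed column order of the nuclear feature table: six color statistics
#' (per-channel mean and population variance inside the nucleus), twelve
#' morphology descriptors (area, perimeter, circularity, compactness,
#' eccentricity and the seven Hu moment invariants) and two wavelet texture
#' statistics (mean and population variance of the diagonal detail subband).
#'
#' @return Character vector of length 20.
#' @export
nuclearFeatureNames <- function() {
  c("R_average", "G_average", "B_average", "R_var", "G_var", "B_var",
    "Area", "Perimeter", "Circularity", "Compactness", "Eccentric",
    paste0("Hu", 0:6), "cD_average", "cD_var")
}

## CohortSpec -----------------------------------------------------------------

#' @rdname cohortSpec
#' @export
setClass("CohortSpec", representation(
  nPatientsClass1 = "integer",
  nPatientsClass2 = "integer",
  nucleiMean = "numeric",
  nucleiDispersion = "numeric",
  tileSize = "integer",
  classEffect = "numeric",
  plantedGenes = "character",
  survivalRate = "numeric",
  censoringRate = "numeric",
  noiseSD = "numeric",
  stainShift = "numeric",
  genes = "character",
  seed = "integer"
))

setValidity("CohortSpec", function(object) {
  msgs <- character()
  if (object@nPatientsClass1 < 1L || object@nPatientsClass2 < 1L) {
    msgs <- c(msgs, "patient counts must be positive")
  }
  if (object@tileSize < 64L) msgs <- c(msgs, "tileSize must be >= 64")
  if (object@censoringRate < 0 || object@censoringRate > 1) {
    msgs <- c(msgs, "censoringRate must lie in [0, 1]")
  }
  if (object@nucleiMean <= 0 || object@nucleiDispersion <= 0) {
    msgs <- c(msgs, "nuclei-per-patient distribution parameters must be positive")
  }
  if (length(object@survivalRate) != 2L || any(object@survivalRate <= 0)) {
    msgs <- c(msgs, "survivalRate must be two positive per-class event rates")
  }
  needed <- c("area", "eccentricity", "color", "expression")
  if (!all(needed %in% names(object@classEffect))) {
    msgs <- c(msgs, paste("classEffect must name:", paste(needed, collapse = ", ")))
  }
  if (!all(object@plantedGenes %in% object@genes)) {
    msgs <- c(msgs, "plantedGenes must be a subset of genes")
  }
  if (length(msgs)) msgs else TRUE
})

## SyntheticCohort ------------------------------------------------------------

#' @rdname generateCohort
#' @export
setClass("SyntheticCohort", representation(
  patients = "data.frame",
  cnv = "matrix",
  snv = "matrix",
  expression = "matrix",
  spec = "CohortSpec"
))

setValidity("SyntheticCohort", function(object) {
  n <- nrow(object@patients)
  for (nm in c("cnv", "snv", "expression")) {
    m <- slot(object, nm)
    if (ncol(m) != n) return(sprintf("%s must have one column per patient", nm))
    if (!identical(rownames(m), object@spec@genes)) {
      return(sprintf("%s rows must cover the configured gene list", nm))
    }
  }
  if (any(object@patients$osTime < 0)) return("osTime must be >= 0")
  TRUE
})

## NucleusSet -----------------------------------------------------------------

#' Per-tile nucleus instances
#'
#' Container for the labeled nucleus instances of one tile: the integer
#' label matrix (0 = background) plus a per-instance measurement table with
#' area \eqn{A} (pixel count), perimeter \eqn{P} (outer-boundary polygon arc
#' length, diagonal steps \eqn{\sqrt 2}) and compactness \eqn{C = P^2/A}.
#' [filterInstances()] fills the `kept` flags and the adaptive thresholds.
#'
#' @slot tileId character tile identifier.
#' @slot labels integer label matrix aligned to the tile.
#' @slot measures data.frame with columns label, area, perimeter, compactness.
#' @slot kept logical per-instance keep flag (NA before filtering).
#' @slot areaThreshold,compactnessThreshold adaptive Otsu thresholds
#'   (NA before filtering or when degenerate).
#' @export
setClass("NucleusSet", representation(
  tileId = "character",
  labels = "matrix",
  measures = "data.frame",
  kept = "logical",
  areaThreshold = "numeric",
  compactnessThreshold = "numeric"
))

setValidity("NucleusSet", function(object) {
  m <- object@measures
  need <- c("label", "area", "perimeter", "compactness")
  if (!all(need %in% names(m))) {
    return("measures must have columns label, area, perimeter, compactness")
  }
  if (nrow(m) && (any(m$area <= 0) || any(m$perimeter <= 0))) {
    return("instance area and perimeter must be positive")
  }
  if (length(object@kept) != nrow(m)) {
    return("kept flags must match the number of instances")
  }
  TRUE
})

## UNetSegmenter --------------------------------------------------------------

#' @rdname trainSegmenter
#' @export
setClass("UNetSegmenter", representation(
  weights = "list",
  config = "list",
  lossHistory = "numeric"
))

## AssembledDataset -----------------------------------------------------------

#' Assembled per-nucleus modeling dataset
#'
#' Per-nucleus rows (nuclear features joined with encoded clinical and
#' genetic patient factors and task labels) balanced to a fixed number of
#' rows per patient, together with a patient-level train/validation/test
#' partition. Built by [assembleDataset()].
#'
#' @slot data data.frame of per-nucleus rows.
#' @slot featureColumns character, the task's design-matrix columns.
#' @slot task one of "subtype", "os1", "os2", "os3".
#' @slot partition named character vector patient id -> partition name.
#' @export
setClass("AssembledDataset", representation(
  data = "data.frame",
  featureColumns = "character",
  task = "character",
  partition = "character"
))

setValidity("AssembledDataset", function(object) {
  if (!all(object@featureColumns %in% names(object@data))) {
    return("featureColumns must be columns of data")
  }
  if (!all(object@data$patient_id %in% names(object@partition))) {
    return("every row's patient must be in the partition")
  }
  if (!all(object@partition %in% c("train", "validation", "test"))) {
    return("partition values must be train/validation/test")
  }
  TRUE
})

## EvalReport -----------------------------------------------------------------

#' @rdname runExperiment
#' @export
setClass("EvalReport", representation(
  task = "character",
  results = "list"
))
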
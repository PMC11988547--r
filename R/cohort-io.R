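## On-disk form of a synthetic cohort: the same plain-text formats the real
## inputs arrive in (clinical TSV, long CNV table, MAF-style SNV TSV,
## gene x patient expression TSV), plus PNG tiles/masks and LabelMe-style
## polygon annotations for the imaging stages, all listed in a manifest.

#' Write a LabelMe-style polygon annotation file
#'
#' @param instances data.frame as returned by [renderTile()] (ellipse
#'   parameters), or a list of polygons (each an n x 2 matrix of x, y
#'   vertex coordinates).
#' @param path output JSON path.
#' @param imagePath image file the annotation refers to.
#' @param height,width image size in pixels.
#' @param vertices polygon vertices used to approximate each ellipse.
#' @return `path`, invisibly.
#' @export
writeLabelMe <- function(instances, path, imagePath = "", height = 0L,
                         width = 0L, vertices = 32L) {
  polys <- if (is.data.frame(instances)) {
    lapply(seq_len(nrow(instances)), function(k) {
      t <- seq(0, 2 * pi, length.out = vertices + 1L)[-(vertices + 1L)]
      a <- instances$a[k]; b <- instances$b[k]; th <- instances$angle[k]
      x <- instances$cx[k] + a * cos(t) * cos(th) - b * sin(t) * sin(th)
      y <- instances$cy[k] + a * cos(t) * sin(th) + b * sin(t) * cos(th)
      cbind(x, y)
    })
  } else instances
  doc <- list(
    version = "5.3.1", flags = structure(list(), names = character()),
    shapes = lapply(polys, function(p) {
      list(label = "nucleus",
           points = lapply(seq_len(nrow(p)), function(i) c(p[i, 1], p[i, 2])),
           group_id = NULL, shape_type = "polygon",
           flags = structure(list(), names = character()))
    }),
    imagePath = imagePath, imageData = NULL,
    imageHeight = height, imageWidth = width
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' Read a LabelMe-style annotation file
#'
#' @param path JSON annotation path.
#' @return List with `polygons` (list of n x 2 matrices of x, y vertices),
#'   `height`, `width`.
#' @export
readLabelMe <- function(path) {
  if (!file.exists(path)) ioError(paste("cannot read annotation:", path))
  doc <- jsonlite::read_json(path)
  polys <- lapply(doc$shapes, function(s) {
    do.call(rbind, lapply(s$points, function(p) c(p[[1]], p[[2]])))
  })
  list(polygons = polys, height = doc$imageHeight %||% 0L,
       width = doc$imageWidth %||% 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a synthetic cohort to disk
#'
#' Writes the four patient tables as TSV (clinical; long-format CNV with
#' per-gene amplitude t; MAF-style SNV with Tumor_Sample_Barcode /
#' Hugo_Symbol / Variant_Classification; gene x patient expression), and
#' optionally renders tiles for the first `renderPatients` patients with
#' their ground-truth masks and LabelMe polygon annotations. A
#' `manifest.tsv` lists every artifact.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if missing).
#' @param renderPatients number of patients to render tiles for.
#' @param nucleiPerTile nuclei per rendered tile.
#' @param tileSize rendered tile side (defaults to the cohort
#'   specification's tile size).
#' @return The manifest as a data.frame, invisibly.
#' @export
writeCohort <- function(cohort, dir, renderPatients = 0L, nucleiPerTile = 20L,
                        tileSize = NULL) {
  if (!is(cohort, "SyntheticCohort")) configError("cohort must be a SyntheticCohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pat <- cohort@patients
  manifest <- list()
  add <- function(kind, file, patient = NA_character_) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      kind = kind, file = file, patient = patient, stringsAsFactors = FALSE)
  }

  clin <- data.frame(
    patient_id = pat$patientId, subtype = ifelse(pat$subtype == 1L, "LUAD", "LUSC"),
    sex = pat$sex, race = pat$race, age_at_diagnosis = pat$ageAtDiagnosis,
    T = pat$tStage, N = pat$nStage, M = pat$mStage, stage = pat$stage,
    os_time = round(pat$osTime, 1), css = pat$css, stringsAsFactors = FALSE)
  f <- file.path(dir, "clinical.tsv")
  write.table(clin, f, sep = "\t", quote = FALSE, row.names = FALSE)
  add("clinical", f)

  cnvLong <- data.frame(
    patient_id = rep(colnames(cohort@cnv), each = nrow(cohort@cnv)),
    gene = rep(rownames(cohort@cnv), ncol(cohort@cnv)),
    t = round(as.vector(cohort@cnv), 4), stringsAsFactors = FALSE)
  f <- file.path(dir, "cnv.tsv")
  write.table(cnvLong, f, sep = "\t", quote = FALSE, row.names = FALSE)
  add("cnv", f)

  mut <- which(!is.na(cohort@snv), arr.ind = TRUE)
  maf <- data.frame(
    Tumor_Sample_Barcode = colnames(cohort@snv)[mut[, 2]],
    Hugo_Symbol = rownames(cohort@snv)[mut[, 1]],
    Variant_Classification = cohort@snv[mut], stringsAsFactors = FALSE)
  f <- file.path(dir, "snv.tsv")
  write.table(maf, f, sep = "\t", quote = FALSE, row.names = FALSE)
  add("snv", f)

  expr <- data.frame(gene = rownames(cohort@expression),
                     round(cohort@expression, 4), check.names = FALSE,
                     stringsAsFactors = FALSE)
  f <- file.path(dir, "mrna.tsv")
  write.table(expr, f, sep = "\t", quote = FALSE, row.names = FALSE)
  add("mrna", f)

  if (renderPatients > 0L) {
    tileDir <- file.path(dir, "tiles")
    dir.create(tileDir, showWarnings = FALSE)
    for (i in seq_len(min(renderPatients, nrow(pat)))) {
      rt <- renderTile(cohort, i, nucleiPerTile,
                       seed = childSeed(cohort@spec@seed, i),
                       tileSize = tileSize)
      id <- pat$patientId[i]
      tf <- file.path(tileDir, paste0(id, "_tile.png"))
      mf <- file.path(tileDir, paste0(id, "_mask.png"))
      jf <- file.path(tileDir, paste0(id, "_tile.json"))
      writeTile(rt$tile, tf)
      png::writePNG(rt$mask + 0, mf)
      writeLabelMe(rt$instances, jf, basename(tf),
                   nrow(rt$mask), ncol(rt$mask))
      add("tile", tf, id); add("mask", mf, id); add("annotation", jf, id)
    }
  }
  man <- do.call(rbind, manifest)
  write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(man)
}
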
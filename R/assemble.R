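## Factor encoding and dataset assembly: clinical string -> integer
## encodings, 1/2/3-year survival labels, CNV amplitude classes, SNV
## synonymy classes, per-patient balancing to a fixed nucleus count, and
## patient-level stratified splitting.

## Clinical encoding vocabularies --------------------------------------------

.clinicalMaps <- list(
  sex = c(male = 1L, female = 2L),
  race = c("unreported" = 0L,
           "american indian or alaska native" = 1L,
           "asian" = 2L,
           "black or african american" = 3L,
           "white" = 4L),
  T = c(t1 = 1L, t2 = 2L, t3 = 3L, t4 = 4L, tx = 5L),
  N = c(n0 = 1L, n1 = 2L, n2 = 3L, n3 = 4L, nx = 5L),
  M = c(m0 = 1L, m1 = 2L, mx = 5L),
  stage = c("stage i" = 1L, "stage ii" = 2L, "stage iii" = 3L,
            "stage iv" = 4L)
)

.encodeOne <- function(values, field) {
  map <- .clinicalMaps[[field]]
  key <- tolower(trimws(as.character(values)))
  out <- unname(map[key])
  if (field == "race") {
    out[is.na(out) | key == "" | is.na(values)] <- 0L  # unreported
  } else if (anyNA(out)) {
    bad <- unique(values[is.na(out)])
    validationError(sprintf("unmapped value(s) in field '%s': %s",
                            field, paste(bad, collapse = ", ")))
  }
  out
}

#' Encode clinical characteristics as integers
#'
#' Applies the fixed string-to-integer vocabulary used throughout the
#' factor system (case-insensitive): sex Male/Female -> 1/2; race
#' Unreported/American Indian or Alaska native/Asian/Black or African
#' American/White -> 0..4 (any unmapped or missing race becomes 0,
#' "Unreported"); T1..T4, TX -> 1..5; N0..N3, NX -> 1..5; M0, M1, MX ->
#' 1, 2, 5; Stage I..IV -> 1..4. An unmapped value in any field other than
#' race is a validation error naming the field and value.
#'
#' @param raw data.frame with (a subset of) columns sex, race, T, N, M,
#'   stage, age_at_diagnosis.
#' @return data.frame with columns Gender, Race, Age_at_diagnosis, T, N,
#'   M, Stage (those present in the input).
#' @export
#' @examples
#' encodeClinical(data.frame(sex = c("Male", "Female"), T = c("T2", "TX")))
encodeClinical <- function(raw) {
  out <- data.frame(row.names = seq_len(nrow(raw)))
  if (!is.null(raw$sex)) out$Gender <- .encodeOne(raw$sex, "sex")
  out$Race <- .encodeOne(if (is.null(raw$race)) rep(NA, nrow(raw)) else raw$race,
                         "race")
  if (!is.null(raw$age_at_diagnosis)) {
    out$Age_at_diagnosis <- as.numeric(raw$age_at_diagnosis)
  }
  for (f in c("T", "N", "M")) {
    if (!is.null(raw[[f]])) out[[f]] <- .encodeOne(raw[[f]], f)
  }
  if (!is.null(raw$stage)) out$Stage <- .encodeOne(raw$stage, "stage")
  out
}

#' Decode encoded clinical integers back to strings
#'
#' Inverse of [encodeClinical()] over the closed vocabularies (used for
#' round-trip checks and reporting).
#'
#' @param field one of "sex", "race", "T", "N", "M", "stage".
#' @param code integer code(s).
#' @return character vector.
#' @export
decodeClinical <- function(field, code) {
  map <- .clinicalMaps[[field]]
  if (is.null(map)) validationError(paste("unknown field:", field))
  names(map)[match(code, map)]
}

#' Survival status label at a horizon
#'
#' Three-class label: 1 = death before the horizon, 2 = survival to the
#' horizon or beyond (whatever the vital status afterwards), 0 = unknown
#' (alive at last follow-up but censored before the horizon).
#'
#' @param css current survival status, "alive" or "dead".
#' @param osTime observed survival time in days (>= 0).
#' @param horizon horizon in days (365 / 730 / 1095 for 1/2/3 years).
#' @return integer vector of 0/1/2.
#' @export
#' @examples
#' survivalLabel(c("dead", "alive", "alive"), c(180, 800, 100), 365)
survivalLabel <- function(css, osTime, horizon) {
  if (any(osTime < 0)) validationError("osTime must be >= 0")
  css <- tolower(css)
  if (!all(css %in% c("alive", "dead"))) {
    validationError("css must be 'alive' or 'dead'")
  }
  ifelse(osTime >= horizon, 2L, ifelse(css == "dead", 1L, 0L))
}

#' Copy-number amplitude class
#'
#' Discretizes a GISTIC-style amplitude t into three classes: 0 for
#' t < 0.1 (copy number close to normal), 1 for 0.1 < t < 0.9 (moderate
#' change), 2 for t > 0.9 (substantial amplification or loss). The
#' boundaries 0.1 and 0.9 are assigned to the lower class (documented tie
#' rule; the defining intervals are open).
#'
#' @param t nonnegative amplitude value(s).
#' @return integer vector of 0/1/2.
#' @export
#' @examples
#' cnvCode(c(0.05, 0.5, 1.2))
cnvCode <- function(t) {
  if (any(t < 0)) validationError("CNV amplitude t must be nonnegative")
  ifelse(t <= 0.1, 0L, ifelse(t <= 0.9, 1L, 2L))
}

.snvNonSyn <- c("Missense", "Nonsense", "Nonstop", "Translation_Start_Site",
                "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del",
                "In_Frame_Ins", "Splice_Site")
.snvSyn <- c("3'UTR", "5'UTR", "3'Flank", "5'Flank", "Silent", "Intron",
             "IGR", "RNA", "Splice region")

#' Somatic-variant synonymy class
#'
#' Maps a variant classification string to 1 (non-synonymous: Missense,
#' Nonsense, Nonstop, Translation_Start_Site, Frame_Shift_Del/Ins,
#' In_Frame_Del/Ins, Splice_Site) or 0 (synonymous: 3'UTR, 5'UTR, 3'Flank,
#' 5'Flank, Silent, Intron, IGR, RNA, Splice region). The vocabulary is
#' closed: any other string (including near-miss spellings such as
#' "Nonsense_Mutation") is a validation error, never silently 0. Unicode
#' prime characters are normalized to ASCII apostrophes.
#'
#' @param variantClassification character vector.
#' @return integer vector of 0/1.
#' @export
#' @examples
#' snvCode(c("Missense", "Silent"))
snvCode <- function(variantClassification) {
  v <- gsub("′", "'", as.character(variantClassification))
  out <- ifelse(v %in% .snvNonSyn, 1L, ifelse(v %in% .snvSyn, 0L, NA_integer_))
  if (anyNA(out)) {
    bad <- unique(v[is.na(out)])
    validationError(paste("unlisted variant classification:",
                          paste(bad, collapse = ", ")))
  }
  out
}

## Balancing and splitting ----------------------------------------------------

#' Balance one patient's nucleus rows to a fixed count
#'
#' Random under-sampling without replacement above the target, random
#' duplication of existing rows below it (every original row is present at
#' least once). Deterministic given `seed`.
#'
#' @param rows data.frame of one patient's per-nucleus rows.
#' @param target target row count (default 200).
#' @param seed integer seed.
#' @return data.frame with exactly `target` rows (input returned unchanged
#'   when it already has `target` rows).
#' @export
balancePatient <- function(rows, target = 200L, seed = 1L) {
  n <- nrow(rows)
  if (n == 0L) {
    warning("patient with zero nucleus rows excluded from balancing")
    return(rows)
  }
  if (n == target) return(rows)
  withSeed(seed, {
    if (n > target) {
      rows[sort(sample.int(n, target)), , drop = FALSE]
    } else {
      extra <- sample.int(n, target - n, replace = TRUE)
      rows[c(seq_len(n), extra), , drop = FALSE]
    }
  })
}

#' Patient-level train/validation/test split
#'
#' Splits patient ids into train/validation/test with no patient in two
#' partitions. With stratification (the default) each subtype stratum is
#' split independently. Within a stratum of size n, the validation and
#' test sets get `floor(f_val * n)` and `floor(f_test * n)` patients and
#' the training set the remainder -- the rule that reproduces the printed
#' 752/250/250 overall and 315/437 per-subtype training counts for a
#' 525 + 727 cohort at 60/20/20.
#'
#' @param patientIds character vector of ids.
#' @param subtype optional parallel vector for stratification.
#' @param fractions train/validation/test fractions summing to 1.
#' @param stratify stratify by subtype (requires `subtype`).
#' @param seed integer seed.
#' @return Named character vector patient id -> "train"/"validation"/"test".
#' @export
#' @examples
#' p <- splitPatients(sprintf("P%04d", 1:1252),
#'                    rep(c(1, 2), c(525, 727)), seed = 1)
#' table(p)
splitPatients <- function(patientIds, subtype = NULL,
                          fractions = c(0.6, 0.2, 0.2),
                          stratify = !is.null(subtype), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) {
    validationError("fractions must sum to 1")
  }
  if (anyDuplicated(patientIds)) validationError("duplicated patient ids")
  strata <- if (stratify) {
    if (is.null(subtype)) validationError("stratify = TRUE needs subtype")
    split(patientIds, subtype)
  } else list(all = patientIds)
  out <- character(0)
  withSeed(seed, {
    for (ids in strata) {
      n <- length(ids)
      if (n < 3L) validationError("each stratum needs at least 3 patients")
      nVal <- floor(fractions[2] * n)
      nTest <- floor(fractions[3] * n)
      ids <- sample(ids)
      lab <- rep("train", n)
      lab[seq_len(nVal)] <- "validation"
      lab[nVal + seq_len(nTest)] <- "test"
      out <- c(out, stats::setNames(lab, ids))
    }
  })
  out[match(patientIds, names(out))]
}

## Table readers ---------------------------------------------------------------

#' Read the patient-level input tables
#'
#' Readers for the four plain-text patient tables: `readClinicalTable()`
#' (one row per patient), `readCnvTable()` (long format: patient_id, gene,
#' amplitude t), `readSnvTable()` (MAF-style: Tumor_Sample_Barcode,
#' Hugo_Symbol, Variant_Classification) and `readExpressionTable()`
#' (gene x patient matrix with a leading `gene` column).
#'
#' @param path TSV file path.
#' @param genes gene panel the matrix rows must cover.
#' @return `readClinicalTable()`: data.frame. `readCnvTable()` /
#'   `readExpressionTable()`: numeric gene x patient matrix.
#'   `readSnvTable()`: 0/1 integer gene x patient matrix (a gene is 1 for
#'   a patient if any of its variants is non-synonymous).
#' @export
readClinicalTable <- function(path) {
  if (!file.exists(path)) ioError(paste("cannot read table:", path))
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname readClinicalTable
#' @export
readCnvTable <- function(path, genes) {
  d <- readClinicalTable(path)
  pats <- unique(d$patient_id)
  m <- matrix(NA_real_, length(genes), length(pats),
              dimnames = list(genes, pats))
  m[cbind(match(d$gene, genes), match(d$patient_id, pats))] <- d$t
  if (anyNA(m)) validationError("CNV table does not cover the gene panel")
  m
}

#' @rdname readClinicalTable
#' @export
readSnvTable <- function(path, genes) {
  d <- readClinicalTable(path)
  pats <- unique(d$Tumor_Sample_Barcode)
  code <- snvCode(d$Variant_Classification)
  m <- matrix(0L, length(genes), length(pats), dimnames = list(genes, pats))
  keep <- d$Hugo_Symbol %in% genes
  idx <- cbind(match(d$Hugo_Symbol[keep], genes),
               match(d$Tumor_Sample_Barcode[keep], pats))
  # a gene is non-synonymously mutated if any of its variants is
  for (i in which(code[keep] == 1L)) m[idx[i, 1], idx[i, 2]] <- 1L
  m
}

#' @rdname readClinicalTable
#' @export
readExpressionTable <- function(path, genes) {
  d <- readClinicalTable(path)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$gene
  m <- m[match(genes, rownames(m)), , drop = FALSE]
  if (anyNA(rownames(m))) validationError("expression table misses panel genes")
  m
}

## Assembly ---------------------------------------------------------------------

.patientFactors <- function(cohort, cnvGenes, snvGenes, mrnaGenes) {
  pat <- cohort@patients
  clin <- encodeClinical(data.frame(
    sex = pat$sex, race = pat$race, age_at_diagnosis = pat$ageAtDiagnosis,
    T = pat$tStage, N = pat$nStage, M = pat$mStage, stage = pat$stage,
    check.names = FALSE))
  cnv <- t(apply(cohort@cnv[cnvGenes, , drop = FALSE], 1L, cnvCode))
  snvRaw <- cohort@snv[snvGenes, , drop = FALSE]
  snv <- matrix(0L, nrow(snvRaw), ncol(snvRaw), dimnames = dimnames(snvRaw))
  has <- !is.na(snvRaw)
  snv[has] <- snvCode(snvRaw[has])
  mrna <- cohort@expression[mrnaGenes, , drop = FALSE]
  df <- data.frame(patient_id = pat$patientId, clin,
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (g in cnvGenes) df[[paste0("CNV_", g)]] <- cnv[g, ]
  for (g in snvGenes) df[[paste0("SNV_", g)]] <- snv[g, ]
  for (g in mrnaGenes) df[[paste0("mRNA_", g)]] <- mrna[g, ]
  df$Type <- pat$subtype
  df$`1_year` <- survivalLabel(pat$css, pat$osTime, 365)
  df$`2_year` <- survivalLabel(pat$css, pat$osTime, 730)
  df$`3_year` <- survivalLabel(pat$css, pat$osTime, 1095)
  df
}

#' Assemble the per-nucleus modeling dataset
#'
#' Joins per-nucleus feature rows with the per-patient clinical and
#' genetic factors by patient id, balances every patient to `target` rows
#' ([balancePatient()]), attaches the task label and splits patients
#' 60/20/20 ([splitPatients()]). The subtype design matrix holds the 20
#' nuclear features plus the mRNA panel (46 columns with the default
#' 26-gene panel); the survival design matrices hold all factors (95
#' columns with the default 20 + 7 + 15 + 27 + 26 schema).
#'
#' @param features per-nucleus feature table ([extractFeatures()] or
#'   [simulateFeatureCohort()] output).
#' @param cohort a [SyntheticCohort-class] carrying the patient tables, or
#'   a pre-built per-patient factor data.frame with a `patient_id` column,
#'   label columns `Type`, `1_year`, `2_year`, `3_year` and the factor
#'   columns.
#' @param task "subtype", "os1", "os2" or "os3".
#' @param target balanced rows per patient (default 200).
#' @param fractions train/validation/test fractions.
#' @param stratify stratify the split by subtype (default TRUE).
#' @param cnvGenes,snvGenes,mrnaGenes factor panels (defaults: first 15 of
#'   the gene panel for CNV, all 27 for SNV, first 26 for mRNA).
#' @param dropUnknown drop survival class-0 rows (default FALSE: the
#'   "unknown" class is kept as a third class).
#' @param seed integer seed driving balancing and splitting.
#' @return An [AssembledDataset-class].
#' @export
assembleDataset <- function(features, cohort,
                            task = c("subtype", "os1", "os2", "os3"),
                            target = 200L, fractions = c(0.6, 0.2, 0.2),
                            stratify = TRUE,
                            cnvGenes = NULL, snvGenes = NULL, mrnaGenes = NULL,
                            dropUnknown = FALSE, seed = 1L) {
  task <- match.arg(task)
  if (is(cohort, "SyntheticCohort")) {
    genes <- cohort@spec@genes
    cnvGenes <- cnvGenes %||% genes[seq_len(min(15L, length(genes)))]
    snvGenes <- snvGenes %||% genes
    mrnaGenes <- mrnaGenes %||% genes[seq_len(min(26L, length(genes)))]
    factors <- .patientFactors(cohort, cnvGenes, snvGenes, mrnaGenes)
  } else {
    factors <- cohort
    cnvGenes <- cnvGenes %||% sub("^CNV_", "", grep("^CNV_", names(factors), value = TRUE))
    snvGenes <- snvGenes %||% sub("^SNV_", "", grep("^SNV_", names(factors), value = TRUE))
    mrnaGenes <- mrnaGenes %||% sub("^mRNA_", "", grep("^mRNA_", names(factors), value = TRUE))
  }

  noFactor <- setdiff(unique(features$patient_id), factors$patient_id)
  if (length(noFactor)) {
    message(length(noFactor),
            " patient(s) with features but no clinical/genetic record dropped")
    features <- features[!features$patient_id %in% noFactor, , drop = FALSE]
  }

  ## balance per patient
  ids <- unique(features$patient_id)
  balanced <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rows <- features[features$patient_id == ids[i], , drop = FALSE]
    balanced[[i]] <- balancePatient(rows, target, seed = childSeed(seed, i))
  }
  data <- do.call(rbind, balanced)
  rownames(data) <- NULL

  data <- merge(data, factors, by = "patient_id", sort = FALSE)

  labelCol <- switch(task, subtype = "Type", os1 = "1_year",
                     os2 = "2_year", os3 = "3_year")
  data$.label <- data[[labelCol]]
  if (dropUnknown && task != "subtype") {
    data <- data[data$.label != 0L, , drop = FALSE]
  }

  clinCols <- c("Gender", "Race", "Age_at_diagnosis", "T", "N", "M", "Stage")
  featureColumns <- if (task == "subtype") {
    c(nuclearFeatureNames(), paste0("mRNA_", mrnaGenes))
  } else {
    c(nuclearFeatureNames(), clinCols, paste0("CNV_", cnvGenes),
      paste0("SNV_", snvGenes), paste0("mRNA_", mrnaGenes))
  }

  sub <- factors$subtype %||% factors$Type
  part <- splitPatients(factors$patient_id,
                        subtype = if (stratify) sub else NULL,
                        fractions = fractions, stratify = stratify,
                        seed = childSeed(seed, 0L))
  part <- part[names(part) %in% data$patient_id]

  new("AssembledDataset", data = data, featureColumns = featureColumns,
      task = task, partition = part)
}
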
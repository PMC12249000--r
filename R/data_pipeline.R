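# Dataset indexing and leakage-free patient-level partitioning.
#
# The canonical input is a comma-separated manifest with header
#   image_path,patient_id,class_label,subtype,magnification
# Every image of a patient carries the patient's single diagnosis; splits and
# folds operate on patients, never on images, so no patient's images can
# straddle a partition boundary.

CLASS_LEVELS <- c("benign", "malignant")
MAGNIFICATIONS <- c(40L, 100L, 200L, 400L)

#' Load and validate a dataset manifest
#'
#' @param path path to a CSV manifest with columns `image_path`,
#'   `patient_id`, `class_label`, `subtype`, `magnification`.
#' @return a `data.frame` of validated sample records (class
#'   `dataset_index`).
#' @export
load_manifest <- function(path) {
  if (!file.exists(path))
    cs_stop("manifest not found: %s", "cellsage_parse_error", path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) cs_stop("cannot parse manifest %s: %s",
                                "cellsage_parse_error", path,
                                conditionMessage(e)))
  if (nrow(df) == 0L)
    cs_stop("manifest %s contains no records", "cellsage_parse_error", path)
  need <- c("image_path", "patient_id", "class_label", "subtype",
            "magnification")
  miss <- setdiff(need, names(df))
  if (length(miss))
    cs_stop("manifest is missing column(s): %s", "cellsage_parse_error",
            paste(miss, collapse = ", "))
  bad <- which(!df$class_label %in% CLASS_LEVELS)
  if (length(bad))
    cs_stop("row %d: unknown class_label '%s'", "cellsage_parse_error",
            bad[1], df$class_label[bad[1]])
  dup <- which(duplicated(df$image_path))
  if (length(dup))
    cs_stop("row %d: duplicate image_path '%s'", "cellsage_parse_error",
            dup[1], df$image_path[dup[1]])
  df$magnification <- suppressWarnings(as.integer(df$magnification))
  bad <- which(!df$magnification %in% MAGNIFICATIONS)
  if (length(bad))
    cs_stop("row %d: magnification must be one of %s", "cellsage_parse_error",
            bad[1], paste(MAGNIFICATIONS, collapse = "/"))
  # per-patient label consistency
  tab <- unique(df[, c("patient_id", "class_label")])
  inc <- tab$patient_id[duplicated(tab$patient_id)]
  if (length(inc)) {
    rows <- which(df$patient_id == inc[1])
    cs_stop("patient '%s' carries both class labels (e.g. rows %d and %d)",
            "cellsage_parse_error", inc[1], rows[1], rows[length(rows)])
  }
  class(df) <- c("dataset_index", "data.frame")
  df
}

#' Write a manifest
#' @param index a `dataset_index` (or compatible data.frame).
#' @param path output CSV path.
#' @export
write_manifest <- function(index, path) {
  utils::write.csv(as.data.frame(index), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter a dataset index by magnification
#' @param index a `dataset_index`.
#' @param magnification one or more of 40, 100, 200, 400.
#' @export
filter_magnification <- function(index, magnification) {
  out <- index[index$magnification %in% as.integer(magnification), ,
               drop = FALSE]
  class(out) <- class(index)
  out
}

patient_table <- function(index) {
  unique(as.data.frame(index)[, c("patient_id", "class_label")])
}

# Largest-remainder seat allocation of n units into length(fractions) parts.
# Ties in the fractional remainders are broken by part order (train first).
largest_remainder <- function(n, fractions) {
  quota <- n * fractions
  seats <- floor(quota)
  left <- n - sum(seats)
  if (left > 0) {
    rem <- quota - seats
    ord <- order(-rem, seq_along(rem))
    seats[ord[seq_len(left)]] <- seats[ord[seq_len(left)]] + 1
  }
  as.integer(seats)
}

#' Patient-wise stratified holdout split
#'
#' Shuffles patients (not images) with the seed, stratifies by the
#' patient-level class label, and allocates patients to train/validation/test
#' by largest-remainder rounding within each class stratum, so each
#' partition's class ratio tracks the global ratio to within one patient.
#' All images follow their patient.
#'
#' @param index a `dataset_index`.
#' @param fractions train/val/test fractions summing to 1 (default
#'   0.6/0.2/0.2).
#' @param seed shuffle seed.
#' @return a `split_plan`: data.frame `patient_id`, `assignment` with
#'   attributes `fractions` and `seed`.
#' @export
patient_stratified_split <- function(index, fractions = c(train = 0.6,
                                                          val = 0.2,
                                                          test = 0.2),
                                     seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9)
    cs_stop("fractions must sum to 1", "cellsage_config_error")
  pts <- patient_table(index)
  if (nrow(pts) < length(fractions))
    cs_stop("need at least %d patients for %d partitions",
            "cellsage_config_error", length(fractions), length(fractions))
  parts <- names(fractions) %||% c("train", "val", "test")
  rows <- list()
  with_seed(seed, {
    for (cl in intersect(CLASS_LEVELS, pts$class_label)) {
      ids <- pts$patient_id[pts$class_label == cl]
      ids <- ids[sample.int(length(ids))]
      seats <- largest_remainder(length(ids), fractions)
      assign_ <- rep(parts, times = seats)
      rows[[cl]] <- data.frame(patient_id = ids, assignment = assign_)
    }
  })
  plan <- do.call(rbind, rows)
  rownames(plan) <- NULL
  structure(plan, fractions = fractions, seed = seed,
            class = c("split_plan", "data.frame"))
}

#' Patient-stratified k-fold plan
#'
#' Shuffles patients within each class and deals them cyclically to folds,
#' continuing the deal across classes, so fold sizes differ by at most one
#' patient overall and per class.
#'
#' @param index a `dataset_index`.
#' @param k number of folds (default 5).
#' @param seed shuffle seed.
#' @return list of k `split_plan`s; plan i assigns fold i's patients to
#'   `"test"` and all others to `"train"`. Each also carries a `fold` column
#'   in attribute form via `attr(, "folds")` (patient -> fold index 1..k).
#' @export
kfold_patient_stratified <- function(index, k = 5L, seed = 1L) {
  pts <- patient_table(index)
  if (k < 2L || k > nrow(pts))
    cs_stop("k must lie in [2, number of patients = %d]",
            "cellsage_config_error", nrow(pts))
  fold_of <- integer(0)
  ids_all <- character(0)
  ptr <- 0L
  with_seed(seed, {
    for (cl in intersect(CLASS_LEVELS, pts$class_label)) {
      ids <- pts$patient_id[pts$class_label == cl]
      ids <- ids[sample.int(length(ids))]
      f <- ((ptr + seq_along(ids) - 1L) %% k) + 1L
      ptr <- (ptr + length(ids)) %% k
      fold_of <- c(fold_of, f)
      ids_all <- c(ids_all, ids)
    }
  })
  folds <- data.frame(patient_id = ids_all, fold = fold_of)
  lapply(seq_len(k), function(i) {
    plan <- data.frame(
      patient_id = folds$patient_id,
      assignment = ifelse(folds$fold == i, "test", "train"))
    structure(plan, fractions = NULL, seed = seed, fold = i, folds = folds,
              class = c("split_plan", "data.frame"))
  })
}

#' Subset a dataset index by a split plan
#'
#' @param index a `dataset_index`.
#' @param plan a `split_plan`.
#' @param partition partition name (`"train"`, `"val"`, `"test"`).
#' @return the records of the patients assigned to `partition`.
#' @export
subset_index <- function(index, plan, partition) {
  ids <- plan$patient_id[plan$assignment == partition]
  out <- index[index$patient_id %in% ids, , drop = FALSE]
  class(out) <- class(index)
  out
}

#' Inverse-frequency class weights
#'
#' Weights `w_c = 1 / (K * f_c)` for class frequency `f_c` over K classes,
#' so the image-weighted mean weight is exactly 1. Intended as loss weights
#' for class rebalancing.
#'
#' @param index a `dataset_index` (or any data.frame with `class_label`).
#' @return named numeric vector `benign`, `malignant`.
#' @export
compute_class_weights <- function(index) {
  f <- table(factor(index$class_label, levels = CLASS_LEVELS)) / nrow(index)
  if (any(f == 0))
    cs_stop("both classes must be present to compute class weights",
            "cellsage_config_error")
  w <- 1 / (length(CLASS_LEVELS) * as.numeric(f))
  names(w) <- CLASS_LEVELS
  w
}

#' Serialize / restore a split plan
#'
#' Writes `assignments.csv` (`patient_id,assignment`) plus a `meta.json`
#' sidecar recording fractions and seed for provenance.
#'
#' @param plan a `split_plan`.
#' @param dir output directory (created if needed).
#' @return `read_split_plan` returns a `split_plan`.
#' @export
write_split_plan <- function(plan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(plan)[, c("patient_id", "assignment")],
                   file.path(dir, "assignments.csv"), row.names = FALSE,
                   quote = FALSE)
  meta <- list(fractions = attr(plan, "fractions"), seed = attr(plan, "seed"),
               fold = attr(plan, "fold"))
  jsonlite::write_json(meta[!vapply(meta, is.null, TRUE)],
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_split_plan
#' @param dir directory previously written by `write_split_plan`.
#' @export
read_split_plan <- function(dir) {
  plan <- utils::read.csv(file.path(dir, "assignments.csv"),
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  meta_path <- file.path(dir, "meta.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  structure(plan, fractions = unlist(meta$fractions), seed = meta$seed,
            fold = meta$fold, class = c("split_plan", "data.frame"))
}

#' Check a plan for patient leakage
#'
#' @param plan a `split_plan`.
#' @return TRUE invisibly; errors if any patient appears in two partitions.
#' @export
assert_no_leakage <- function(plan) {
  if (anyDuplicated(plan$patient_id))
    cs_stop("patient '%s' appears in more than one partition",
            "cellsage_leakage_error",
            plan$patient_id[duplicated(plan$patient_id)][1])
  invisible(TRUE)
}
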
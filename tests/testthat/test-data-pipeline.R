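# data_pipeline: manifest validation, patient-wise partitioning, class
# weights, serialization.

test_that("load_manifest validates structure and patient consistency", {
  idx <- make_index(2, 2, 1)
  f <- write_index_csv(idx, tempfile(fileext = ".csv"))
  got <- load_manifest(f)
  expect_s3_class(got, "dataset_index")
  expect_equal(nrow(got), 4L)
  # one patient with both labels -> error naming the patient
  bad <- make_index(2, 2, 2)
  bad$class_label[1] <- "malignant"   # first image of two-image patient B01
  f2 <- write_index_csv(bad, tempfile(fileext = ".csv"))
  expect_error(load_manifest(f2), "B01", class = "cellsage_parse_error")
  # empty file
  f3 <- tempfile(fileext = ".csv")
  writeLines("image_path,patient_id,class_label,subtype,magnification", f3)
  expect_error(load_manifest(f3), class = "cellsage_parse_error")
  # missing column
  f4 <- tempfile(fileext = ".csv")
  utils::write.csv(idx[, -2], f4, row.names = FALSE)
  expect_error(load_manifest(f4), "patient_id", class = "cellsage_parse_error")
  # duplicate path / unknown label / magnification
  dup <- rbind(idx, idx[1, ])
  expect_error(load_manifest(write_index_csv(dup, tempfile())),
               "duplicate", class = "cellsage_parse_error")
  lab <- idx; lab$class_label[2] <- "normal"
  expect_error(load_manifest(write_index_csv(lab, tempfile())),
               "class_label", class = "cellsage_parse_error")
  mag <- idx; mag$magnification[2] <- 63L
  expect_error(load_manifest(write_index_csv(mag, tempfile())),
               "magnification", class = "cellsage_parse_error")
})

test_that("holdout split: disjoint, exhaustive, stratified, deterministic", {
  for (s in 1:5) {
    nb <- sample(5:20, 1); nm <- sample(5:25, 1)
    idx <- make_index(nb, nm, 2)
    plan <- patient_stratified_split(idx, seed = s)
    expect_true(assert_no_leakage(plan))
    expect_setequal(plan$patient_id, unique(idx$patient_id))
    # stratification: partition class fraction within one patient's worth
    glob <- nm / (nb + nm)
    for (part in c("train", "val", "test")) {
      sub <- subset_index(idx, plan, part)
      pt <- unique(sub[, c("patient_id", "class_label")])
      np <- nrow(pt)
      expect_lte(abs(sum(pt$class_label == "malignant") - glob * np), 1)
    }
    # images follow their patient: no image path in two partitions
    paths <- lapply(c("train", "val", "test"),
                    function(p) subset_index(idx, plan, p)$image_path)
    expect_equal(length(unlist(paths)), nrow(idx))
    expect_false(any(duplicated(unlist(paths))))
  }
  idx <- make_index(6, 6, 1)
  p1 <- patient_stratified_split(idx, seed = 4)
  p2 <- patient_stratified_split(idx, seed = 4)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  expect_error(patient_stratified_split(idx, fractions = c(0.7, 0.2, 0.2)),
               class = "cellsage_config_error")
})

test_that("82 patients at 60/20/20 allocate 50/16/16 by largest remainder", {
  idx <- make_index(41, 41, 1)
  plan <- patient_stratified_split(idx, seed = 3)
  sizes <- table(plan$assignment)
  expect_equal(as.integer(sizes[c("train", "val", "test")]), c(50L, 16L, 16L))
})

test_that("k-fold plans partition patients with balanced folds", {
  idx <- make_index(41, 41, 1)
  plans <- kfold_patient_stratified(idx, k = 5, seed = 2)
  expect_length(plans, 5L)
  test_sets <- lapply(plans, function(p) p$patient_id[p$assignment == "test"])
  # pairwise disjoint, union = all patients
  expect_equal(sort(unlist(test_sets)), sort(unique(idx$patient_id)))
  expect_false(any(duplicated(unlist(test_sets))))
  sizes <- lengths(test_sets)
  expect_true(all(sizes %in% c(16L, 17L)))
  expect_equal(sum(sizes), 82L)
  # per-fold malignant fraction within one patient of proportional
  for (ts in test_sets) {
    nm <- sum(startsWith(ts, "M"))
    expect_lte(abs(nm - 0.5 * length(ts)), 1)
  }
  expect_error(kfold_patient_stratified(idx, k = 1),
               class = "cellsage_config_error")
  expect_error(kfold_patient_stratified(make_index(2, 2, 1), k = 9),
               class = "cellsage_config_error")
  # determinism
  plans2 <- kfold_patient_stratified(idx, k = 5, seed = 2)
  expect_identical(lapply(plans, as.data.frame), lapply(plans2, as.data.frame))
})

test_that("class weights are inverse-frequency with image-weighted mean 1", {
  bal <- make_index(4, 4, 2)
  expect_equal(unname(compute_class_weights(bal)), c(1, 1))
  imb <- make_index(2, 6, 2)  # 25% benign, 75% malignant
  w <- compute_class_weights(imb)
  expect_equal(unname(w["malignant"]), 2 / 3)
  expect_equal(unname(w["benign"]), 2)
  f <- table(imb$class_label) / nrow(imb)
  expect_equal(sum(w[names(f)] * as.numeric(f)), 1)
  expect_true(all(w > 0))
  only <- make_index(3, 0, 2)
  expect_error(compute_class_weights(only), class = "cellsage_config_error")
})

test_that("split plans serialize with provenance", {
  idx <- make_index(5, 5, 1)
  plan <- patient_stratified_split(idx, seed = 11)
  d <- tempfile()
  write_split_plan(plan, d)
  back <- read_split_plan(d)
  expect_equal(as.data.frame(back)[, c("patient_id", "assignment")],
               as.data.frame(plan)[, c("patient_id", "assignment")])
  expect_equal(attr(back, "seed"), 11L)
  expect_equal(unname(attr(back, "fractions")), c(0.6, 0.2, 0.2))
})

test_that("magnification filter pools and filters as documented", {
  idx <- make_index(2, 2, 8)
  f40 <- filter_magnification(idx, 40)
  expect_true(all(f40$magnification == 40L))
  expect_equal(nrow(f40), 8L)
  expect_equal(nrow(filter_magnification(idx, c(40, 400))), 16L)
})
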
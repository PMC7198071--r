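# Filename parsing, manifests, dataset splitting, preprocessing,
# augmentation.

test_that("BreakHis file names parse into label, patient and magnification", {
  r <- parse_breakhis_filename("SOB_B_TA-14-4659-40-001.png")
  expect_equal(r$label, "benign")
  expect_equal(r$patient_id, "14-4659")
  expect_equal(r$magnification, 40L)
  r2 <- parse_breakhis_filename("SOB_M_DC-14-2523-400-012.png")
  expect_equal(r2$label, "malignant")
  expect_equal(r2$patient_id, "14-2523")
  expect_equal(r2$magnification, 400L)
  expect_error(parse_breakhis_filename("image001.png"), "image001.png")
  # full paths are fine; only the base name is parsed
  r3 <- parse_breakhis_filename("/data/benign/x/SOB_B_A-91-0001-100-003.png")
  expect_equal(r3$magnification, 100L)
})

test_that("manifest write -> load is the identity and errors carry positions", {
  recs <- make_records(n_patients = 10L, images_per = 10L, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest(recs, path)
  back <- load_manifest(path)
  expect_equal(back, recs, ignore_attr = TRUE)

  bad <- recs
  bad$magnification[7] <- 250L
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(load_manifest(path2), "row 7.*250")

  nocol <- recs[, c("path", "label", "patient_id")]
  path3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(nocol, path3, row.names = FALSE)
  expect_error(load_manifest(path3), "missing column.*magnification")
})

test_that("image-level splits are sized, stratified, disjoint and exhaustive", {
  recs <- make_records(n_patients = 10L, images_per = 10L, seed = 3)  # 100 rows
  sp <- split_dataset(recs, c(0.5, 0.2, 0.3), seed = 1)
  expect_equal(nrow(sp$train), 50L)
  expect_equal(nrow(sp$validation), 20L)
  expect_equal(nrow(sp$test), 30L)
  # determinism
  sp2 <- split_dataset(recs, c(0.5, 0.2, 0.3), seed = 1)
  expect_identical(sp$train$path, sp2$train$path)
  expect_false(identical(sp$train$path,
                         split_dataset(recs, seed = 2)$train$path))
  for (seed in 1:5) {
    s <- split_dataset(recs, seed = seed)
    all_paths <- c(s$train$path, s$validation$path, s$test$path)
    expect_setequal(all_paths, recs$path)
    expect_equal(anyDuplicated(all_paths), 0L)
    # stratification: each subset's class counts within 1 of the global ratio
    for (part in list(s$train, s$validation, s$test)) {
      frac <- nrow(part) / nrow(recs)
      for (lb in c("benign", "malignant")) {
        expect_lte(abs(sum(part$label == lb) - frac * sum(recs$label == lb)), 1)
      }
    }
  }
  expect_error(split_dataset(recs, c(0.5, 0.2, 0.2)), "fractions")
})

test_that("patient-disjoint splits never share a patient", {
  recs <- make_records(n_patients = 12L, images_per = 6L, seed = 4)
  for (seed in 1:5) {
    s <- split_dataset(recs, seed = seed, mode = "patient")
    parts <- list(s$train, s$validation, s$test)
    for (i in 1:2) for (j in (i + 1):3) {
      expect_length(intersect(parts[[i]]$patient_id, parts[[j]]$patient_id), 0L)
    }
    expect_equal(sum(vapply(parts, nrow, integer(1))), nrow(recs))
  }
})

test_that("preprocessing resizes to 224x224 and applies the normalization law", {
  set.seed(33)
  raw <- array(runif(460 * 700 * 3), c(460, 700, 3))  # BreakHis frame size
  out <- preprocess_image(raw, size = 224L)
  expect_equal(dim(out), c(224, 224, 3))

  gray <- array(0.5, c(64, 64, 3))
  ni <- preprocess_image(gray, size = 64L, normalize = "imagenet")
  stats <- idsnet:::imagenet_stats
  for (c_ in 1:3) {
    expect_equal(unique(as.vector(ni[, , c_])),
                 (0.5 - stats$mean[c_]) / stats$std[c_], tolerance = 1e-12)
  }
  # already-at-size inputs pass through untouched
  same <- rand_fmap(224, 224, 3)
  expect_identical(preprocess_image(same, 224L, normalize = "unit"), same)
  expect_error(preprocess_image(withr::local_tempfile(fileext = ".png")),
               "cannot decode|no such|cannot open")
})

test_that("augmentation yields the five dihedral variants and a six-fold pool", {
  set.seed(34)
  img <- rand_fmap(8, 8, 3)   # asymmetric with probability 1
  a <- augment_image(img)
  expect_named(a, c("rot90", "rot180", "rot270", "mirror_h", "mirror_v"))
  expect_equal(attr(a, "n_distinct"), 5L)
  for (v in a) expect_equal(dim(v), dim(img))
  # pairwise distinct, and distinct from the original
  vs <- c(list(img), a)
  for (i in seq_along(vs)) for (j in seq_len(i - 1)) {
    expect_false(isTRUE(all.equal(vs[[i]], vs[[j]])))
  }
  # dihedral identity: rot180 = horizontal then vertical mirror
  expect_equal(a$rot180,
               idsnet:::mirror_vertical(idsnet:::mirror_horizontal(img)))
  # four quarter turns are the identity
  expect_equal(idsnet:::rotate90(a$rot270), img)

  # a 90-degree-rotation-invariant image yields duplicates, reported not fatal
  sym <- array(1, c(6, 6, 1))
  expect_lt(attr(augment_image(sym), "n_distinct"), 5L)

  # 10 originals make a training pool of 60
  x10 <- rand_fmap(8, 8, 3, B = 10)
  pool <- idsnet:::augment_batch(x10, rep(0:1, 5))
  expect_equal(dim(pool$x)[4], 60L)
  expect_length(pool$y, 60L)
  expect_equal(pool$x[, , , 1:10], x10)
})

test_that("PNG reading feeds the pipeline (gray and RGBA coerced to RGB)", {
  p <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(runif(64), 8, 8), p)
  expect_equal(dim(preprocess_image(p, 8L, normalize = "unit")), c(8, 8, 3))
  p2 <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(runif(8 * 8 * 4), c(8, 8, 4)), p2)
  expect_equal(dim(preprocess_image(p2, 8L, normalize = "unit")), c(8, 8, 3))
})
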
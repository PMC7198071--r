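# Data handling: BreakHis-style filename parsing and directory scanning,
# manifest CSVs, train/validation/test splitting, image preprocessing and
# the rotation/mirror training augmentation.
#
# An image record set is a data frame with columns
#   path (chr), label ("benign"|"malignant"), patient_id (chr),
#   magnification (40|100|200|400)
# -- one row per labelled image, the atom of splitting and evaluation.

.labels <- c("benign", "malignant")
.magnifications <- c(40L, 100L, 200L, 400L)

.manifest_cols <- c("path", "label", "patient_id", "magnification")

#' Parse BreakHis-dialect file names
#'
#' File names follow `SOB_<B|M>_<subtype>-<slide-id>-<magnification>-<seq>.png`,
#' e.g. `SOB_B_TA-14-4659-40-001.png`.  The slide id serves as the patient id.
#'
#' @param name character vector of file names (paths allowed; only the base
#'   name is parsed).
#' @return data frame with columns `label`, `patient_id`, `magnification`.
#' @export
parse_breakhis_filename <- function(name) {
  base <- basename(name)
  rx <- "^SOB_([BM])_([A-Za-z]+)-(.+)-(40|100|200|400)-([0-9]+)\\.png$"
  ok <- grepl(rx, base)
  if (any(!ok)) {
    stop("cannot parse BreakHis file name: ", base[!ok][1])
  }
  data.frame(
    label = ifelse(sub(rx, "\\1", base) == "B", "benign", "malignant"),
    patient_id = sub(rx, "\\3", base),
    magnification = as.integer(sub(rx, "\\4", base)),
    stringsAsFactors = FALSE
  )
}

#' Scan a benign/malignant image tree into an image record set
#'
#' Recursively collects `*.png` files under `dir` and parses their BreakHis
#' file names.
#'
#' @param dir root directory.
#' @return image record data frame.
#' @export
scan_breakhis_dir <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  paths <- list.files(dir, pattern = "\\.png$", recursive = TRUE,
                      full.names = TRUE)
  if (!length(paths)) stop("no PNG images found under ", dir)
  cbind(data.frame(path = paths, stringsAsFactors = FALSE),
        parse_breakhis_filename(paths))
}

validate_records <- function(records, where = "manifest") {
  miss <- setdiff(.manifest_cols, names(records))
  if (length(miss)) {
    stop(where, " is missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- which(!(records$label %in% .labels))
  if (length(bad)) {
    stop(sprintf("%s row %d: unknown label '%s'", where, bad[1],
                 records$label[bad[1]]))
  }
  bad <- which(!(records$magnification %in% .magnifications))
  if (length(bad)) {
    stop(sprintf("%s row %d: unknown magnification '%s'", where, bad[1],
                 records$magnification[bad[1]]))
  }
  bad <- which(is.na(records$patient_id) | !nzchar(records$patient_id))
  if (length(bad)) {
    stop(sprintf("%s row %d: empty patient_id", where, bad[1]))
  }
  records$magnification <- as.integer(records$magnification)
  records[, union(.manifest_cols, names(records))]
}

#' Read / write a dataset manifest CSV
#'
#' The manifest has the header `path,label,patient_id,magnification` with
#' `label` in benign/malignant and `magnification` in 40/100/200/400.
#' Writing then reading a record set is the identity.
#'
#' @param path CSV file path.
#' @param records image record data frame.
#' @return `load_manifest` returns the record data frame; `write_manifest`
#'   returns `path` invisibly.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("no such manifest: ", path)
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  df <- validate_records(df, where = path)
  df
}

#' @rdname load_manifest
#' @export
write_manifest <- function(records, path) {
  records <- validate_records(records)
  utils::write.csv(records[, .manifest_cols], path, row.names = FALSE)
  invisible(path)
}

#' Split an image record set into train/validation/test
#'
#' In `"image"` mode individual images are assigned to subsets, stratified
#' by class label, mirroring a protocol in which images of all patients and
#' magnifications are pooled before division.  Because all magnifications of
#' a patient enter the pool, this mode leaks patient identity between
#' subsets; `"patient"` mode assigns whole patients (stratified by the
#' patient's class) so that no patient contributes images to two subsets,
#' which is the recommended protocol for honest generalization estimates.
#'
#' @param records image record data frame.
#' @param fractions train/validation/test fractions, summing to 1.
#' @param seed integer seed; the split is deterministic given the seed.
#' @param mode `"image"` (stratified by label) or `"patient"`
#'   (patient-disjoint).
#' @return object of class `dataset_split`: list with `train`, `validation`,
#'   `test` record data frames plus the `fractions`, `seed` and `mode` used.
#' @export
split_dataset <- function(records, fractions = c(0.5, 0.2, 0.3), seed = 1L,
                          mode = c("image", "patient")) {
  mode <- match.arg(mode)
  records <- validate_records(records, "records")
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must be three non-negative numbers summing to 1")
  }
  take <- function(n) {
    # subset sizes within +/-1 of fraction * n
    n_tr <- round(fractions[1] * n)
    n_va <- round(fractions[2] * n)
    if (n_tr + n_va > n) n_va <- n - n_tr
    c(n_tr, n_va, n - n_tr - n_va)
  }
  assign_groups <- function(n) {
    sz <- take(n)
    rep.int(c("train", "validation", "test"), sz)[sample.int(n)]
  }
  withr::with_seed(seed, {
    if (mode == "image") {
      grp <- character(nrow(records))
      for (lb in unique(records$label)) {
        sel <- which(records$label == lb)
        grp[sel] <- assign_groups(length(sel))
      }
    } else {
      pat <- unique(records[, c("patient_id", "label")])
      pgrp <- character(nrow(pat))
      for (lb in unique(pat$label)) {
        sel <- which(pat$label == lb)
        pgrp[sel] <- assign_groups(length(sel))
      }
      grp <- pgrp[match(records$patient_id, pat$patient_id)]
    }
  })
  structure(list(train = records[grp == "train", , drop = FALSE],
                 validation = records[grp == "validation", , drop = FALSE],
                 test = records[grp == "test", , drop = FALSE],
                 fractions = fractions, seed = seed, mode = mode),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("dataset split (%s mode, seed %d): %d train / %d validation / %d test\n",
              x$mode, x$seed, nrow(x$train), nrow(x$validation), nrow(x$test)))
  invisible(x)
}

## ---- preprocessing -----------------------------------------------------------

imagenet_stats <- list(mean = c(0.485, 0.456, 0.406),
                       std = c(0.229, 0.224, 0.225))

#' Bilinear resize of an (H, W, C) image array
#'
#' @param img image array with values of any real scale.
#' @param out_h,out_w target size.
#' @return resized `(out_h, out_w, C)` array.
#' @export
resize_bilinear <- function(img, out_h, out_w) {
  d <- dim(img)
  if (d[1] == out_h && d[2] == out_w) return(img)
  src <- function(n_out, n_in) {
    s <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    s[s < 0] <- 0
    s[s > n_in - 1] <- n_in - 1
    i0 <- floor(s)
    list(i0 = as.integer(i0) + 1L,
         i1 = pmin(as.integer(i0) + 2L, n_in),
         w = s - i0)
  }
  ri <- src(out_h, d[1])
  cj <- src(out_w, d[2])
  out <- array(0, dim = c(out_h, out_w, d[3]))
  for (c_ in seq_len(d[3])) {
    M <- img[, , c_]
    R <- M[ri$i0, , drop = FALSE] * (1 - ri$w) + M[ri$i1, , drop = FALSE] * ri$w
    out[, , c_] <- sweep(R[, cj$i0, drop = FALSE], 2L, 1 - cj$w, `*`) +
      sweep(R[, cj$i1, drop = FALSE], 2L, cj$w, `*`)
  }
  out
}

read_image <- function(path) {
  img <- tryCatch(png::readPNG(path),
                  error = function(e) stop("cannot decode image ", path, ": ",
                                           conditionMessage(e)))
  d <- dim(img)
  if (is.null(d) || length(d) == 2L) img <- array(img, dim = c(dim(img), 1L))
  if (dim(img)[3] == 1L) img <- img[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Preprocess one image for the network
#'
#' Decodes (if given a path), bilinearly resizes to `size x size` and
#' normalizes per channel.  The default normalization uses the ImageNet
#' channel statistics so that a trunk initialized from ImageNet-pretrained
#' weights sees inputs on the scale it was trained with; `"unit"` keeps
#' plain \[0, 1\] intensities.
#'
#' @param input a PNG file path or an `(H, W, C)` array in \[0, 1\].
#' @param size target side length.
#' @param normalize `"imagenet"`, `"unit"` or `"none"` (alias of unit).
#' @return a `(size, size, 3)` array.
#' @export
preprocess_image <- function(input, size = 224L,
                             normalize = c("imagenet", "unit", "none")) {
  normalize <- match.arg(normalize)
  img <- if (is.character(input)) read_image(input) else input
  d <- dim(img)
  if (is.null(d) || length(d) != 3L) stop("image must be an (H, W, C) array")
  img <- resize_bilinear(img, size, size)
  if (normalize == "imagenet") {
    for (c_ in 1:3) {
      img[, , c_] <- (img[, , c_] - imagenet_stats$mean[c_]) /
        imagenet_stats$std[c_]
    }
  }
  img
}

#' Load a record set as a preprocessed batch
#'
#' @param records image record data frame.
#' @param size target side length.
#' @param normalize see [preprocess_image()].
#' @return list with `x` (`(size, size, 3, N)` array) and `y` (integer
#'   labels, 0 = benign, 1 = malignant).
#' @export
load_images <- function(records, size = 224L, normalize = "imagenet") {
  n <- nrow(records)
  x <- array(0, dim = c(size, size, 3L, n))
  for (i in seq_len(n)) {
    x[, , , i] <- preprocess_image(records$path[i], size, normalize)
  }
  list(x = x, y = as.integer(records$label == "malignant"))
}

## ---- augmentation ------------------------------------------------------------

rotate90 <- function(img) aperm(img[dim(img)[1]:1, , , drop = FALSE], c(2L, 1L, 3L))
mirror_horizontal <- function(img) img[, dim(img)[2]:1, , drop = FALSE]
mirror_vertical <- function(img) img[dim(img)[1]:1, , , drop = FALSE]

#' Rotation/mirror augmentation
#'
#' Produces exactly five variants of the input: rotations by 90/180/270
#' degrees and horizontal and vertical mirrors.  Together with the retained
#' original this expands a training set six-fold.  All five are elements of
#' the dihedral group acting on the image, so a symmetric input can yield
#' duplicates; the number of distinct variants is reported in the
#' `n_distinct` attribute (duplicates are not an error).
#'
#' @param img `(H, W, C)` image array (square images keep their shape under
#'   rotation; augmentation is applied after resizing).
#' @return named list of five image arrays (`rot90`, `rot180`, `rot270`,
#'   `mirror_h`, `mirror_v`) with attribute `n_distinct`.
#' @export
augment_image <- function(img) {
  d <- dim(img)
  if (is.null(d) || length(d) != 3L) stop("image must be an (H, W, C) array")
  r90 <- rotate90(img)
  r180 <- rotate90(r90)
  r270 <- rotate90(r180)
  out <- list(rot90 = r90, rot180 = r180, rot270 = r270,
              mirror_h = mirror_horizontal(img),
              mirror_v = mirror_vertical(img))
  variants <- c(list(original = img), out)
  dup <- logical(length(variants))
  for (i in seq_along(variants)[-1L]) {
    for (j in seq_len(i - 1L)) {
      if (!dup[i] && isTRUE(all.equal(variants[[i]], variants[[j]],
                                      check.attributes = FALSE))) {
        dup[i] <- TRUE
      }
    }
  }
  attr(out, "n_distinct") <- sum(!dup[-1L])
  out
}

# expand a preprocessed batch with the five augmentation variants
augment_batch <- function(x, y) {
  d <- dim(x)
  out <- array(0, dim = c(d[1], d[2], d[3], d[4] * 6L))
  out[, , , seq_len(d[4])] <- x
  for (i in seq_len(d[4])) {
    a <- augment_image(x[, , , i])
    for (j in seq_along(a)) out[, , , d[4] * j + i] <- a[[j]]
  }
  list(x = out, y = rep.int(y, 6L))
}
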
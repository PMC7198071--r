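# Synthetic BreakHis-emulating dataset generator.  Images are simple H&E
# caricatures: elliptical "nuclei" blobs on a stained background.  The two
# classes differ in background hue (pink vs purple), nucleus density, size
# and shape irregularity, with magnification simulated by blob scale and a
# per-patient hue jitter so that image-level and patient-disjoint splits
# measurably differ.  The textures are synthetic fixtures for exercising the
# pipeline, not a simulation of histology.

#' Specification of a synthetic dataset
#'
#' The default texture parameters put the two classes well apart on several
#' axes (background color, nucleus density, irregularity), which guarantees
#' that the classes are learnable by a small network.  The `overlap` knob
#' linearly pulls both classes toward their common midpoint: at `overlap = 1`
#' the class distributions coincide and no classifier can beat chance --
#' useful as a negative control.
#'
#' @param n_patients_benign,n_patients_malignant patients per class.
#' @param images_per_patient_per_magnification images per patient and
#'   magnification.
#' @param magnifications subset of 40/100/200/400.
#' @param image_size square image side in pixels (down to 32 for fast tests).
#' @param overlap class-overlap knob in \[0, 1\]; 0 = fully separable
#'   defaults, 1 = indistinguishable classes.
#' @param patient_jitter_sd per-patient background hue jitter (RGB units).
#' @param seed integer; generation is fully deterministic given the seed.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_patients_benign = 5L,
                           n_patients_malignant = 5L,
                           images_per_patient_per_magnification = 2L,
                           magnifications = c(40L, 100L, 200L, 400L),
                           image_size = 224L,
                           overlap = 0,
                           patient_jitter_sd = 0.02,
                           seed = 1L) {
  stopifnot(n_patients_benign >= 1, n_patients_malignant >= 1,
            images_per_patient_per_magnification >= 1,
            all(magnifications %in% .magnifications),
            image_size >= 32, overlap >= 0, overlap <= 1)
  base <- list(
    benign = list(background = c(0.92, 0.75, 0.85),
                  nucleus = c(0.48, 0.28, 0.58),
                  density = 6,          # blobs per 64x64 tile at 100x
                  radius = c(3.5, 5.5), # pixels at 100x on a 64-pixel tile
                  irregularity = 0.12,
                  speckle_sd = 0.01),
    malignant = list(background = c(0.68, 0.48, 0.80),
                     nucleus = c(0.30, 0.12, 0.46),
                     density = 18,
                     radius = c(1.8, 3.4),
                     irregularity = 0.55,
                     speckle_sd = 0.05)
  )
  if (overlap > 0) {
    mid <- Map(function(a, b) (a + b) / 2, base$benign, base$malignant)
    blend <- function(p) Map(function(a, m) a + overlap * (m - a), p, mid)
    base <- list(benign = blend(base$benign), malignant = blend(base$malignant))
  }
  structure(list(n_patients_benign = as.integer(n_patients_benign),
                 n_patients_malignant = as.integer(n_patients_malignant),
                 images_per_patient_per_magnification =
                   as.integer(images_per_patient_per_magnification),
                 magnifications = as.integer(sort(magnifications)),
                 image_size = as.integer(image_size),
                 overlap = overlap,
                 patient_jitter_sd = patient_jitter_sd,
                 texture = base,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# render one synthetic histology caricature; RNG state supplies all randomness
render_synthetic_image <- function(params, jitter, magnification, size) {
  bg <- pmin(pmax(params$background + jitter, 0), 1)
  img <- array(rep(bg, each = size * size), dim = c(size, size, 3L))
  scale <- sqrt(magnification / 100) * size / 64
  n_blobs <- stats::rpois(1L, params$density * (size / 64)^2 /
                            (magnification / 100))
  xs <- seq_len(size)
  for (b in seq_len(n_blobs)) {
    cx <- stats::runif(1, 1, size)
    cy <- stats::runif(1, 1, size)
    r <- stats::runif(1, params$radius[1], params$radius[2]) * scale
    elong <- 1 + params$irregularity * abs(stats::rnorm(1))
    a <- r * elong
    bmin <- r / elong
    phi <- stats::runif(1, 0, pi)
    ext <- ceiling(2.2 * a)
    ri <- max(1L, floor(cy - ext)):min(size, ceiling(cy + ext))
    cj <- max(1L, floor(cx - ext)):min(size, ceiling(cx + ext))
    dy <- xs[ri] - cy
    dx <- xs[cj] - cx
    U <- outer(dy, rep(1, length(dx)))
    V <- outer(rep(1, length(dy)), dx)
    q <- ((U * cos(phi) + V * sin(phi)) / a)^2 +
      ((-U * sin(phi) + V * cos(phi)) / bmin)^2
    w <- 0.9 * exp(-q * q)
    for (c_ in 1:3) {
      img[ri, cj, c_] <- img[ri, cj, c_] * (1 - w) + params$nucleus[c_] * w
    }
  }
  if (params$speckle_sd > 0) {
    img <- img + stats::rnorm(length(img), sd = params$speckle_sd)
  }
  img <- img + stats::rnorm(length(img), sd = 0.01)
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic BreakHis-like dataset on disk
#'
#' Writes one PNG per (patient, magnification, replicate) under
#' `out_dir/<class>/<slide>/<mag>X/`, named in the BreakHis dialect
#' (`SOB_<B|M>_SY-<slide>-<mag>-<seq>.png`, so every file name round-trips
#' through [parse_breakhis_filename()]), plus a `manifest.csv`.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir output directory (created if needed).
#' @return the manifest as an image record data frame, invisibly; the
#'   manifest CSV path is in attribute `manifest`.
#' @export
generate_dataset <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  rows <- list()
  withr::with_seed(spec$seed, {
    for (lb in .labels) {
      n_pat <- if (lb == "benign") spec$n_patients_benign else spec$n_patients_malignant
      code <- if (lb == "benign") "B" else "M"
      params <- spec$texture[[lb]]
      for (p in seq_len(n_pat)) {
        slide <- sprintf("9%d-%04d", as.integer(lb == "malignant"), p)
        jitter <- stats::rnorm(3L, sd = spec$patient_jitter_sd)
        for (mag in spec$magnifications) {
          sub <- file.path(out_dir, lb, sprintf("SOB_%s_SY-%s", code, slide),
                           sprintf("%dX", mag))
          dir.create(sub, recursive = TRUE, showWarnings = FALSE)
          for (i in seq_len(spec$images_per_patient_per_magnification)) {
            img <- render_synthetic_image(params, jitter, mag, spec$image_size)
            fname <- sprintf("SOB_%s_SY-%s-%d-%03d.png", code, slide, mag, i)
            fpath <- file.path(sub, fname)
            png::writePNG(img, fpath)
            rows[[length(rows) + 1L]] <- data.frame(
              path = fpath, label = lb, patient_id = slide,
              magnification = mag, stringsAsFactors = FALSE)
          }
        }
      }
    }
  })
  records <- do.call(rbind, rows)
  manifest <- file.path(out_dir, "manifest.csv")
  write_manifest(records, manifest)
  attr(records, "manifest") <- manifest
  invisible(records)
}

#' Generate deterministic toy predictions with known per-patient accuracy
#'
#' For each patient, exactly `round(accuracy * N_p)` of its images are
#' marked correctly classified (which ones is decided by the seeded RNG),
#' giving fixtures with known patient scores for the recognition-rate
#' metrics.
#'
#' @param records image record data frame (e.g. a test split).
#' @param accuracy single value in \[0, 1\], or a named vector keyed by
#'   patient id.
#' @param seed integer seed.
#' @return prediction record data frame: the input records plus `pred_label`
#'   and `p_malignant`.
#' @export
generate_toy_predictions <- function(records, accuracy, seed = 1L) {
  records <- validate_records(records, "records")
  stopifnot(all(accuracy >= 0), all(accuracy <= 1))
  acc_for <- function(pid) {
    if (length(accuracy) == 1L && is.null(names(accuracy))) return(accuracy)
    if (!pid %in% names(accuracy)) stop("no accuracy given for patient ", pid)
    accuracy[[pid]]
  }
  correct <- logical(nrow(records))
  withr::with_seed(seed, {
    for (pid in unique(records$patient_id)) {
      sel <- which(records$patient_id == pid)
      n_ok <- round(acc_for(pid) * length(sel))
      correct[sel[sample.int(length(sel))[seq_len(n_ok)]]] <- TRUE
    }
  })
  other <- ifelse(records$label == "benign", "malignant", "benign")
  records$pred_label <- ifelse(correct, records$label, other)
  records$p_malignant <- ifelse(records$pred_label == "malignant", 0.9, 0.1)
  records
}
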
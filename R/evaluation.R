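# Evaluation statistics: patient recognition rate (PRR) and image
# recognition rate (IRR), per-magnification breakdowns, and mean +/- sd
# aggregation over repeated runs.
#
# A prediction record set is an image record data frame plus columns
# `pred_label` and `p_malignant`.

check_preds <- function(preds) {
  if (is.null(preds) || nrow(preds) == 0L) stop("empty prediction set")
  need <- c("label", "patient_id", "pred_label")
  miss <- setdiff(need, names(preds))
  if (length(miss)) stop("predictions are missing column(s): ",
                         paste(miss, collapse = ", "))
  preds
}

#' Patient recognition rate
#'
#' Every patient gets a score `N_rec / N_p` -- the fraction of that
#' patient's images classified correctly -- and the PRR is the unweighted
#' mean of the scores over the `N` distinct patients present.
#'
#' @param preds prediction record data frame.
#' @return list with `prr` and `patients` (per-patient table: patient_id,
#'   n_images, n_correct, score).
#' @export
compute_prr <- function(preds) {
  preds <- check_preds(preds)
  correct <- preds$pred_label == preds$label
  n_p <- tapply(correct, preds$patient_id, length)
  n_rec <- tapply(correct, preds$patient_id, sum)
  tab <- data.frame(patient_id = names(n_p),
                    n_images = as.integer(n_p),
                    n_correct = as.integer(n_rec),
                    score = as.numeric(n_rec / n_p),
                    stringsAsFactors = FALSE, row.names = NULL)
  list(prr = mean(tab$score), patients = tab)
}

#' Image recognition rate
#'
#' The fraction of all images whose predicted label equals the true label.
#'
#' @param preds prediction record data frame.
#' @return scalar in \[0, 1\].
#' @export
compute_irr <- function(preds) {
  preds <- check_preds(preds)
  mean(preds$pred_label == preds$label)
}

#' Recognition rates overall and per magnification
#'
#' PRR and IRR are computed over the whole prediction set and independently
#' within each magnification stratum.  In a stratum, a patient's image count
#' covers only its images at that magnification, and patients absent from a
#' stratum do not enter that stratum's patient count.
#'
#' @param preds prediction record data frame with a `magnification` column.
#' @return object of class `evaluation_report`: list with `prr`, `irr`,
#'   `n_patients`, `n_images` and `by_magnification` (data frame with one
#'   row per magnification present).
#' @export
evaluate_by_magnification <- function(preds) {
  preds <- check_preds(preds)
  overall_prr <- compute_prr(preds)$prr
  mags <- sort(unique(preds$magnification))
  by_mag <- do.call(rbind, lapply(mags, function(m) {
    sub <- preds[preds$magnification == m, , drop = FALSE]
    data.frame(magnification = m,
               prr = compute_prr(sub)$prr,
               irr = compute_irr(sub),
               n_patients = length(unique(sub$patient_id)),
               n_images = nrow(sub))
  }))
  structure(list(prr = overall_prr, irr = compute_irr(preds),
                 n_patients = length(unique(preds$patient_id)),
                 n_images = nrow(preds),
                 by_magnification = by_mag),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("recognition rates over %d images from %d patients\n",
              x$n_images, x$n_patients))
  cat(sprintf("  overall  PRR %.4f  IRR %.4f\n", x$prr, x$irr))
  for (i in seq_len(nrow(x$by_magnification))) {
    r <- x$by_magnification[i, ]
    cat(sprintf("  %4dx    PRR %.4f  IRR %.4f  (%d patients, %d images)\n",
                r$magnification, r$prr, r$irr, r$n_patients, r$n_images))
  }
  invisible(x)
}

#' Aggregate evaluation reports over repeated runs
#'
#' @param reports list of at least two [evaluate_by_magnification()] reports.
#' @return data frame with one row per (metric, stratum): columns `metric`,
#'   `magnification` (`"overall"` or the factor), `mean`, `sd` (sample
#'   standard deviation, n - 1 denominator), `n_runs`.
#' @export
aggregate_runs <- function(reports) {
  if (length(reports) < 2L) stop("need at least 2 reports to aggregate")
  stopifnot(all(vapply(reports, inherits, logical(1), "evaluation_report")))
  strata <- c("overall", sort(unique(unlist(
    lapply(reports, function(r) r$by_magnification$magnification)))))
  rows <- list()
  for (metric in c("prr", "irr")) {
    for (s in strata) {
      vals <- vapply(reports, function(r) {
        if (s == "overall") return(r[[metric]])
        i <- match(as.integer(s), r$by_magnification$magnification)
        if (is.na(i)) NA_real_ else r$by_magnification[[metric]][i]
      }, numeric(1))
      vals <- vals[!is.na(vals)]
      rows[[length(rows) + 1L]] <- data.frame(
        metric = metric, magnification = as.character(s),
        mean = mean(vals), sd = stats::sd(vals), n_runs = length(vals))
    }
  }
  do.call(rbind, rows)
}

#' Read / write a predictions CSV
#'
#' Columns: `path,label,patient_id,magnification,pred_label,p_malignant`.
#'
#' @param preds prediction record data frame.
#' @param path CSV file path.
#' @return `load_predictions` returns the prediction data frame.
#' @export
write_predictions <- function(preds, path) {
  check_preds(preds)
  cols <- c(.manifest_cols, "pred_label", "p_malignant")
  utils::write.csv(preds[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
load_predictions <- function(path) {
  if (!file.exists(path)) stop("no such predictions file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$magnification <- as.integer(df$magnification)
  check_preds(validate_records(df, where = path))
}

#' Published image distribution of the BreakHis collection
#'
#' The class-by-magnification image counts and patient totals of the public
#' BreakHis breast-tumour collection, as commonly tabulated; useful for
#' planning real-data runs and as a reference for the synthetic generator's
#' layout.  The collection itself is an optional input and never required.
#'
#' @return data frame with columns `magnification`, `benign`, `malignant`,
#'   plus attribute `patients` (named vector: benign, malignant).
#' @export
breakhis_distribution <- function() {
  df <- data.frame(
    magnification = c(40L, 100L, 200L, 400L),
    benign = c(625L, 644L, 623L, 588L),
    malignant = c(1370L, 1437L, 1390L, 1232L)
  )
  attr(df, "patients") <- c(benign = 24L, malignant = 58L)
  df
}
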
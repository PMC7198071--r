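# Recognition-rate metrics and run aggregation.

test_that("PRR is the unweighted mean of patient scores", {
  fix <- two_patient_fixture()
  r <- compute_prr(fix)
  expect_equal(r$prr, 0.625)                      # (3/4 + 1/2) / 2
  expect_equal(sort(r$patients$score), c(0.5, 0.75))
  expect_equal(compute_irr(fix), 4 / 6)           # the metrics differ
  all_ok <- fix
  all_ok$pred_label <- all_ok$label
  expect_equal(compute_prr(all_ok)$prr, 1)
  all_bad <- fix
  all_bad$pred_label <- "benign"
  expect_equal(compute_irr(all_bad), 0)
  expect_error(compute_prr(fix[0, ]), "empty")
  expect_error(compute_irr(fix[0, ]), "empty")
})

test_that("PRR matches an independent group-by oracle on 50 random patients", {
  set.seed(40)
  rows <- do.call(rbind, lapply(1:50, function(p) {
    n <- sample(1:8, 1)
    data.frame(path = sprintf("p%d_%d.png", p, seq_len(n)),
               label = sample(c("benign", "malignant"), n, replace = TRUE),
               patient_id = sprintf("P%02d", p),
               magnification = sample(c(40L, 100L, 200L, 400L), n, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  rows$pred_label <- ifelse(stats::runif(nrow(rows)) < 0.7, rows$label,
                            ifelse(rows$label == "benign", "malignant", "benign"))
  got <- compute_prr(rows)$prr
  # oracle: explicit loop over patients
  scores <- vapply(unique(rows$patient_id), function(pid) {
    sub <- rows[rows$patient_id == pid, ]
    sum(sub$pred_label == sub$label) / nrow(sub)
  }, numeric(1))
  expect_equal(got, mean(scores), tolerance = 1e-12)
  expect_equal(compute_irr(rows), mean(rows$pred_label == rows$label))
})

test_that("PRR equals IRR exactly when patients carry equal image counts", {
  set.seed(41)
  for (rep_ in 1:5) {
    n_per <- sample(2:5, 1)
    rows <- do.call(rbind, lapply(1:8, function(p) {
      data.frame(path = sprintf("q%d_%d.png", p, seq_len(n_per)),
                 label = "malignant", patient_id = sprintf("Q%d", p),
                 magnification = 40L, stringsAsFactors = FALSE)
    }))
    rows$pred_label <- sample(c("benign", "malignant"), nrow(rows),
                              replace = TRUE)
    expect_equal(compute_prr(rows)$prr, compute_irr(rows), tolerance = 1e-12)
  }
})

test_that("duplicating one patient's images moves IRR but not PRR", {
  fix <- two_patient_fixture()
  dup <- rbind(fix, fix[fix$patient_id == "B", ])
  expect_equal(compute_prr(dup)$prr, compute_prr(fix)$prr)
  expect_false(isTRUE(all.equal(compute_irr(dup), compute_irr(fix))))
})

test_that("per-magnification strata are evaluated independently and partition", {
  set.seed(42)
  recs <- make_records(n_patients = 8L, images_per = 8L, seed = 8)
  preds <- generate_toy_predictions(recs, 1.0, seed = 1)
  # introduce errors only at 400x
  at400 <- preds$magnification == 400L
  flip <- which(at400)[1:3]
  preds$pred_label[flip] <- ifelse(preds$label[flip] == "benign",
                                   "malignant", "benign")
  rep_ <- evaluate_by_magnification(preds)
  bm <- rep_$by_magnification
  expect_true(all(bm$prr[bm$magnification != 400L] == 1))
  expect_true(all(bm$irr[bm$magnification != 400L] == 1))
  expect_lt(bm$irr[bm$magnification == 400L], 1)
  expect_lt(bm$prr[bm$magnification == 400L], 1)
  expect_equal(sum(bm$n_images), rep_$n_images)

  # single-magnification input: stratum equals overall
  one <- preds[preds$magnification == 40L, ]
  r1 <- evaluate_by_magnification(one)
  expect_equal(r1$by_magnification$prr, r1$prr)
  expect_equal(r1$by_magnification$irr, r1$irr)

  # strata match per-stratum group-by oracles
  for (m in unique(preds$magnification)) {
    sub <- preds[preds$magnification == m, ]
    expect_equal(bm$irr[bm$magnification == m],
                 mean(sub$pred_label == sub$label))
  }
})

test_that("run aggregation reports mean and sample standard deviation", {
  mk <- function(prr, irr) {
    structure(list(prr = prr, irr = irr, n_patients = 4L, n_images = 12L,
                   by_magnification = data.frame(magnification = 40L,
                                                 prr = prr, irr = irr,
                                                 n_patients = 4L,
                                                 n_images = 12L)),
              class = "evaluation_report")
  }
  agg <- aggregate_runs(list(mk(0.88, 0.8), mk(0.90, 0.8), mk(0.92, 0.8)))
  row <- agg[agg$metric == "prr" & agg$magnification == "overall", ]
  expect_equal(row$mean, 0.90)
  expect_equal(row$sd, 0.02, tolerance = 1e-12)
  irr_row <- agg[agg$metric == "irr" & agg$magnification == "overall", ]
  expect_equal(irr_row$sd, 0)
  expect_error(aggregate_runs(list(mk(0.9, 0.9))), "at least 2")

  set.seed(43)
  vals <- stats::runif(3)
  agg2 <- aggregate_runs(lapply(vals, function(v) mk(v, v)))
  r2 <- agg2[agg2$metric == "prr" & agg2$magnification == "overall", ]
  # two-pass oracle
  mu <- sum(vals) / 3
  expect_equal(r2$mean, mu)
  expect_equal(r2$sd, sqrt(sum((vals - mu)^2) / 2))
})

test_that("predictions CSV round-trips", {
  fix <- two_patient_fixture()
  p <- withr::local_tempfile(fileext = ".csv")
  write_predictions(fix, p)
  back <- load_predictions(p)
  expect_equal(back$pred_label, fix$pred_label)
  expect_equal(compute_prr(back)$prr, 0.625)
})

test_that("published collection table sums to its printed totals", {
  tab <- breakhis_distribution()
  expect_equal(sum(tab$benign) + sum(tab$malignant), 7909L)
  expect_equal(sum(attr(tab, "patients")), 82L)
})
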
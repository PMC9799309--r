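test_that("oxidation labelling is inclusive at the minimum level", {
  expect_equal(label_from_oxidation(c(5.0, 4.6, 0.0, 65.6)),
               c(1L, 0L, 0L, 1L))
  expect_equal(label_from_oxidation(4.6, min_level = 4), 1L)
  expect_error(label_from_oxidation(-1))
})

test_that("label confusion counts match the benchmark internal dataset", {
  tab <- reference_tables()$forced_oxidation
  obs <- label_from_oxidation(tab$ox_percent)
  expect_equal(sum(obs), 6L)
  cm <- confusion_from_labels(obs, tab$pred_wcn_oh)
  expect_equal(unlist(cm[c("TP", "FN", "FP", "TN")]),
               c(TP = 6L, FN = 0L, FP = 0L, TN = 20L))
  cm_s <- confusion_from_labels(obs, tab$pred_ssasa)
  expect_equal(cm_s$FP, 2L)
  expect_equal(cm_s$TN, 18L)
  expect_equal(unlist(confusion_from_labels(rep(0, 3), rep(0, 3))),
               c(TP = 0L, FN = 0L, FP = 0L, TN = 3L))
  expect_error(confusion_from_labels(c(0, 1), 1), "length")
})

test_that("event-count matching follows TP = min(observed, predicted)", {
  one <- function(n, obs, pred)
    confusion_from_event_counts(data.frame(n_met = n, observed_events = obs,
                                           predicted_events = pred))
  expect_equal(unlist(one(4, 2, 2)), c(TP = 2L, FN = 0L, FP = 0L, TN = 2L))
  expect_equal(unlist(one(3, 1, 0)), c(TP = 0L, FN = 1L, FP = 0L, TN = 2L))
  expect_equal(unlist(one(3, 0, 2)), c(TP = 0L, FN = 0L, FP = 2L, TN = 1L))
  expect_error(one(3, 4, 0), "exceed")
})

test_that("the CST benchmark under WCN-OH misassigns exactly one of 46 events", {
  units <- cst_event_units("wcn_oh")
  expect_equal(sum(units$n_met), 46L)
  cm <- confusion_from_event_counts(units)
  expect_equal(unlist(cm[c("TP", "FN", "FP", "TN")]),
               c(TP = 8L, FN = 1L, FP = 0L, TN = 37L))
  ss <- sens_spec(cm)
  expect_equal(ss$sensitivity, 8 / 9, tolerance = 1e-12)
  expect_equal(ss$specificity, 1.0)
  # expansion into per-methionine outcomes preserves the cells
  out <- expand_event_outcomes(units)
  expect_equal(nrow(out), 46L)
  cm2 <- confusion_from_labels(out$observed, out$predicted)
  expect_equal(unlist(cm2), unlist(cm))
})

test_that("sensitivity and specificity handle undefined denominators", {
  ss <- sens_spec(metox:::new_confusion(8, 1, 0, 37))
  expect_equal(round(ss$sensitivity, 3), 0.889)
  expect_equal(ss$specificity, 1.0)
  ss2 <- sens_spec(metox:::new_confusion(5, 1, 0, 20))
  expect_equal(round(ss2$sensitivity, 3), 0.833)
  ss3 <- sens_spec(metox:::new_confusion(0, 0, 0, 5))
  expect_true(is.na(ss3$sensitivity))
  expect_false(ss3$sens_defined)
  expect_equal(ss3$specificity, 1.0)
})

test_that("label confusions agree with a brute-force recount oracle", {
  set.seed(555)
  for (case in 1:1000) {
    n <- sample(1:40, 1)
    obs <- rbinom(n, 1, runif(1))
    pred <- rbinom(n, 1, runif(1))
    cm <- confusion_from_labels(obs, pred)
    # independent recount: explicit per-element tallies
    tp <- fn <- fp <- tn <- 0L
    for (i in seq_len(n)) {
      if (obs[i] == 1 && pred[i] == 1) tp <- tp + 1L
      else if (obs[i] == 1) fn <- fn + 1L
      else if (pred[i] == 1) fp <- fp + 1L
      else tn <- tn + 1L
    }
    expect_identical(unlist(cm), c(TP = tp, FN = fn, FP = fp, TN = tn))
    ss <- sens_spec(cm)
    if (tp + fn > 0) expect_equal(ss$sensitivity, tp / (tp + fn))
    if (tn + fp > 0) expect_equal(ss$specificity, tn / (tn + fp))
  }
})

test_that("residue-resolved and event-count confusions agree when sets coincide", {
  set.seed(99)
  for (case in 1:20) {
    mols <- lapply(1:5, function(i) {
      n <- sample(2:6, 1)
      flags <- rbinom(n, 1, 0.3)
      list(obs = flags, pred = flags)   # residue-wise identical sets
    })
    cm_lab <- confusion_from_labels(unlist(lapply(mols, `[[`, "obs")),
                                    unlist(lapply(mols, `[[`, "pred")))
    cm_evt <- confusion_from_event_counts(data.frame(
      n_met = vapply(mols, function(m) length(m$obs), 1L),
      observed_events = vapply(mols, function(m) sum(m$obs), 1L),
      predicted_events = vapply(mols, function(m) sum(m$pred), 1L)))
    expect_identical(unlist(cm_lab), unlist(cm_evt))
    expect_equal(cm_evt$FN + cm_evt$FP, 0L)
  }
})

test_that("bootstrap is deterministic under a seed and degenerate on perfect data", {
  units <- cst_event_units("wcn_oh")
  b1 <- bootstrap_errors(units, n_reps = 50, seed = 7)
  b2 <- bootstrap_errors(units, n_reps = 50, seed = 7)
  expect_identical(b1[c("sens_mean", "sens_err", "spec_mean", "spec_err")],
                   b2[c("sens_mean", "sens_err", "spec_mean", "spec_err")])
  b3 <- bootstrap_errors(units, n_reps = 50, seed = 8)
  expect_false(identical(b1$sens_mean, b3$sens_mean))
  # predicted == observed everywhere: no error in either ratio
  perfect <- data.frame(observed = c(1, 1, 0, 0, 0, 1),
                        predicted = c(1, 1, 0, 0, 0, 1))
  bp <- bootstrap_errors(perfect, n_reps = 20, seed = 1)
  expect_equal(bp$sens_err, 0)
  expect_equal(bp$spec_err, 0)
  expect_equal(bp$sens_mean, 1)
  # bootstrap leaves the session RNG stream untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(bootstrap_errors(perfect, 10, 42))
  expect_identical(rnorm(1), before)
})

test_that("bootstrap error shrinks as the dataset is replicated", {
  units <- expand_event_outcomes(cst_event_units("wcn_oh"))
  errs <- vapply(c(1, 4, 16), function(k) {
    big <- units[rep(seq_len(nrow(units)), k), ]
    bootstrap_errors(big, n_reps = 50, seed = 11)$sens_err
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("undefined replicates are dropped and counted; all-undefined errors", {
  units <- data.frame(observed = c(1, 0, 0, 0, 0, 0, 0, 0),
                      predicted = c(1, 0, 0, 0, 0, 0, 0, 0))
  b <- bootstrap_errors(units, n_reps = 200, seed = 3)
  expect_gt(b$n_dropped_sens, 0)   # some resamples miss the lone positive
  expect_equal(b$n_dropped_spec, 0)
  all_neg <- data.frame(observed = 0, predicted = 0)
  expect_error(bootstrap_errors(data.frame(observed = integer(0),
                                           predicted = integer(0)), 10, 1),
               "no units")
})

test_that("semiquantitative metrics behave on canonical shapes", {
  x <- 1:10
  lin <- semiquant_metrics(x, 2 * x + 3)
  expect_equal(unlist(lin[c("R2", "pearson_r", "spearman_rho")]),
               c(R2 = 1, pearson_r = 1, spearman_rho = 1))
  const <- semiquant_metrics(rep(2, 5), c(1, 2, 3, 4, 5))
  expect_false(const$defined)
  expect_true(is.na(const$R2))
  cubic <- semiquant_metrics(x, x^3)
  expect_equal(cubic$spearman_rho, 1)
  expect_lt(cubic$pearson_r, 1)
})

# minimal prediction table covering the CST molecules for event-style joins
cst_flag_table <- function() {
  units <- cst_event_units("wcn_oh")
  do.call(rbind, lapply(seq_len(nrow(units)), function(i) {
    n <- units$n_met[i]
    flags <- c(rep(1L, units$predicted_events[i]),
               rep(0L, n - units$predicted_events[i]))
    data.frame(molecule_id = units$molecule_id[i], chain = "H",
               residue_label = as.character(seq_len(n)),
               flag_ssasa = flags, flag_dsasa = flags, flag_wcn = flags,
               flag_wcn_oh = flags, stringsAsFactors = FALSE)
  }))
}

test_that("high-level evaluation joins tables and reports both styles", {
  tab <- reference_tables()$forced_oxidation
  pred <- data.frame(molecule_id = tab$molecule, chain = "X",
                     residue_label = tab$met_id,
                     flag_ssasa = tab$pred_ssasa,
                     flag_dsasa = tab$pred_dsasa,
                     flag_wcn = tab$pred_wcn,
                     flag_wcn_oh = tab$pred_wcn_oh,
                     stringsAsFactors = FALSE)
  obs <- data.frame(molecule_id = tab$molecule, chain = "X",
                    residue_label = tab$met_id,
                    ox_percent = tab$ox_percent, stringsAsFactors = FALSE)
  ev <- evaluate_predictions(pred, obs, method = "wcn_oh", seed = 5)
  expect_equal(ev$sensitivity, 1.0)
  expect_equal(ev$specificity, 1.0)
  ev_w <- evaluate_predictions(pred, obs, method = "wcn", seed = 5)
  expect_equal(round(ev_w$sensitivity, 3), 0.833)
  expect_equal(ev_w$specificity, 1.0)
  # event-count style
  ev_e <- evaluate_predictions(
    cst_flag_table(), cst_event_units("wcn_oh")[, 1:3],
    method = "wcn_oh", seed = 5)
  expect_s3_class(ev_e, "metox_evaluation")
  expect_equal(ev_e$confusion$FN, 1L)
  # join failure names the unmatched site
  obs_bad <- obs; obs_bad$residue_label[1] <- "Met#99"
  expect_error(evaluate_predictions(pred, obs_bad, method = "wcn"),
               "Met#99")
})
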
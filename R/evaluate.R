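#' Label observed oxidation from a measured oxidation level
#'
#' A methionine counts as an observed oxidation event when its measured
#' oxidation percentage reaches the established minimum level (default 5%,
#' inclusive).
#'
#' @param ox_percent measured oxidation level(s) in percent.
#' @param min_level minimum oxidation level in percent (default 5).
#' @return integer 0/1 label(s).
#' @examples
#' label_from_oxidation(c(5.0, 4.6, 0))  # 1 0 0
#' @export
label_from_oxidation <- function(ox_percent, min_level = 5.0) {
  stopifnot(all(ox_percent >= 0))
  as.integer(ox_percent >= min_level)
}

new_confusion <- function(tp, fn, fp, tn) {
  structure(list(TP = as.integer(tp), FN = as.integer(fn),
                 FP = as.integer(fp), TN = as.integer(tn)),
            class = "metox_confusion")
}

#' Confusion matrix from residue-resolved labels
#'
#' @param observed 0/1 vector of observed oxidation labels.
#' @param predicted 0/1 vector of predicted flags, same length.
#' @return object of class `metox_confusion` with fields `TP`, `FN`,
#'   `FP`, `TN`.
#' @export
confusion_from_labels <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed (", length(observed), ") and predicted (",
         length(predicted), ") labels differ in length")
  observed <- as.integer(observed); predicted <- as.integer(predicted)
  stopifnot(all(observed %in% 0:1), all(predicted %in% 0:1))
  new_confusion(sum(observed & predicted), sum(observed & !predicted),
                sum(!observed & predicted), sum(!observed & !predicted))
}

#' Confusion matrix from per-molecule event counts
#'
#' When observed oxidation is known only as a per-molecule event count
#' (not which residue oxidized), predicted and observed events are matched
#' count-wise within each molecule: `TP = min(observed, predicted)`,
#' `FN = observed - TP`, `FP = predicted - TP`, and the remaining
#' methionines are true negatives. Cells are summed over molecules.
#'
#' @param per_molecule data.frame with columns `n_met`, `observed_events`,
#'   `predicted_events` (one row per molecule).
#' @return a `metox_confusion`.
#' @export
confusion_from_event_counts <- function(per_molecule) {
  need <- c("n_met", "observed_events", "predicted_events")
  miss <- setdiff(need, names(per_molecule))
  if (length(miss))
    stop("event-count table is missing column(s): ",
         paste(miss, collapse = ", "))
  with(per_molecule, {
    if (any(observed_events > n_met) || any(predicted_events > n_met))
      stop("event counts exceed the number of methionines in a molecule")
    if (any(observed_events < 0) || any(predicted_events < 0))
      stop("negative event counts")
    tp <- pmin(observed_events, predicted_events)
    fn <- observed_events - tp
    fp <- predicted_events - tp
    tn <- n_met - observed_events - fp
    new_confusion(sum(tp), sum(fn), sum(fp), sum(tn))
  })
}

#' Expand per-molecule event counts into per-methionine outcomes
#'
#' The count-matched confusion cells of [confusion_from_event_counts()],
#' spelled out as one `(observed, predicted)` outcome per methionine —
#' the unit set that methionine-level bootstrap resampling draws from.
#'
#' @inheritParams confusion_from_event_counts
#' @return data.frame with columns `observed`, `predicted`, one row per
#'   methionine.
#' @export
expand_event_outcomes <- function(per_molecule) {
  rows <- lapply(seq_len(nrow(per_molecule)), function(i) {
    r <- per_molecule[i, ]
    cm <- confusion_from_event_counts(r)
    data.frame(
      observed = rep(c(1L, 1L, 0L, 0L), c(cm$TP, cm$FN, cm$FP, cm$TN)),
      predicted = rep(c(1L, 0L, 1L, 0L), c(cm$TP, cm$FN, cm$FP, cm$TN)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.metox_confusion <- function(x, ...) {
  # TP FN on the first row; FP TN on the second
  cat("Confusion matrix (rows: observed +/-; columns: predicted +/-):\n")
  cat(sprintf("  %4d %4d\n  %4d %4d\n", x$TP, x$FN, x$FP, x$TN))
  ss <- sens_spec(x)
  cat(sprintf("  sensitivity %s, specificity %s\n",
              fmt_ratio(ss$sensitivity), fmt_ratio(ss$specificity)))
  invisible(x)
}

fmt_ratio <- function(v) if (is.na(v)) "undefined" else sprintf("%.3f", v)

#' Sensitivity and specificity of a confusion matrix
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`. An
#' undefined ratio (empty denominator) is reported as `NA` with the
#' corresponding `*_defined` flag set to `FALSE`, never silently as 0.
#'
#' @param confusion a `metox_confusion`.
#' @return list with `sensitivity`, `specificity`, `sens_defined`,
#'   `spec_defined`.
#' @export
sens_spec <- function(confusion) {
  pos <- confusion$TP + confusion$FN
  neg <- confusion$TN + confusion$FP
  list(sensitivity = if (pos > 0) confusion$TP / pos else NA_real_,
       specificity = if (neg > 0) confusion$TN / neg else NA_real_,
       sens_defined = pos > 0, spec_defined = neg > 0)
}

#' Bootstrap errors on sensitivity and specificity
#'
#' Resamples the evaluation units with replacement `n_reps` times,
#' recomputes sensitivity and specificity per replicate and reports their
#' mean and standard deviation across replicates. Replicates in which a
#' ratio is undefined (no positives or no negatives drawn) are dropped
#' from that ratio's statistics and counted. Deterministic under a fixed
#' seed; the RNG state of the session is left untouched.
#'
#' The resampling unit is whatever one row of `units` is: per-methionine
#' `(observed, predicted)` outcomes for residue-resolved data, or
#' per-molecule `(n_met, observed_events, predicted_events)` tuples for
#' event-count data (detected from the columns).
#'
#' @param units data.frame of resampling units (see above).
#' @param n_reps number of bootstrap replicates (default 50, >= 2).
#' @param seed RNG seed; required and logged in the result.
#' @return object of class `metox_bootstrap`: list with `sens_mean`,
#'   `sens_err`, `spec_mean`, `spec_err`, `n_dropped_sens`,
#'   `n_dropped_spec`, `n_reps`, `seed`.
#' @export
bootstrap_errors <- function(units, n_reps = 50L, seed = 20221229L) {
  stopifnot(n_reps >= 2)
  per_mol <- all(c("n_met", "observed_events", "predicted_events") %in%
                 names(units))
  if (!per_mol && !all(c("observed", "predicted") %in% names(units)))
    stop("units must be per-methionine (observed, predicted) or ",
         "per-molecule (n_met, observed_events, predicted_events) records")
  n <- nrow(units)
  if (n == 0L) stop("no units to resample")
  conf_of <- if (per_mol) confusion_from_event_counts else
    function(u) confusion_from_labels(u$observed, u$predicted)
  sens <- spec <- numeric(n_reps)
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      u <- units[sample.int(n, n, replace = TRUE), , drop = FALSE]
      ss <- sens_spec(conf_of(u))
      sens[r] <- ss$sensitivity
      spec[r] <- ss$specificity
    }
  })
  if (all(is.na(sens)) && all(is.na(spec)))
    stop("all bootstrap replicates had undefined ratios")
  structure(list(
    sens_mean = mean(sens, na.rm = TRUE),
    sens_err = stats::sd(sens, na.rm = TRUE),
    spec_mean = mean(spec, na.rm = TRUE),
    spec_err = stats::sd(spec, na.rm = TRUE),
    n_dropped_sens = sum(is.na(sens)), n_dropped_spec = sum(is.na(spec)),
    n_reps = as.integer(n_reps), seed = as.integer(seed)),
    class = "metox_bootstrap")
}

# evaluate `expr` under a private RNG stream, restoring session state
with_seed <- function(seed, expr) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit(if (is.null(old))
    rm(".Random.seed", envir = env) else
    assign(".Random.seed", old, envir = env))
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' @export
print.metox_bootstrap <- function(x, ...) {
  cat(sprintf(
    "Bootstrap (%d replicates, seed %d):\n  sensitivity %.2f±%.2f (%d undefined dropped)\n  specificity %.2f±%.2f (%d undefined dropped)\n",
    x$n_reps, x$seed, x$sens_mean, x$sens_err, x$n_dropped_sens,
    x$spec_mean, x$spec_err, x$n_dropped_spec))
  invisible(x)
}

#' Semiquantitative agreement between a descriptor and oxidation levels
#'
#' Ordinary least-squares R² of the oxidation level on the descriptor,
#' plus Pearson and Spearman correlation coefficients, for ranking-style
#' use of the continuous descriptors. Zero variance in either input makes
#' all three undefined (`NA`, flagged).
#'
#' @param descriptor_values numeric descriptor vector.
#' @param ox_percent measured oxidation levels, same length (>= 3).
#' @return list with `R2`, `pearson_r`, `spearman_rho`, `defined`.
#' @export
semiquant_metrics <- function(descriptor_values, ox_percent) {
  stopifnot(length(descriptor_values) == length(ox_percent),
            length(ox_percent) >= 3)
  if (stats::var(descriptor_values) == 0 || stats::var(ox_percent) == 0)
    return(list(R2 = NA_real_, pearson_r = NA_real_,
                spearman_rho = NA_real_, defined = FALSE))
  fit <- stats::lm(ox_percent ~ descriptor_values)
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((ox_percent - mean(ox_percent))^2)
  list(R2 = r2,
       pearson_r = stats::cor(descriptor_values, ox_percent),
       spearman_rho = stats::cor(descriptor_values, ox_percent,
                                 method = "spearman"),
       defined = TRUE)
}

#' Evaluate a prediction table against observed oxidation data
#'
#' Joins a prediction table with an observed table on
#' `(molecule_id, chain, residue_label)` (residue-resolved observed data
#' with an `ox_percent` column), or consumes a per-molecule event-count
#' table (`molecule_id`, `n_met`, `observed_events`), and produces the
#' full evaluation: confusion matrix, point sensitivity/specificity,
#' bootstrap errors, and — for residue-resolved data — semiquantitative
#' correlation metrics per continuous descriptor if a descriptor table is
#' supplied.
#'
#' @param predictions a `metox_predictions` table.
#' @param observed observed table (see above).
#' @param method which flag column to evaluate: `"ssasa"`, `"dsasa"`,
#'   `"wcn"` or `"wcn_oh"`.
#' @param min_level minimum oxidation level in percent (default 5).
#' @param n_reps bootstrap replicates (default 50).
#' @param seed bootstrap seed.
#' @param descriptors optional `metox_descriptors` table for the
#'   semiquantitative metrics.
#' @return object of class `metox_evaluation`.
#' @export
evaluate_predictions <- function(predictions, observed,
                                 method = c("wcn_oh", "ssasa", "dsasa",
                                            "wcn"),
                                 min_level = 5.0, n_reps = 50L,
                                 seed = 20221229L, descriptors = NULL) {
  method <- match.arg(method)
  flag_col <- paste0("flag_", method)
  event_style <- all(c("n_met", "observed_events") %in% names(observed))
  if (event_style) {
    pred_events <- stats::aggregate(
      predictions[[flag_col]],
      by = list(molecule_id = predictions$molecule_id), FUN = sum)
    names(pred_events)[2] <- "predicted_events"
    units <- merge(observed, pred_events, by = "molecule_id", all.x = TRUE)
    if (any(is.na(units$predicted_events)))
      stop("no predictions for molecule(s): ",
           paste(units$molecule_id[is.na(units$predicted_events)],
                 collapse = ", "))
    confusion <- confusion_from_event_counts(units)
    boot_units <- units
    semiquant <- NULL
  } else {
    need <- c("molecule_id", "chain", "residue_label", "ox_percent")
    miss <- setdiff(need, names(observed))
    if (length(miss))
      stop("observed table is missing column(s): ",
           paste(miss, collapse = ", "))
    keys_p <- with(predictions, paste(molecule_id, chain, residue_label,
                                      sep = "\r"))
    keys_o <- with(observed, paste(molecule_id, chain, residue_label,
                                   sep = "\r"))
    unmatched <- setdiff(keys_o, keys_p)
    if (length(unmatched))
      stop("observed sites with no prediction: ",
           paste(gsub("\r", ":", unmatched), collapse = ", "))
    m <- match(keys_o, keys_p)
    obs_lab <- label_from_oxidation(observed$ox_percent, min_level)
    pred_lab <- predictions[[flag_col]][m]
    confusion <- confusion_from_labels(obs_lab, pred_lab)
    boot_units <- data.frame(observed = obs_lab, predicted = pred_lab)
    semiquant <- if (!is.null(descriptors)) {
      keys_d <- with(descriptors, paste(molecule_id, chain, residue_label,
                                        sep = "\r"))
      dm <- match(keys_o, keys_d)
      col <- c(ssasa = "sSASA_rel", dsasa = "dSASA_rel", wcn = "WCN",
               wcn_oh = "WCN")[method]
      semiquant_metrics(descriptors[[col]][dm], observed$ox_percent)
    }
  }
  point <- sens_spec(confusion)
  boot <- bootstrap_errors(boot_units, n_reps = n_reps, seed = seed)
  structure(list(method = method, confusion = confusion,
                 sensitivity = point$sensitivity,
                 specificity = point$specificity,
                 bootstrap = boot, semiquant = semiquant,
                 n_units = nrow(boot_units)),
            class = "metox_evaluation")
}

#' @export
print.metox_evaluation <- function(x, ...) {
  cat("Evaluation of method '", x$method, "' (", x$n_units,
      " unit(s))\n", sep = "")
  print(x$confusion)
  print(x$bootstrap)
  if (!is.null(x$semiquant) && isTRUE(x$semiquant$defined))
    cat(sprintf("  semiquantitative: R2 %.2f, Pearson %.2f, Spearman %.2f\n",
                x$semiquant$R2, x$semiquant$pearson_r,
                x$semiquant$spearman_rho))
  invisible(x)
}

#' @export
summary.metox_evaluation <- function(object, ...) {
  c(TP = object$confusion$TP, FN = object$confusion$FN,
    FP = object$confusion$FP, TN = object$confusion$TN,
    sensitivity = object$sensitivity, specificity = object$specificity,
    sens_boot_mean = object$bootstrap$sens_mean,
    sens_boot_err = object$bootstrap$sens_err,
    spec_boot_mean = object$bootstrap$spec_mean,
    spec_boot_err = object$bootstrap$spec_err)
}
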
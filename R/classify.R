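#' Oxidation-proneness threshold rules
#'
#' The method's decision thresholds. A methionine is flagged oxidation
#' prone when:
#' \describe{
#'   \item{sSASA / dSASA}{relative side-chain SASA strictly greater than
#'     `sasa_rel_cut` (default 15%).}
#'   \item{WCN}{at least `wcn_cut` water molecules within the shell
#'     (default 6; the comparison operator is configurable, see below).}
#'   \item{WCN-OH}{`WCN > wcn_cut`, or `WCN > wcn_floor` and
#'     `#OH > oh_cut` (all strict).}
#' }
#' The plain WCN rule is worded "at least 6" where it is introduced but
#' "greater than 6" where it reappears as condition 1 of the WCN-OH rule —
#' an internal inconsistency of the method's description. Both behaviours
#' are exposed: `wcn_op` controls the plain WCN rule (default `">="`,
#' matching "at least"), `wcn_oh_op` controls condition 1 of WCN-OH
#' (default `">"`). At the default thresholds the two differ only at
#' WCN exactly 6.
#'
#' @param sasa_rel_cut relative-SASA cut in percent (default 15).
#' @param wcn_cut water-count cut (default 6).
#' @param wcn_floor minimum WCN for WCN-OH condition 2 (default 0.1).
#' @param oh_cut hydroxyl-count cut for WCN-OH condition 2 (default 1.5).
#' @param wcn_op comparison for the plain WCN rule, `">="` or `">"`.
#' @param wcn_oh_op comparison for WCN-OH condition 1, `">"` or `">="`.
#' @return object of class `metox_thresholds`.
#' @export
ox_thresholds <- function(sasa_rel_cut = 15.0, wcn_cut = 6.0,
                          wcn_floor = 0.1, oh_cut = 1.5,
                          wcn_op = ">=", wcn_oh_op = ">") {
  stopifnot(wcn_floor < wcn_cut, sasa_rel_cut >= 0, wcn_cut >= 0,
            wcn_floor >= 0, oh_cut >= 0,
            wcn_op %in% c(">=", ">"), wcn_oh_op %in% c(">=", ">"))
  structure(list(sasa_rel_cut = sasa_rel_cut, wcn_cut = wcn_cut,
                 wcn_floor = wcn_floor, oh_cut = oh_cut,
                 wcn_op = wcn_op, wcn_oh_op = wcn_oh_op),
            class = "metox_thresholds")
}

#' @export
print.metox_thresholds <- function(x, ...) {
  cat("Oxidation-proneness thresholds:\n",
      "  sSASA/dSASA: relative SASA > ", x$sasa_rel_cut, "%\n",
      "  WCN:         WCN ", x$wcn_op, " ", x$wcn_cut, "\n",
      "  WCN-OH:      WCN ", x$wcn_oh_op, " ", x$wcn_cut,
      "  OR  (WCN > ", x$wcn_floor, " AND #OH > ", x$oh_cut, ")\n",
      sep = "")
  invisible(x)
}

#' Single-descriptor classification rules
#'
#' `classify_sasa` flags a relative SASA strictly above the cut;
#' `classify_wcn` flags a water coordination number of at least the cut
#' (operator configurable); `classify_wcn_oh` applies the combined rule:
#' condition 1, `WCN > wcn_cut`, or condition 2, `WCN > wcn_floor` and
#' `#OH > oh_cut`.
#'
#' @param rel_sasa relative SASA in percent (vectorised).
#' @param wcn water coordination number (vectorised).
#' @param oh hydroxyl coordination count (vectorised).
#' @param thresholds an [ox_thresholds()] object.
#' @return integer 0/1 flag(s).
#' @examples
#' th <- ox_thresholds()
#' classify_sasa(c(15, 38), th)        # 0 1 (strict at the boundary)
#' classify_wcn(c(12.32, 3.31), th)    # 1 0
#' classify_wcn_oh(3.31, 2.00, th)     # 1 (via condition 2)
#' @export
classify_sasa <- function(rel_sasa, thresholds = ox_thresholds()) {
  as.integer(rel_sasa > thresholds$sasa_rel_cut)
}

#' @rdname classify_sasa
#' @export
classify_wcn <- function(wcn, thresholds = ox_thresholds()) {
  cmp <- match.fun(thresholds$wcn_op)
  as.integer(cmp(wcn, thresholds$wcn_cut))
}

#' @rdname classify_sasa
#' @export
classify_wcn_oh <- function(wcn, oh, thresholds = ox_thresholds()) {
  cmp1 <- match.fun(thresholds$wcn_oh_op)
  as.integer(cmp1(wcn, thresholds$wcn_cut) |
             (wcn > thresholds$wcn_floor & oh > thresholds$oh_cut))
}

#' Apply all threshold rules to a descriptor table
#'
#' The `predict` method for [met_descriptors()] output: appends the four
#' binary oxidation-prone flags (one per method) to the per-site records.
#'
#' @param object a `metox_descriptors` table.
#' @param thresholds an [ox_thresholds()] object.
#' @param ... unused.
#' @return object of class `metox_predictions` (a data.frame): the site
#'   identity columns plus `flag_ssasa`, `flag_dsasa`, `flag_wcn`,
#'   `flag_wcn_oh`.
#' @export
predict.metox_descriptors <- function(object, thresholds = ox_thresholds(),
                                      ...) {
  classify_descriptors(object, thresholds)
}

#' @rdname predict.metox_descriptors
#' @param descriptors a `metox_descriptors` table (or any data.frame with
#'   the descriptor-table columns).
#' @export
classify_descriptors <- function(descriptors,
                                 thresholds = ox_thresholds()) {
  need <- c("molecule_id", "chain", "residue_label",
            "sSASA_rel", "dSASA_rel", "WCN", "OH")
  miss <- setdiff(need, names(descriptors))
  if (length(miss))
    stop("descriptor table is missing required column(s): ",
         paste(miss, collapse = ", "))
  out <- descriptors[, c("molecule_id", "chain", "residue_label")]
  out$flag_ssasa <- classify_sasa(descriptors$sSASA_rel, thresholds)
  out$flag_dsasa <- classify_sasa(descriptors$dSASA_rel, thresholds)
  out$flag_wcn <- classify_wcn(descriptors$WCN, thresholds)
  out$flag_wcn_oh <- classify_wcn_oh(descriptors$WCN, descriptors$OH,
                                     thresholds)
  attr(out, "thresholds") <- thresholds
  class(out) <- c("metox_predictions", "data.frame")
  out
}

#' @export
print.metox_predictions <- function(x, ...) {
  cat("Oxidation-proneness predictions (", nrow(x), " site(s))\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  for (m in c("ssasa", "dsasa", "wcn", "wcn_oh"))
    cat(sprintf("  %-7s events: %d\n", m, count_events(x, m)))
  invisible(x)
}

#' Count predicted oxidation events for one molecule
#'
#' @param predictions a `metox_predictions` table (rows of one molecule).
#' @param method one of `"ssasa"`, `"dsasa"`, `"wcn"`, `"wcn_oh"`.
#' @return non-negative integer: sum of the chosen flag.
#' @export
count_events <- function(predictions, method) {
  col <- paste0("flag_", match.arg(method,
                                   c("ssasa", "dsasa", "wcn", "wcn_oh")))
  if (!col %in% names(predictions))
    stop("prediction table lacks column ", col)
  sum(predictions[[col]])
}

PREDICTION_COLUMNS <- c("molecule_id", "chain", "residue_label",
                        "flag_ssasa", "flag_dsasa", "flag_wcn",
                        "flag_wcn_oh")

#' Write / read the prediction table contract
#'
#' Tab-delimited; the resolved thresholds are echoed in a `#` header
#' comment line for provenance.
#'
#' @param x a `metox_predictions` table.
#' @param path file path.
#' @return `path` (write) or the table (read).
#' @export
write_prediction_table <- function(x, path) {
  th <- attr(x, "thresholds")
  header <- if (!is.null(th))
    sprintf("thresholds: sasa_rel_cut=%g wcn_cut=%g (%s) wcn_floor=%g oh_cut=%g",
            th$sasa_rel_cut, th$wcn_cut, th$wcn_op, th$wcn_floor, th$oh_cut)
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_prediction_table
#' @export
read_prediction_table <- function(path) {
  x <- read_tsv_table(path, colClasses = c(residue_label = "character"))
  miss <- setdiff(PREDICTION_COLUMNS, names(x))
  if (length(miss))
    stop("prediction table is missing required column(s): ",
         paste(miss, collapse = ", "))
  class(x) <- c("metox_predictions", "data.frame")
  x
}
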
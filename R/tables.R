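#' Packaged reference benchmark tables
#'
#' Loads the three published benchmark tables the method was reported on,
#' shipped with the package as delimited text and verified against an md5
#' manifest on every load:
#' \describe{
#'   \item{cst_events}{14 clinical-stage antibodies: number of heavy-chain
#'     Fd methionines, observed oxidation-event count, and the predicted
#'     event count of each method (46 methionines in total, 9 observed
#'     events).}
#'   \item{crystal_descriptors}{11 heavy-chain methionines of the three
#'     antibodies with X-ray structures (Abituzumab, Ofatuzumab,
#'     Vesencumab): sSASA/dSASA (Å²), WCN and #OH, from the homology
#'     model and from the crystal structure.}
#'   \item{forced_oxidation}{26 methionines of 7 antibodies and 2
#'     antibody-drug conjugates with measured oxidation levels (% after
#'     0.1% tBHP, 24 h) and the per-method predicted flags.}
#' }
#'
#' @return named list of three data.frames.
#' @examples
#' tabs <- reference_tables()
#' sum(tabs$cst_events$n_met)  # 46
#' @export
reference_tables <- function() {
  dir <- system.file("extdata", package = "metox", mustWork = TRUE)
  manifest <- utils::read.table(file.path(dir, "MANIFEST.tsv"),
                                sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  for (i in seq_len(nrow(manifest))) {
    path <- file.path(dir, manifest$file[i])
    sum <- unname(tools::md5sum(path))
    if (!identical(sum, manifest$md5[i]))
      stop("packaging error: checksum mismatch for ", manifest$file[i],
           " (expected ", manifest$md5[i], ", got ", sum, ")")
  }
  load <- function(f) read_tsv_table(file.path(dir, f))
  list(cst_events = load("cst_events.tsv"),
       crystal_descriptors = load("crystal_descriptors.tsv"),
       forced_oxidation = load("forced_oxidation.tsv"))
}

#' Per-molecule event-count evaluation units from the CST benchmark
#'
#' Convenience accessor: the `cst_events` table reshaped into the
#' `(n_met, observed_events, predicted_events)` schema consumed by
#' [confusion_from_event_counts()] and [bootstrap_errors()] for a chosen
#' method.
#'
#' @param method one of `"adimab"`, `"ssasa"`, `"dsasa"`, `"wcn"`,
#'   `"wcn_oh"`.
#' @return data.frame with columns `molecule_id`, `n_met`,
#'   `observed_events`, `predicted_events`.
#' @export
cst_event_units <- function(method = c("wcn_oh", "wcn", "ssasa", "dsasa",
                                       "adimab")) {
  method <- match.arg(method)
  tab <- reference_tables()$cst_events
  data.frame(molecule_id = tab$name, n_met = tab$n_met,
             observed_events = tab$observed_events,
             predicted_events = tab[[paste0("pred_", method)]],
             stringsAsFactors = FALSE)
}
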
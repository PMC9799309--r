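#' Count candidate atoms within a shell around a center atom
#'
#' Number of candidate atoms whose distance to the center atom is at most
#' `radius` (closed ball: the boundary is counted, so the convention is
#' deterministic). With a box, distances follow the minimum-image
#' convention for an orthorhombic cell. The center atom itself is never
#' counted.
#'
#' @param frame numeric `n` x 3 coordinate matrix (Å).
#' @param center_index index of the center atom.
#' @param candidates integer vector of candidate atom indices.
#' @param radius shell radius in Å (> 0).
#' @param box optional length-3 orthorhombic cell edges in Å.
#' @return non-negative integer count.
#' @examples
#' xyz <- rbind(c(0, 0, 0), c(3, 0, 0), c(5, 0, 0), c(7, 0, 0))
#' count_within_radius(xyz, 1, 2:4, 6)  # 2
#' @export
count_within_radius <- function(frame, center_index, candidates, radius,
                                box = NULL) {
  stopifnot(radius > 0)
  frame <- as.matrix(frame)
  candidates <- setdiff(as.integer(candidates), as.integer(center_index))
  if (length(candidates) == 0L) return(0L)
  d <- sweep(frame[candidates, , drop = FALSE], 2, frame[center_index, ])
  if (!is.null(box)) {
    if (any(box < 2 * radius))
      warning("box edge (", paste(sprintf("%.2f", box), collapse = ", "),
              " Å) is smaller than twice the shell radius; the shell ",
              "wraps onto itself under periodic images")
    d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
  }
  sum(rowSums(d^2) <= radius^2)
}

#' Per-site solvent-environment descriptors over an ensemble
#'
#' Computes, for each methionine site, the full descriptor record of the
#' method: static side-chain SASA (`sSASA`) on the reference coordinates,
#' dynamic SASA (`dSASA`) as the equal-weight mean of per-frame side-chain
#' SASA values, the two-shell water coordination number (`WCN`) as the mean
#' count of water oxygens within the shell of the sulfur atom, and the
#' hydroxyl coordination count (`OH`) as the mean count of Ser/Thr/Tyr
#' side-chain hydroxyl oxygens in the same shell. Absolute SASA values are
#' also expressed relative to the residue's maximum allowed area.
#'
#' SASA is computed with all solvent stripped from the context; the
#' coordination counts are computed with solvent present.
#'
#' @param x a `metox_ensemble` or a `metox_structure` (treated as a
#'   one-frame ensemble, so `dSASA == sSASA` and `WCN` equals the static
#'   count).
#' @param sites list of `metox_site` objects; default: all methionines of
#'   the topology.
#' @param params a [descriptor_params()] object.
#' @param static optional `metox_structure` providing the reference
#'   coordinates for `sSASA`; default: the first frame.
#' @param molecule_id identifier echoed into the output table.
#' @return object of class `metox_descriptors` (a data.frame) with columns
#'   `molecule_id`, `chain`, `residue_label`, `sSASA_abs`, `sSASA_rel`,
#'   `dSASA_abs`, `dSASA_rel`, `WCN`, `OH`, `n_frames`.
#' @export
met_descriptors <- function(x, sites = NULL, params = descriptor_params(),
                            static = NULL, molecule_id = "mol") {
  if (inherits(x, "metox_structure"))
    x <- as_ensemble(x, frame_coords(x))
  stopifnot(inherits(x, "metox_ensemble"))
  topo <- x$topology
  nf <- n_frames(x)
  if (nf < 1L) stop("ensemble has no frames")
  if (is.null(sites)) sites <- select_methionines(topo)
  if (length(sites) == 0L) return(empty_descriptors())
  waters <- select_water_oxygens(topo, params$water_resnames)
  hydroxyls <- select_hydroxyl_oxygens(topo)
  box <- if (params$use_pbc) topo$box else NULL
  rows <- lapply(sites, function(site) {
    wcn_f <- numeric(nf); oh_f <- numeric(nf); dsasa_f <- numeric(nf)
    for (f in seq_len(nf)) {
      fr <- x$coords[, , f, drop = TRUE]
      wcn_f[f] <- count_within_radius(fr, site$sulfur_index, waters,
                                      params$shell_radius, box)
      oh_f[f] <- count_within_radius(fr, site$sulfur_index, hydroxyls,
                                     params$shell_radius, box)
      dsasa_f[f] <- sidechain_sasa(fr, site, params, topology = topo)
    }
    s_coords <- if (is.null(static)) x$coords[, , 1, drop = TRUE] else
      frame_coords(static)
    s_topo <- if (is.null(static)) topo else static
    s_site <- if (is.null(static)) site else
      match_site(static, site)
    ssasa <- sidechain_sasa(s_coords, s_site, params, topology = s_topo)
    dsasa <- mean(dsasa_f)
    data.frame(molecule_id = molecule_id, chain = site$chain,
               residue_label = site$residue_label,
               sSASA_abs = ssasa,
               sSASA_rel = relative_sasa(ssasa, "MET", params),
               dSASA_abs = dsasa,
               dSASA_rel = relative_sasa(dsasa, "MET", params),
               WCN = mean(wcn_f), OH = mean(oh_f), n_frames = nf,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("metox_descriptors", "data.frame")
  out
}

match_site <- function(static, site) {
  cand <- select_methionines(static)
  for (s in cand)
    if (s$chain == site$chain && s$residue_label == site$residue_label)
      return(s)
  stop("site ", site$chain, ":", site$residue_label,
       " not found in the static reference structure")
}

empty_descriptors <- function() {
  out <- data.frame(molecule_id = character(), chain = character(),
                    residue_label = character(), sSASA_abs = numeric(),
                    sSASA_rel = numeric(), dSASA_abs = numeric(),
                    dSASA_rel = numeric(), WCN = numeric(), OH = numeric(),
                    n_frames = integer(), stringsAsFactors = FALSE)
  class(out) <- c("metox_descriptors", "data.frame")
  out
}

DESCRIPTOR_COLUMNS <- c("molecule_id", "chain", "residue_label",
                        "sSASA_abs", "sSASA_rel", "dSASA_abs", "dSASA_rel",
                        "WCN", "OH", "n_frames")

#' @export
print.metox_descriptors <- function(x, digits = 2, ...) {
  cat("Methionine solvent-environment descriptors (", nrow(x),
      " site(s), ", if (nrow(x)) x$n_frames[1] else 0, " frame(s))\n",
      sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Write / read the descriptor table contract
#'
#' Tab-delimited table with the fixed column set that the classifier and
#' evaluation stages read back. `#`-prefixed header comment lines carry
#' provenance and are skipped on reading.
#'
#' @param x a `metox_descriptors` data.frame.
#' @param path file path.
#' @param header optional character vector of provenance comment lines.
#' @return `path` (write) or the table (read).
#' @export
write_descriptor_table <- function(x, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# tab-delimited reader for the table contracts: lines starting with '#'
# are provenance comments; '#' elsewhere (e.g. in "Met#10" ids) is data
read_tsv_table <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  utils::read.table(text = lines, sep = "\t", header = TRUE,
                    comment.char = "", stringsAsFactors = FALSE, ...)
}

#' @rdname write_descriptor_table
#' @export
read_descriptor_table <- function(path) {
  x <- read_tsv_table(path, colClasses = c(residue_label = "character"))
  miss <- setdiff(DESCRIPTOR_COLUMNS, names(x))
  if (length(miss))
    stop("descriptor table is missing required column(s): ",
         paste(miss, collapse = ", "))
  class(x) <- c("metox_descriptors", "data.frame")
  x
}
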
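#' Residue names recognised as water
#'
#' Default set covering crystallographic and simulation water naming.
#' @export
WATER_RESNAMES <- c("HOH", "WAT", "SPC", "TIP3", "SOL", "T3P")

# backbone atoms (and backbone hydrogens) excluded from side-chain sets
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT", "H", "H1", "H2", "H3",
                    "HA", "HA2", "HA3", "HXT")

#' Locate methionine sites in a structure
#'
#' One site per MET residue (optionally MSE, selenomethionine, with SE
#' playing the sulfur role) that carries its side-chain sulfur. Sites are
#' ordered by chain, then residue number, then insertion code; residue
#' labels keep the insertion code verbatim (Kabat-style, e.g. `"100F"`).
#' A MET residue lacking its sulfur atom is skipped with a warning.
#'
#' @param structure a `metox_structure`.
#' @param mse_as_met treat MSE as MET (default `TRUE`).
#' @return list of `metox_site` objects with fields `chain`,
#'   `residue_label`, `resname`, `sulfur_index`, `sidechain_indices`.
#' @examples
#' s <- build_probe(probe_spec(n_waters_in = 2, seed = 1))$structure
#' select_methionines(s)[[1]]$residue_label
#' @export
select_methionines <- function(structure, mse_as_met = TRUE) {
  a <- structure$atoms
  resnames <- c("MET", if (mse_as_met) "MSE")
  is_met <- a$resname %in% resnames
  if (!any(is_met)) return(list())
  key <- paste(a$chain, a$resnum, a$inscode, sep = "\r")
  sites <- list()
  for (k in unique(key[is_met])) {
    idx <- which(key == k & is_met)
    sulfur <- idx[a$name[idx] %in% c("SD", "SE")]
    if (length(sulfur) == 0L) {
      warning("methionine ", a$chain[idx[1]], ":", a$resnum[idx[1]],
              a$inscode[idx[1]], " lacks its SD/SE sulfur; site skipped")
      next
    }
    side <- idx[!(a$name[idx] %in% BACKBONE_ATOMS)]
    sites[[length(sites) + 1L]] <- structure(
      list(chain = a$chain[idx[1]],
           residue_label = paste0(a$resnum[idx[1]], a$inscode[idx[1]]),
           resname = a$resname[idx[1]],
           sulfur_index = sulfur[1],
           sidechain_indices = side),
      class = "metox_site")
  }
  ord <- order(vapply(sites, `[[`, "", "chain"),
               vapply(sites, function(s) structure$atoms$resnum[s$sulfur_index],
                      integer(1)),
               vapply(sites, function(s) structure$atoms$inscode[s$sulfur_index],
                      ""))
  sites[ord]
}

#' @export
print.metox_site <- function(x, ...) {
  cat("metox_site ", x$chain, ":", x$residue_label, " (", x$resname,
      "), sulfur atom #", x$sulfur_index, ", ",
      length(x$sidechain_indices), " side-chain atoms\n", sep = "")
  invisible(x)
}

#' Water oxygen atom indices
#'
#' Indices of oxygen atoms belonging to residues named as water. Counting is
#' heavy-atom based: each water is represented by its oxygen, so hydrogen
#' presence never changes a count.
#'
#' @param structure a `metox_structure`.
#' @param water_resnames residue names treated as water.
#' @return integer vector of atom indices (possibly empty).
#' @export
select_water_oxygens <- function(structure, water_resnames = WATER_RESNAMES) {
  a <- structure$atoms
  which(a$resname %in% water_resnames & a$element == "O")
}

#' Hydroxyl oxygen atom indices
#'
#' Side-chain hydroxyl oxygens of serine (OG), threonine (OG1) and tyrosine
#' (OH). A residue with a truncated side chain simply contributes nothing.
#'
#' @param structure a `metox_structure`.
#' @return integer vector of atom indices (possibly empty).
#' @export
select_hydroxyl_oxygens <- function(structure) {
  a <- structure$atoms
  which((a$resname == "SER" & a$name == "OG") |
        (a$resname == "THR" & a$name == "OG1") |
        (a$resname == "TYR" & a$name == "OH"))
}

# protein context for SASA: everything that is not water (solvent stripped)
select_protein_atoms <- function(structure,
                                 water_resnames = WATER_RESNAMES) {
  which(!(structure$atoms$resname %in% water_resnames))
}
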
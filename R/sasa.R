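#' Default van der Waals radii (Å) by element
#'
#' Bondi-style radii for the elements that occur in protein/solvent
#' systems. Unknown elements fall back to 1.70 Å.
#' @export
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               SE = 1.90, P = 1.80, F = 1.47, CL = 1.75, BR = 1.85)

#' Maximum allowed solvent-accessible areas (Å²) per residue
#'
#' Theoretical maximum accessible surface areas used to express SASA as a
#' percentage of the fully exposed value (Tien-style normalisation).
#' Configurable through [descriptor_params()].
#' @export
MAX_SASA_REFERENCE <- c(
  ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
  GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
  LEU = 201.0, LYS = 236.0, MET = 224.4, PHE = 240.0, PRO = 159.0,
  SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0,
  MSE = 224.4)

#' Descriptor computation parameters
#'
#' Bundles every tunable of the descriptor stack: the 6 Å coordination
#' shell, the Shrake-Rupley quadrature, the vdW radii set and the
#' relative-SASA normalisation.
#'
#' @param shell_radius coordination-shell radius in Å (default 6.0).
#' @param probe_radius solvent probe radius in Å (default 1.4, water).
#' @param sphere_points Shrake-Rupley test points per atom (default 960).
#' @param use_pbc apply minimum-image distances when the structure carries
#'   a box (default `TRUE`).
#' @param radii_set named numeric vector, element -> vdW radius in Å.
#' @param max_sasa_reference named numeric vector, residue name -> maximum
#'   allowed area in Å².
#' @param water_resnames residue names treated as water.
#' @return object of class `metox_params`.
#' @export
descriptor_params <- function(shell_radius = 6.0, probe_radius = 1.4,
                              sphere_points = 960L, use_pbc = TRUE,
                              radii_set = VDW_RADII,
                              max_sasa_reference = MAX_SASA_REFERENCE,
                              water_resnames = WATER_RESNAMES) {
  stopifnot(shell_radius > 0, probe_radius >= 0, sphere_points >= 32)
  structure(list(shell_radius = shell_radius, probe_radius = probe_radius,
                 sphere_points = as.integer(sphere_points),
                 use_pbc = isTRUE(use_pbc), radii_set = radii_set,
                 max_sasa_reference = max_sasa_reference,
                 water_resnames = water_resnames),
            class = "metox_params")
}

# deterministic quasi-uniform points on the unit sphere (golden-spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley per-atom solvent-accessible surface area
#'
#' Classic test-point quadrature: each atom's sphere is inflated by the
#' probe radius and sampled with `sphere_points` quasi-uniform points; a
#' point is accessible if it lies outside every other atom's inflated
#' sphere. The per-atom area is the accessible fraction of the full
#' inflated-sphere area, so an isolated atom tends to
#' \eqn{4\pi (r + r_{probe})^2} as the point count grows.
#'
#' @param coords numeric `n` x 3 coordinate matrix (Å).
#' @param radii numeric vector of `n` per-atom vdW radii (Å), all > 0.
#' @param params a [descriptor_params()] object (probe radius and point
#'   count are taken from it).
#' @param atom_subset optional indices: compute areas only for these atoms
#'   (others still occlude). Default all atoms.
#' @return numeric vector of length `n` with accessible areas in Å²
#'   (`NA` outside `atom_subset` when a subset is given).
#' @examples
#' a <- shrake_rupley(matrix(0, 1, 3), 1.7, descriptor_params())
#' abs(a - 4 * pi * 3.1^2) / (4 * pi * 3.1^2) < 0.01
#' @export
shrake_rupley <- function(coords, radii, params = descriptor_params(),
                          atom_subset = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(length(radii) == n, all(radii > 0))
  if (is.null(atom_subset)) atom_subset <- seq_len(n)
  pts <- sphere_points(params$sphere_points)
  probe <- params$probe_radius
  inflated <- radii + probe
  areas <- rep(NA_real_, n)
  for (i in atom_subset) {
    ri <- inflated[i]
    d2 <- rowSums(sweep(coords, 2, coords[i, ])^2)
    nb <- which(d2 < (ri + inflated)^2 & seq_len(n) != i)
    if (any(d2[nb] == 0))
      warning("degenerate geometry: atom ", i,
              " coincides with a neighbour")
    if (length(nb) == 0L) {
      areas[i] <- 4 * pi * ri^2
      next
    }
    test <- pts * ri
    test <- sweep(test, 2, coords[i, ], "+")
    # test points (m x 3) vs neighbour spheres
    acc <- rep(TRUE, nrow(test))
    nb_r2 <- inflated[nb]^2
    for (jj in seq_along(nb)) {
      j <- nb[jj]
      if (!any(acc)) break
      dd <- sweep(test[acc, , drop = FALSE], 2, coords[j, ])
      acc[acc] <- rowSums(dd^2) > nb_r2[jj]
    }
    areas[i] <- 4 * pi * ri^2 * sum(acc) / nrow(test)
  }
  areas
}

#' Side-chain SASA of a methionine site
#'
#' Sum of Shrake-Rupley areas over the site's side-chain atoms, computed in
#' the context of all protein atoms with solvent stripped (SASA is a
#' protein-surface property; waters never occlude it).
#'
#' @param x a `metox_structure`, or a coordinate matrix congruent with
#'   `topology` (then `topology` must be supplied).
#' @param site a `metox_site` from [select_methionines()].
#' @param params a [descriptor_params()] object.
#' @param topology the `metox_structure` the coordinates belong to, when
#'   `x` is a bare coordinate matrix (ensemble frame).
#' @return side-chain accessible area in Å².
#' @export
sidechain_sasa <- function(x, site, params = descriptor_params(),
                           topology = NULL) {
  if (inherits(x, "metox_structure")) {
    topology <- x
    coords <- frame_coords(x)
  } else {
    if (is.null(topology)) stop("topology required with bare coordinates")
    coords <- as.matrix(x)
  }
  if (length(site$sidechain_indices) == 0L)
    stop("site has no side-chain atoms")
  context <- select_protein_atoms(topology, params$water_resnames)
  if (!all(site$sidechain_indices %in% context))
    stop("site side-chain atoms are not part of the protein context")
  sub <- coords[context, , drop = FALSE]
  radii <- atom_radii(topology$atoms$element[context], params$radii_set)
  target <- match(site$sidechain_indices, context)
  areas <- shrake_rupley(sub, radii, params, atom_subset = target)
  sum(areas[target])
}

atom_radii <- function(elements, radii_set) {
  r <- radii_set[elements]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Relative (percent of maximum) SASA
#'
#' @param abs_area absolute accessible area in Å².
#' @param resname residue name to normalise against (default `"MET"`).
#' @param params a [descriptor_params()] object.
#' @return percentage of the configured maximum allowed area. Values above
#'   100 are possible if the reference maximum is exceeded and are flagged
#'   with a warning.
#' @export
relative_sasa <- function(abs_area, resname = "MET",
                          params = descriptor_params()) {
  ref <- params$max_sasa_reference[resname]
  if (any(is.na(ref)))
    stop("no maximum-SASA reference for residue '",
         paste(resname[is.na(ref)], collapse = "', '"),
         "'; known residues: ",
         paste(names(params$max_sasa_reference), collapse = ", "))
  rel <- 100 * abs_area / unname(ref)
  if (any(rel > 100))
    warning("relative SASA exceeds 100% of the reference maximum")
  rel
}
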
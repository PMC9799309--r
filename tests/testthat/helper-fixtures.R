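# shared fixtures and independent oracles (built in code, no binary data)

# extended Gly-Met-Gly tripeptide, heavy atoms, idealized geometry
gmg_structure <- function() {
  atoms <- data.frame(
    name = c("N", "CA", "C", "O",
             "N", "CA", "C", "O", "CB", "CG", "SD", "CE",
             "N", "CA", "C", "O", "OXT"),
    element = c("N", "C", "C", "O",
                "N", "C", "C", "O", "C", "C", "S", "C",
                "N", "C", "C", "O", "O"),
    resname = c(rep("GLY", 4), rep("MET", 8), rep("GLY", 5)),
    chain = "A",
    resnum = c(rep(1L, 4), rep(2L, 8), rep(3L, 5)),
    inscode = "", altloc = "", occupancy = 1, het = FALSE,
    x = c(-7.2, -6.0, -4.8, -4.8, -3.6, -2.4, -1.2, -1.2, -2.4, -2.4,
          -2.4, -0.85, 0.0, 1.2, 2.4, 2.4, 3.45),
    y = c(0.4, -0.3, 0.5, 1.73, -0.1, 0.7, -0.1, -1.33, 1.58, 2.75,
          3.37, 4.27, 0.6, -0.2, 0.6, 1.83, -0.05),
    z = c(0, 0, 0, 0, 0, 0, 0, 0, 1.25, 2.22, 3.92, 3.92, 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE)
  structure(list(atoms = atoms, box = NULL), class = "metox_structure")
}

# brute-force shell-count oracle: explicit enumeration of the 27 periodic
# images per candidate, independent of the package's min-image arithmetic
oracle_count <- function(frame, center, candidates, radius, box = NULL) {
  frame <- as.matrix(frame)
  candidates <- setdiff(candidates, center)
  shifts <- if (is.null(box)) matrix(0, 1, 3) else
    as.matrix(expand.grid(-1:1, -1:1, -1:1)) %*% diag(box)
  n <- 0L
  for (j in candidates) {
    dmin <- min(sqrt(rowSums(
      sweep(shifts, 2, frame[j, ] - frame[center, ], "+")^2)))
    if (dmin <= radius) n <- n + 1L
  }
  n
}

# independent SASA oracle: biotite's Shrake-Rupley with the same vdW radii
biotite_sasa <- function(structure, probe = 1.4, npts = 1000) {
  pdb <- tempfile(fileext = ".pdb")
  write_pdb(structure, pdb)
  py <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, numpy as np",
    "import biotite.structure.io.pdb as pdb",
    "import biotite.structure as struc",
    "path, probe, npts = sys.argv[1], float(sys.argv[2]), int(sys.argv[3])",
    "arr = pdb.PDBFile.read(path).get_structure(model=1)",
    "rm = {'H':1.20,'C':1.70,'N':1.55,'O':1.52,'S':1.80,'SE':1.90,'P':1.80}",
    "radii = np.array([rm.get(e.upper(), 1.70) for e in arr.element])",
    "sasa = struc.sasa(arr, probe_radius=probe, vdw_radii=radii,",
    "                  point_number=npts)",
    "np.savetxt(sys.stdout, sasa, fmt='%.6f')"), py)
  out <- system2("python", c(py, pdb, probe, npts), stdout = TRUE)
  as.numeric(out)
}

# PDB text for a minimal methionine with altloc A/B sulfurs
altloc_met_pdb <- function() {
  c("ATOM      1  CB  MET A  10      -2.400  -1.400   0.000  1.00  0.00           C",
    "ATOM      2  CG  MET A  10      -1.810   0.000   0.000  1.00  0.00           C",
    "ATOM      3  SD AMET A  10       0.000   0.000   0.000  0.40  0.00           S",
    "ATOM      4  SD BMET A  10       0.200   0.000   0.000  0.60  0.00           S",
    "ATOM      5  CE  MET A  10       0.310   1.760   0.000  1.00  0.00           C",
    "END")
}
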
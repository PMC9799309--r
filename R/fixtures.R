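# idealized methionine heavy-atom template, side-chain sulfur at the origin
MET_TEMPLATE <- data.frame(
  name = c("N", "CA", "C", "O", "CB", "CG", "SD", "CE"),
  element = c("N", "C", "C", "O", "C", "C", "S", "C"),
  x = c(-4.63, -3.85, -4.60, -5.77, -2.40, -1.81, 0.00, 0.31),
  y = c(-1.62, -0.80, 0.45, 0.62, -1.40, 0.00, 0.00, 1.76),
  z = c(1.22, 0.35, -0.08, 0.26, 0.00, 0.00, 0.00, 0.00),
  stringsAsFactors = FALSE)

#' Specification of a synthetic solvated methionine probe
#'
#' Describes a ground-truth-known test structure: a single idealized
#' methionine whose sulfur sits at the origin, surrounded by water oxygens
#' and Ser/Thr/Tyr hydroxyl oxygens placed at controlled distances so
#' shell membership is unambiguous. "In" atoms are placed at sulfur
#' distances in `in_range` (default `[2.8, shell_radius - jitter]`), "out"
#' atoms in `out_range` (default `[shell_radius + jitter,
#' shell_radius + 10]`); no atom ever falls within `jitter` of the shell
#' boundary, so the closed-ball counting convention can never change a
#' fixture's truth. A minimum interatomic distance of 2.4 Å is enforced
#' among methionine, water and hydroxyl atoms.
#'
#' An optional occluding cage — a quasi-uniform spherical shell of carbon
#' atoms around the sulfur — buries the side chain for SASA purposes. The
#' cage is a purely geometric occluder (no packing realism is claimed): it
#' is exempt from the 2.4 Å rule with respect to shell waters, which is
#' harmless because waters are counted by sulfur-oxygen distance and are
#' stripped before any SASA computation.
#'
#' @param n_waters_in,n_waters_out waters inside / outside the shell.
#' @param n_ser_in,n_thr_in,n_tyr_in hydroxyl-bearing side chains (one
#'   oxygen each: SER OG, THR OG1, TYR OH) inside the shell.
#' @param n_hydroxyl_out hydroxyl oxygens outside the shell.
#' @param shell_radius shell radius in Å (default 6).
#' @param jitter exclusion margin around the shell boundary in Å
#'   (default 0.05).
#' @param in_range,out_range sulfur-distance ranges overriding the
#'   defaults (e.g. to make room for a cage).
#' @param cage_radius radius of the occluding carbon shell, or `NULL` for
#'   no cage.
#' @param n_cage number of cage atoms (default 60 when caged).
#' @param water_resnames residue name(s) for the waters, recycled
#'   (default `"HOH"`).
#' @param box optional orthorhombic box edges (Å).
#' @param seed RNG seed; fixtures are bit-reproducible under a fixed seed.
#' @return object of class `metox_probe_spec`.
#' @export
probe_spec <- function(n_waters_in = 0L, n_waters_out = 0L,
                       n_ser_in = 0L, n_thr_in = 0L, n_tyr_in = 0L,
                       n_hydroxyl_out = 0L, shell_radius = 6.0,
                       jitter = 0.05, in_range = NULL, out_range = NULL,
                       cage_radius = NULL, n_cage = 60L,
                       water_resnames = "HOH", box = NULL, seed = 1L) {
  stopifnot(n_waters_in >= 0, n_waters_out >= 0, n_ser_in >= 0,
            n_thr_in >= 0, n_tyr_in >= 0, n_hydroxyl_out >= 0,
            shell_radius > 0, jitter > 0)
  if (is.null(in_range)) in_range <- c(2.8, shell_radius - jitter)
  if (is.null(out_range))
    out_range <- c(shell_radius + jitter, shell_radius + 10)
  if (in_range[2] >= shell_radius - jitter + 1e-9)
    in_range[2] <- shell_radius - jitter
  if (out_range[1] < shell_radius + jitter)
    out_range[1] <- shell_radius + jitter
  structure(list(n_waters_in = as.integer(n_waters_in),
                 n_waters_out = as.integer(n_waters_out),
                 n_ser_in = as.integer(n_ser_in),
                 n_thr_in = as.integer(n_thr_in),
                 n_tyr_in = as.integer(n_tyr_in),
                 n_hydroxyl_out = as.integer(n_hydroxyl_out),
                 shell_radius = shell_radius, jitter = jitter,
                 in_range = in_range, out_range = out_range,
                 cage_radius = cage_radius, n_cage = as.integer(n_cage),
                 water_resnames = water_resnames, box = box,
                 seed = as.integer(seed)),
            class = "metox_probe_spec")
}

MIN_PLACEMENT_DIST <- 2.4

#' Build a synthetic solvated methionine probe
#'
#' Realises a [probe_spec()] as a `metox_structure` with exact
#' ground-truth shell counts: by construction the water coordination count
#' equals `n_waters_in` and the hydroxyl count equals
#' `n_ser_in + n_thr_in + n_tyr_in`.
#'
#' @param spec a [probe_spec()].
#' @return list with `structure` (a `metox_structure`), `ground_truth`
#'   (list `wcn`, `oh`), and bookkeeping (`water_indices`,
#'   `in_positions`, `out_positions` for ensemble scheduling).
#' @export
build_probe <- function(spec) {
  stopifnot(inherits(spec, "metox_probe_spec"))
  with_seed(spec$seed, build_probe_impl(spec))
}

build_probe_impl <- function(spec) {
  placed <- as.matrix(MET_TEMPLATE[, c("x", "y", "z")])
  place <- function(n, range) {
    out <- matrix(NA_real_, n, 3)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(5000)) {
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        p <- u * stats::runif(1, range[1], range[2])
        if (min(sqrt(rowSums(sweep(placed, 2, p)^2))) >=
            MIN_PLACEMENT_DIST) { ok <- TRUE; break }
      }
      if (!ok)
        stop("infeasible packing: cannot place atom ", i, " of ", n,
             " in [", range[1], ", ", range[2], "] Å without steric ",
             "overlap < ", MIN_PLACEMENT_DIST, " Å")
      out[i, ] <- p
      placed <<- rbind(placed, p)
    }
    out
  }
  n_w <- spec$n_waters_in + spec$n_waters_out
  w_in <- place(spec$n_waters_in, spec$in_range)
  w_out <- place(spec$n_waters_out, spec$out_range)
  # a reserve "out" position for every in-shell water (ensemble schedules
  # translate waters across the boundary without changing the topology)
  w_reserve <- place(spec$n_waters_in, spec$out_range)
  oh_in <- place(spec$n_ser_in + spec$n_thr_in + spec$n_tyr_in,
                 spec$in_range)
  oh_out <- place(spec$n_hydroxyl_out, spec$out_range)
  cage <- if (!is.null(spec$cage_radius))
    sphere_points(spec$n_cage) * spec$cage_radius else
    matrix(numeric(), 0, 3)

  oh_names <- c(rep("OG", spec$n_ser_in), rep("OG1", spec$n_thr_in),
                rep("OH", spec$n_tyr_in), rep("OG", spec$n_hydroxyl_out))
  oh_res <- c(rep("SER", spec$n_ser_in), rep("THR", spec$n_thr_in),
              rep("TYR", spec$n_tyr_in), rep("SER", spec$n_hydroxyl_out))
  w_res <- rep_len(spec$water_resnames, n_w)

  atoms <- rbind(
    data.frame(name = MET_TEMPLATE$name, element = MET_TEMPLATE$element,
               resname = "MET", chain = "A",
               resnum = 1L, inscode = "", altloc = "", occupancy = 1,
               het = FALSE, as.matrix_df(placed[seq_len(8), ]),
               stringsAsFactors = FALSE),
    if (nrow(cage)) data.frame(
      name = "CA", element = "C", resname = "GLY", chain = "C",
      resnum = seq_len(nrow(cage)), inscode = "", altloc = "",
      occupancy = 1, het = FALSE, as.matrix_df(cage),
      stringsAsFactors = FALSE),
    if (length(oh_names)) data.frame(
      name = oh_names, element = "O", resname = oh_res, chain = "S",
      resnum = seq_along(oh_names), inscode = "", altloc = "",
      occupancy = 1, het = FALSE, as.matrix_df(rbind(oh_in, oh_out)),
      stringsAsFactors = FALSE),
    if (n_w) data.frame(
      name = "O", element = "O", resname = w_res, chain = "W",
      resnum = seq_len(n_w), inscode = "", altloc = "", occupancy = 1,
      het = TRUE, as.matrix_df(rbind(w_in, w_out)),
      stringsAsFactors = FALSE))
  rownames(atoms) <- NULL
  struct <- structure(list(atoms = atoms, box = spec$box),
                      class = "metox_structure")
  water_idx <- which(atoms$chain == "W")
  list(structure = struct,
       ground_truth = list(
         wcn = spec$n_waters_in,
         oh = spec$n_ser_in + spec$n_thr_in + spec$n_tyr_in),
       water_indices = water_idx[seq_len(spec$n_waters_in)],
       in_positions = w_in, out_positions = w_reserve,
       spec = spec)
}

as.matrix_df <- function(m) {
  m <- matrix(m, ncol = 3)
  data.frame(x = m[, 1], y = m[, 2], z = m[, 3])
}

#' Build a synthetic ensemble with a scheduled water count per frame
#'
#' Takes a probe and a per-frame schedule of in-shell water counts and
#' produces an ensemble over the probe's fixed topology: in frame `f` the
#' first `schedule[f]` schedulable waters sit at their in-shell positions
#' and the rest are translated to reserve positions outside the shell. No
#' atom ever appears or disappears, so every frame is congruent with the
#' topology, and the exact per-frame counts — hence their time averages —
#' are known by construction.
#'
#' @param spec a [probe_spec()]; `n_waters_in` is the maximum schedulable
#'   count.
#' @param schedule integer vector of per-frame in-shell water counts, each
#'   in `[0, spec$n_waters_in]`.
#' @param frame_interval optional frame spacing in ps (metadata).
#' @return list with `ensemble` (a `metox_ensemble`), `ground_truth`
#'   (list `wcn_per_frame`, `wcn`, `oh`), and the underlying `probe`.
#' @export
build_ensemble <- function(spec, schedule, frame_interval = NULL) {
  probe <- build_probe(spec)
  schedule <- as.integer(schedule)
  if (length(schedule) < 1L) stop("schedule must contain at least one frame")
  if (any(schedule < 0L | schedule > spec$n_waters_in))
    stop("schedule counts must lie in [0, n_waters_in = ",
         spec$n_waters_in, "]")
  base <- frame_coords(probe$structure)
  frames <- array(base, dim = c(nrow(base), 3, length(schedule)))
  for (f in seq_along(schedule)) {
    k <- schedule[f]
    move <- seq_len(spec$n_waters_in) > k
    if (any(move))
      frames[probe$water_indices[move], , f] <-
        probe$out_positions[move, , drop = FALSE]
  }
  ens <- as_ensemble(probe$structure, frames,
                     frame_interval = frame_interval)
  list(ensemble = ens,
       ground_truth = list(wcn_per_frame = schedule,
                           wcn = mean(schedule),
                           oh = probe$ground_truth$oh),
       probe = probe)
}
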
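test_that("shell counting follows the closed-ball convention", {
  xyz <- rbind(c(0, 0, 0), c(3, 0, 0), c(5, 0, 0), c(7, 0, 0))
  expect_equal(count_within_radius(xyz, 1, 2:4, 6), 2L)
  # exactly on the boundary: counted
  xyz2 <- rbind(c(0, 0, 0), c(6, 0, 0))
  expect_equal(count_within_radius(xyz2, 1, 2, 6), 1L)
  expect_equal(count_within_radius(xyz2, 1, 2, 5.999), 0L)
  # the center is never its own neighbour
  expect_equal(count_within_radius(xyz, 1, 1:4, 6), 2L)
})

test_that("minimum-image counting wraps distances; tight boxes warn", {
  xyz <- rbind(c(0, 0, 0), c(9, 0, 0))
  expect_warning(n <- count_within_radius(xyz, 1, 2, 6, box = c(10, 10, 10)),
                 "twice the shell radius")
  expect_equal(n, 1L)   # image at 1 Å
  expect_equal(count_within_radius(xyz, 1, 2, 6, box = c(20, 20, 20)), 0L)
})

test_that("shell counts match the brute-force image-enumeration oracle", {
  set.seed(4001)
  for (case in 1:100) {
    n <- sample(5:40, 1)
    use_box <- case %% 2 == 0
    box <- if (use_box) runif(3, 14, 30)
    xyz <- if (use_box)
      cbind(runif(n, 0, box[1]), runif(n, 0, box[2]), runif(n, 0, box[3]))
    else matrix(runif(3 * n, -12, 12), ncol = 3)
    center <- sample(n, 1)
    cand <- sample(n, sample(n, 1))
    r <- runif(1, 2, 7)
    expect_equal(
      count_within_radius(xyz, center, cand, r, box = box),
      oracle_count(xyz, center, cand, r, box = box))
  }
})

test_that("an isolated atom recovers the closed-form sphere area", {
  pars <- descriptor_params()
  a <- shrake_rupley(matrix(0, 1, 3), 1.7, pars)
  exact <- 4 * pi * (1.7 + 1.4)^2
  expect_lt(abs(a - exact) / exact, 0.01)
  # two atoms far apart are both full spheres
  a2 <- shrake_rupley(rbind(c(0, 0, 0), c(100, 0, 0)), c(1.7, 1.7), pars)
  expect_lt(max(abs(a2 - exact)) / exact, 0.01)
})

test_that("a caged atom has zero accessible area; coincident atoms warn", {
  cage <- metox:::sphere_points(80) * 3.0
  coords <- rbind(c(0, 0, 0), cage)
  a <- shrake_rupley(coords, rep(1.7, nrow(coords)), descriptor_params(),
                     atom_subset = 1)
  expect_equal(a[1], 0)
  expect_warning(
    shrake_rupley(rbind(c(0, 0, 0), c(0, 0, 0)), c(1.7, 1.7),
                  descriptor_params(), atom_subset = 1),
    "degenerate")
})

test_that("accessible area shrinks monotonically as a neighbour approaches", {
  pars <- descriptor_params()
  areas <- vapply(c(10, 6, 4, 3, 2.4, 2), function(d)
    shrake_rupley(rbind(c(0, 0, 0), c(d, 0, 0)), c(1.7, 1.7), pars)[1],
    numeric(1))
  expect_true(all(diff(areas) <= 1e-9))
})

test_that("quadrature is converged at the default point count", {
  s <- build_probe(probe_spec(n_waters_in = 3, n_ser_in = 1,
                              seed = 9))$structure
  site <- select_methionines(s)[[1]]
  a960 <- sidechain_sasa(s, site, descriptor_params(sphere_points = 960))
  a4000 <- sidechain_sasa(s, site, descriptor_params(sphere_points = 4000))
  expect_lt(abs(a960 - a4000) / a4000, 0.02)
})

test_that("side-chain SASA agrees with an independent implementation", {
  gmg <- gmg_structure()
  site <- select_methionines(gmg)[[1]]
  mine <- sidechain_sasa(gmg, site)
  oracle <- sum(biotite_sasa(gmg)[site$sidechain_indices])
  expect_lt(abs(mine - oracle) / oracle, 0.05)
  # an extended, fully exposed side chain is a substantially open surface
  expect_gt(relative_sasa(mine), 50)
  # solvated probe peptide: waters in the structure must not occlude
  p <- build_probe(probe_spec(n_waters_in = 5, n_ser_in = 1, seed = 31))
  psite <- select_methionines(p$structure)[[1]]
  pm <- sidechain_sasa(p$structure, psite)
  dry <- p$structure
  dry$atoms <- dry$atoms[dry$atoms$chain != "W", , drop = FALSE]
  po <- sum(biotite_sasa(dry)[select_methionines(dry)[[1]]$sidechain_indices])
  expect_lt(abs(pm - po) / po, 0.05)
})

test_that("a methionine buried in a synthetic cage scores < 1 Å²", {
  p <- build_probe(probe_spec(cage_radius = 4.5, n_cage = 80, seed = 3))
  site <- select_methionines(p$structure)[[1]]
  expect_lt(sidechain_sasa(p$structure, site), 1)
})

test_that("relative SASA normalises against the residue maximum", {
  pars <- descriptor_params()
  expect_equal(relative_sasa(0, "MET", pars), 0)
  expect_equal(relative_sasa(pars$max_sasa_reference[["MET"]], "MET", pars),
               100)
  expect_equal(relative_sasa(pars$max_sasa_reference[["MET"]] / 2, "MET",
                             pars), 50)
  expect_error(relative_sasa(10, "XYZ", pars), "known residues")
  expect_warning(relative_sasa(300, "MET", pars), "exceeds 100%")
})

test_that("ensemble descriptors are exact frame averages of the schedule", {
  spec <- probe_spec(n_waters_in = 8, n_waters_out = 2, n_ser_in = 1,
                     n_tyr_in = 1, seed = 5)
  be <- build_ensemble(spec, schedule = c(4, 8))
  d <- met_descriptors(be$ensemble, molecule_id = "ens")
  expect_equal(d$WCN, 6.0)
  expect_equal(d$OH, 2.0)
  expect_equal(d$n_frames, 2L)
  # 100-frame randomized schedule: mean matches bookkeeping exactly
  set.seed(77)
  sched <- sample(0:8, 100, replace = TRUE)
  be2 <- build_ensemble(spec, schedule = sched)
  d2 <- met_descriptors(be2$ensemble)
  expect_identical(d2$WCN, mean(sched))
  expect_identical(d2$OH, 2)
})

test_that("a static structure degenerates to dSASA == sSASA and static WCN", {
  p <- build_probe(probe_spec(n_waters_in = 4, n_waters_out = 2,
                              n_thr_in = 1, seed = 17))
  d <- met_descriptors(p$structure)
  expect_equal(d$dSASA_abs, d$sSASA_abs)
  expect_equal(d$WCN, p$ground_truth$wcn)
  expect_equal(d$OH, p$ground_truth$oh)
  expect_equal(d$n_frames, 1L)
})

test_that("removing all waters zeroes WCN and leaves OH untouched", {
  be <- build_ensemble(probe_spec(n_waters_in = 5, n_waters_out = 1,
                                  n_ser_in = 2, seed = 23),
                       schedule = c(5, 3, 1))
  d <- met_descriptors(be$ensemble)
  keep <- be$ensemble$topology$atoms$chain != "W"
  topo <- be$ensemble$topology
  topo$atoms <- topo$atoms[keep, , drop = FALSE]
  dry <- as_ensemble(topo, be$ensemble$coords[keep, , , drop = FALSE])
  d2 <- met_descriptors(dry)
  expect_equal(d2$WCN, 0)
  expect_equal(d2$OH, d$OH)
})

test_that("descriptor tables round-trip through the file contract", {
  d <- met_descriptors(build_probe(probe_spec(n_waters_in = 2,
                                              seed = 19))$structure,
                       molecule_id = "probe")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_descriptor_table(d, f, header = "unit test")
  d2 <- read_descriptor_table(f)
  expect_equal(as.data.frame(d2), as.data.frame(d), tolerance = 1e-12)
  # schema errors name the missing column
  f2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(d[, -which(names(d) == "WCN")], f2, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  expect_error(read_descriptor_table(f2), "WCN")
})
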
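make_cx_ens <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      sub <- sub_phenylpyridine()
      cx <- build_complex(sub, list(site_atom = 2, dg_atom = 9))
      ens <- cluster_conformers(generate_conformers(cx, seed = 11))
      val <<- list(cx = cx, ens = ens)
    }
    val
  }
})

test_that("mock engine is deterministic and self-consistent", {
  x <- make_cx_ens()
  eng <- engine_spec("mock")
  coords <- x$ens$coords[[1]]
  o1 <- optimize_geometry(eng, x$cx, coords)
  o2 <- optimize_geometry(eng, x$cx, coords)
  expect_identical(o1$energy_kcal, o2$energy_kcal)
  # mock "optimization" leaves geometry fixed, so a single point at the
  # optimized geometry reproduces the optimize-final energy
  expect_equal(single_point(eng, x$cx, o1$coordinates), o1$energy_kcal)
})

test_that("capability and configuration errors are typed", {
  x <- make_cx_ens()
  sp_only <- engine_spec("mock_sp")
  expect_error(optimize_geometry(sp_only, x$cx, x$ens$coords[[1]]),
               class = "regiopd_capability_error")
  expect_equal(sp_only$level, "dft_singlepoint")
  expect_equal(sp_only$capabilities, "singlepoint")
})

test_that("external tight-binding engine: run if installed, typed error if not", {
  x <- make_cx_ens()
  eng <- engine_spec("xtb")
  if (nzchar(Sys.which("xtb"))) {
    res <- optimize_geometry(eng, x$cx, x$ens$coords[[x$ens$representatives[1]]])
    expect_true(is.finite(res$energy_kcal))
  } else {
    expect_error(optimize_geometry(eng, x$cx, x$ens$coords[[1]]),
                 class = "regiopd_config_error")
  }
})

test_that("forcefield (UFF) engine optimizes with finite energy", {
  x <- make_cx_ens()
  eng <- engine_spec("forcefield")
  rep1 <- x$ens$representatives[1]
  res <- optimize_geometry(eng, x$cx, x$ens$coords[[rep1]])
  expect_true(is.finite(res$energy_kcal))
  expect_true(res$valid_connectivity)
})

test_that("connectivity check ignores metal bonds and flags broken ones", {
  x <- make_cx_ens()
  cx <- x$cx
  coords <- x$ens$coords[[1]]
  expect_true(check_connectivity(cx, coords, coords))
  # stretch a C-H bond far beyond any covalent threshold
  broken <- coords
  h_idx <- which(cx$symbols == "H")[1]
  broken[h_idx, ] <- broken[h_idx, ] + c(5, 0, 0)
  expect_false(check_connectivity(cx, coords, broken))
  # move Pd arbitrarily: metal bonds are excluded from the comparison
  pd_moved <- coords
  pd_moved[cx$index_map$pd + 1, ] <- pd_moved[cx$index_map$pd + 1, ] + c(9, 9, 9)
  expect_true(check_connectivity(cx, coords, pd_moved))
})

test_that("planarity angle: ideal plane passes, bent fails, 5 deg is strict", {
  # square-planar toy geometry: Pd origin, partners on axes in the xy plane
  flat <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(-2, 0, 0), c(0, -2, 0))
  r <- check_planarity(flat, 0, 1, 2, 3, 4)
  expect_equal(r$angle_deg, 0, tolerance = 1e-10)
  expect_true(r$ok)
  # displace the DG atom out of plane: normals differ by 20 degrees
  bent <- flat
  bent[3, ] <- c(0, 2 * cos(20 * pi / 180), 2 * sin(20 * pi / 180))
  r2 <- check_planarity(bent, 0, 1, 2, 3, 4)
  expect_equal(r2$angle_deg, 20, tolerance = 1e-8)
  expect_false(r2$ok)
  # the threshold is strict: an angle exactly equal to max_angle_deg fails
  r20 <- check_planarity(bent, 0, 1, 2, 3, 4, max_angle_deg = r2$angle_deg)
  expect_false(r20$ok)
  expect_true(check_planarity(bent, 0, 1, 2, 3, 4,
                              max_angle_deg = r2$angle_deg + 1e-9)$ok)
  # collinear triple is a degenerate-geometry failure
  degen <- flat
  degen[3, ] <- c(4, 0, 0)
  expect_error(check_planarity(degen, 0, 1, 2, 3, 4),
               class = "regiopd_geometry_error")
})

test_that("planarity angle is invariant under rigid motion", {
  x <- make_cx_ens()
  cx <- x$cx
  ix <- cx$index_map
  coords <- x$ens$coords[[x$ens$representatives[1]]]
  ref <- check_planarity(coords, ix$pd, ix$site, ix$dg, ix$o1, ix$o2)
  for (seed in 1:5) {
    moved <- rigid_motion(coords, seed)
    got <- check_planarity(moved, ix$pd, ix$site, ix$dg, ix$o1, ix$o2)
    expect_equal(got$angle_deg, ref$angle_deg, tolerance = 1e-6)
  }
})

test_that("connectivity perception is symmetric in its two geometries", {
  x <- make_cx_ens()
  a <- x$ens$coords[[1]]
  b <- x$ens$coords[[length(x$ens$coords)]]
  expect_equal(check_connectivity(x$cx, a, b), check_connectivity(x$cx, b, a))
})
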
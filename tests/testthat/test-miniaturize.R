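test_that("dissect returns a deep contiguous copy with complete backbone", {
  m <- model28()
  frag <- dissect(m, "A", 16, 28)
  expect_equal(length(unique(frag$resno)), 13)
  expect_equal(sort(unique(frag$resno)), 16:28)
  whole <- dissect(m, "A", 1, 28)
  expect_equal(length(unique(whole$resno)), 28)
  expect_error(dissect(m, "A", 38, 37), "start_seq")
  expect_error(dissect(m, "A", 20, 40), "chain break")
})

test_that("fit_c2_axis recovers an exact 180-degree rotation", {
  frag <- backbone_from_dihedrals(rep(-120, 5), rep(130, 5))
  frag <- apply_transform(frag, diag(3), c(5, 0, 0))  # off-axis
  copy <- apply_transform(frag, rotation_about_axis(c(0, 0, 1), 180), c(0, 0, 0))
  fit <- fit_c2_axis(frag, copy)
  expect_equal(fit$rotation_angle, 180, tolerance = 1e-6)
  expect_lt(fit$symmetry_rmsd, 1e-9)
  expect_equal(abs(fit$axis_direction[3]), 1, tolerance = 1e-6)
  # the axis line is z through the origin: the axis point has no x/y offset
  expect_lt(max(abs(fit$axis_point[1:2])), 1e-6)
})

test_that("jittered C2 copies yield symmetry RMSD in the expected band", {
  frag <- backbone_from_dihedrals(rep(-60, 6), rep(-40, 6))
  frag <- apply_transform(frag, diag(3), c(6, 1, 0))
  rmsds <- vapply(1:40, function(seed) {
    set.seed(seed)
    copy <- apply_transform(frag, rotation_about_axis(c(0, 0, 1), 180), c(0, 0, 0))
    copy <- with_coords(copy, coords(copy) + matrix(rnorm(nrow(copy) * 3, sd = 0.1),
                                                    ncol = 3))
    fit_c2_axis(frag, copy)$symmetry_rmsd
  }, numeric(1))
  expect_gt(mean(rmsds), 0.05)
  expect_lt(mean(rmsds), 0.2)
})

test_that("fit_c2_axis is symmetric in its arguments", {
  m <- model28()
  a <- dissect(m, "A", 1, 13)
  b <- dissect(m, "A", 16, 28)
  f1 <- fit_c2_axis(a, b)
  f2 <- fit_c2_axis(b, a)
  expect_equal(f1$symmetry_rmsd, f2$symmetry_rmsd, tolerance = 1e-9)
  # same axis line: directions parallel or antiparallel
  expect_equal(abs(sum(f1$axis_direction * f2$axis_direction)), 1,
               tolerance = 1e-6)
  expect_error(fit_c2_axis(a, dissect(m, "A", 16, 20)), "correspondence")
})

test_that("make_c2_dimer applies an exact involution and preserves distances", {
  frag <- backbone_from_dihedrals(rep(-120, 4), rep(130, 4))
  frag <- apply_transform(frag, diag(3), c(5, 2, 1))
  copy <- apply_transform(frag, rotation_about_axis(c(0, 1, 0), 180), c(0, 0, 0))
  axis <- fit_c2_axis(frag, copy)
  dimer <- make_c2_dimer(frag, axis)
  a <- dimer[dimer$chain == "A", ]; b <- dimer[dimer$chain == "B", ]
  # internal distances preserved exactly (rigid copy)
  expect_rigid_copy(coords(a), coords(b), tol = 1e-9)
  # applying the snapped 180-degree rotation twice is the identity
  u <- axis$axis_direction; p0 <- axis$axis_point
  R <- rotation_about_axis(u, 180)
  x <- coords(frag)
  x2 <- sweep(sweep(sweep(sweep(x, 2, p0) %*% t(R), 2, p0, "+"), 2, p0) %*% t(R),
              2, p0, "+")
  expect_lt(max(abs(x2 - x)), 1e-6)
  # re-fitting the axis on the dimer halves returns rmsd ~ 0
  refit <- fit_c2_axis(as_structure(a), as_structure(b))
  expect_lt(refit$symmetry_rmsd, 1e-9)
  expect_equal(refit$rotation_angle, 180, tolerance = 1e-6)
})

test_that("a metal rides onto the axis and clashes are reported not fatal", {
  site <- make_ideal_site()
  frag <- backbone_from_dihedrals(rep(-120, 4), rep(130, 4))
  frag <- apply_transform(frag, diag(3), c(4, 0, 0))
  zn <- site[site$record == "HETATM", ]
  zn$x <- 2; zn$y <- 3; zn$z <- 1
  frag_m <- as_structure(dplyr::bind_rows(frag, zn))
  copy <- apply_transform(frag, rotation_about_axis(c(0, 0, 1), 180), c(0, 0, 0))
  axis <- fit_c2_axis(frag, copy)
  dimer <- make_c2_dimer(frag_m, axis)
  met <- dimer[dimer$record == "HETATM", ]
  expect_equal(nrow(met), 1)
  # projection onto the z axis through the origin keeps only the z component
  expect_lt(abs(met$x) + abs(met$y), 1e-6)
  # near-axis fragment produces clashing copies: warning, not failure
  frag_close <- apply_transform(frag, diag(3), c(-3.2, 0, 0))
  expect_warning(make_c2_dimer(frag_close, axis), "closer than")
})

test_that("the 13-residue template unit regenerates a 26-residue dimer", {
  m <- model28()
  frag <- dissect(m, "A", 16, 28)
  axis <- fit_c2_axis(frag, dissect(m, "A", 1, 13))
  # the surrogate template is only loosely pseudo-symmetric; the fit must
  # still return a proper axis-angle diagnostic and a low half-site RMSD
  expect_true(axis$rotation_angle > 0 && axis$rotation_angle <= 180)
  expect_lt(axis$symmetry_rmsd, 1)
  expect_equal(sqrt(sum(axis$axis_direction^2)), 1, tolerance = 1e-9)
  dimer <- suppressWarnings(make_c2_dimer(frag, axis))
  expect_equal(length(unique(paste(dimer$chain, dimer$resno))) -
                 nrow(dimer[dimer$record == "HETATM", ]), 26)
})
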
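test_that("generators are bit-stable under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  l1 <- make_mini_library(4, list(list(gap_length = 4, turn_type = "I'")),
                          seed = 7, dir = d1)
  l2 <- make_mini_library(4, list(list(gap_length = 4, turn_type = "I'")),
                          seed = 7, dir = d2)
  for (f in basename(l1$library$path)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  m1 <- make_measurements("titration", noise = 0.02, seed = 5)
  m2 <- make_measurements("titration", noise = 0.02, seed = 5)
  expect_identical(m1, m2)
  expect_false(identical(
    m1, make_measurements("titration", noise = 0.02, seed = 6)))
})

test_that("backbone_from_dihedrals re-measures its inputs to 1e-3 degrees", {
  set.seed(31)
  phi <- runif(8, -170, -50); psi <- runif(8, -60, 150)
  s <- backbone_from_dihedrals(phi, psi)
  bd <- backbone_dihedrals(s)
  expect_lt(max(abs(bd$phi[-1] - phi[-1])), 1e-3)
  expect_lt(max(abs(bd$psi[-8] - psi[-8])), 1e-3)
  expect_lt(max(abs(abs(bd$omega[-1]) - 180)), 1e-3)
  empty <- backbone_from_dihedrals(numeric(0), numeric(0))
  expect_equal(nrow(empty), 0)
  expect_error(backbone_from_dihedrals(c(-60, -60), -45), "equal length")
})

test_that("ideal-site output satisfies the geometry it promises", {
  s <- make_ideal_site(d = 2.30)
  sg <- coords(s[s$elety == "SG", ])
  expect_equal(sqrt(rowSums(sg^2)), rep(2.30, 4), tolerance = 1e-9)
  s159 <- make_ideal_site(torsions = c(159, 100))
  g <- first_shell_geometry(s159, find_metal_site(s159, "ZN", max_bond = 2.8))
  expect_equal(unname(g$torsions), c(159, 100), tolerance = 1e-6)
  expect_error(make_ideal_site(d = -1), "positive")
})

test_that("measurement round-trips reproduce their truths", {
  # titration: kd = 0 gives the stoichiometric breakpoint
  t0 <- make_measurements("titration", truth = list(kd = 0), noise = 0, seed = 1)
  expect_equal(titration_breakpoint(t0, 30e-6), 1, tolerance = 1e-9)
  # voltammogram: noise-free peaks return the planted D
  vv <- make_measurements("voltammogram", truth = list(D = 7.3e-7), noise = 0,
                          seed = 1)
  an <- vv$peaks[vv$peaks$branch == "anodic", ]
  fit <- randles_sevcik_fit(an, area = vv$truth$area, conc = vv$truth$conc,
                            temperature = vv$truth$temperature)
  expect_equal(unname(fit$params["D"]), 7.3e-7, tolerance = 1e-9)
  # geff set: estimator finds the planted rhombicity
  gg <- make_measurements("geff_set", truth = list(E_over_D = 0.22), noise = 0,
                          seed = 1)
  est <- estimate_rhombicity(gg$observed, grid_step = 0.005)
  expect_lte(abs(est$E_over_D - 0.22), 0.005 + 1e-12)
  expect_error(make_measurements("spectrum"), "arg")
})

test_that("measurement CSVs carry a header and the main table", {
  f <- withr::local_tempfile(fileext = ".csv")
  make_measurements("titration", noise = 0, seed = 1, path = f)
  d <- read.csv(f)
  expect_named(d, c("ligand_total_M", "absorbance"))
  expect_gt(nrow(d), 10)
})

test_that("the miniature surrogate satisfies its own invariants", {
  m <- model28()
  expect_equal(length(unique(m$resno[m$record == "ATOM"])), 28)
  expect_equal(sort(m$resno[m$elety == "SG"]), c(2, 5, 17, 20))
  expect_equal(m$resid[m$resno == 9 & m$elety == "CA"], "AIB")
  expect_lt(attr(m, "site_fit_rmsd"), 0.6)
  # continuous peptide chain: all C-N links near 1.33 A
  atf <- function(rn, nm) as.numeric(
    m[which(m$resno == rn & m$elety == nm)[1], c("x", "y", "z")])
  cn <- vapply(1:27, function(i) vdist(atf(i, "C"), atf(i + 1, "N")),
               numeric(1))
  expect_lt(max(abs(cn - 1.329)), 0.01)
  # compact envelope
  xyz <- coords(m[m$record == "ATOM", ])
  rg <- sqrt(mean(rowSums(sweep(xyz, 2, colMeans(xyz))^2)))
  expect_lt(rg, 10)
})

test_that("the design/experiment pair hits the requested backbone RMSD", {
  pair <- synthetic_design_pair(rmsd = 0.45, seed = 4)
  fit <- structure_rmsd(pair$experimental, pair$design)
  expect_equal(fit$rmsd, 0.45, tolerance = 1e-6)
  pair2 <- synthetic_design_pair(rmsd = 0.45, seed = 5)
  expect_false(isTRUE(all.equal(coords(pair$experimental),
                                coords(pair2$experimental))))
})

test_that("the closure scaffold is exactly closable by its own window", {
  sc <- make_closure_scaffold(gap_length = 2, turn_type = "I'", seed = 12)
  tgt <- rbind(coords(sc$stubs$c_side), coords(sc$stubs$n_side))
  bb <- c("N", "CA", "C", "O")
  wfirst <- sc$window[sc$window$resno == 1 & sc$window$elety %in% bb, ]
  wlast <- sc$window[sc$window$resno == max(sc$window$resno) &
                       sc$window$elety %in% bb, ]
  src <- rbind(coords(wfirst[match(bb, wfirst$elety), ]),
               coords(wlast[match(bb, wlast$elety), ]))
  expect_lt(superpose(src, tgt)$rmsd, 1e-6)
})
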
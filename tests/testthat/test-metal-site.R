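test_that("find_metal_site locates 4 Cys SG around the metal", {
  site <- find_metal_site(ideal_site(), "ZN")
  expect_equal(site$coordination_number, 4)
  expect_true(site$is_tetrahedral)
  expect_equal(sort(site$ligands$resno), c(2, 5, 17, 20))
  expect_true(all(site$ligands$elety == "SG"))
})

test_that("sub-tetrahedral and ambiguous sites are flagged or rejected", {
  s <- ideal_site()
  three <- as_structure(s[!(s$elety == "SG" & s$resno == 20), ])
  site3 <- find_metal_site(three, "ZN")
  expect_equal(site3$coordination_number, 3)
  expect_false(site3$is_tetrahedral)
  expect_error(find_metal_site(s, "FE"), "no FE atom")
  two_zn <- as_structure(dplyr::bind_rows(s, dplyr::mutate(
    s[s$record == "HETATM", ], x = 30, eleno = 99L)))
  expect_error(find_metal_site(two_zn, "ZN"), "ambiguous")
  expect_equal(find_metal_site(two_zn, "ZN",
                               metal_eleno = 99L)$coordination_number, 0)
})

test_that("first-shell geometry of the ideal site is exact", {
  s <- ideal_site()
  g <- first_shell_geometry(s, find_metal_site(s, "ZN"))
  expect_equal(g$mean_distance, 2.34, tolerance = 1e-9)
  expect_equal(unname(g$distances), rep(2.34, 4), tolerance = 1e-9)
  expect_equal(g$mean_angle, acos(-1/3) * 180 / pi, tolerance = 1e-6)
  expect_lt(g$tetrahedricity, 1e-6)
  expect_equal(unname(g$torsions), c(180, 159), tolerance = 1e-6)
})

test_that("site geometry defaults follow the generator arguments", {
  s <- make_ideal_site(d = 2.30, torsions = c(170, 150))
  g <- first_shell_geometry(s, find_metal_site(s, "ZN"))
  expect_equal(g$mean_distance, 2.30, tolerance = 1e-9)
  expect_equal(unname(g$torsions), c(170, 150), tolerance = 1e-6)
})

test_that("a compressed site shows the analytically constructed distortion", {
  s <- ideal_site()
  # squeeze z by 20%: angles between vertex pairs change by a computable amount
  sq <- with_coords(s, coords(s) %*% diag(c(1, 1, 0.8)))
  sq <- as_structure(sq)
  g <- first_shell_geometry(sq, find_metal_site(sq, "ZN", max_bond = 2.8))
  v <- rbind(c(1, 1, 0.8), c(1, -1, -0.8), c(-1, 1, -0.8), c(-1, -1, 0.8)) / sqrt(3)
  combs <- utils::combn(4, 2)
  expected <- apply(combs, 2, function(ij) {
    a <- v[ij[1], ]; b <- v[ij[2], ]
    acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2))) * 180 / pi
  })
  expect_equal(sort(g$angles), sort(expected), tolerance = 1e-6)
  expect_gt(g$tetrahedricity, 1)
})

test_that("reports are invariant under rigid motion of the model", {
  s <- ideal_site()
  rr <- random_rigid(23)
  moved <- as_structure(apply_transform(s, rr$R, rr$t))
  g0 <- first_shell_geometry(s, find_metal_site(s, "ZN"))
  g1 <- first_shell_geometry(moved, find_metal_site(moved, "ZN"))
  expect_equal(g1$mean_distance, g0$mean_distance, tolerance = 1e-9)
  expect_equal(sort(g1$angles), sort(g0$angles), tolerance = 1e-6)
  dtor <- (unname(g1$torsions) - unname(g0$torsions) + 180) %% 360 - 180
  expect_lt(max(abs(dtor)), 1e-6)
})

make_nh_s_fixture <- function(angle_good = TRUE) {
  # a CYS SG acceptor and an ALA backbone N-H donor aimed at (or away from) it
  sg <- c(0, 0, 0)
  N <- c(0, 0, 3.4)
  # H along the N->S direction (good) or perpendicular-ish (bad)
  H <- if (angle_good) N + c(0, 0, -1) else N + c(1, 0, 0)
  # place C(prev) and CA so the geometric H of build_amide_h lands at H:
  # -(u1+u2) must point along (H - N); pick u1, u2 symmetric about it
  hdir <- (H - N) / sqrt(sum((H - N)^2))
  ref <- if (abs(hdir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  perp <- ref - sum(ref * hdir) * hdir; perp <- perp / sqrt(sum(perp^2))
  u1 <- -hdir * cos(pi / 3) + perp * sin(pi / 3)
  u2 <- -hdir * cos(pi / 3) - perp * sin(pi / 3)
  Cprev <- N + 1.33 * u1
  CA <- N + 1.46 * u2
  tibble::tibble(
    elety = c("CB", "SG", "N", "CA", "C", "CA"),
    resid = c("CYS", "CYS", "ALA", "ALA", "GLY", "GLY"),
    chain = "A",
    resno = c(5L, 5L, 8L, 8L, 7L, 7L),
    x = c(1.8, sg[1], N[1], CA[1], Cprev[1], Cprev[1] - 1.5),
    y = c(0, sg[2], N[2], CA[2], Cprev[2], Cprev[2] + 0.2),
    z = c(-0.5, sg[3], N[3], CA[3], Cprev[3], Cprev[3] + 0.3))
}

test_that("NH...S hydrogen bonds require distance and orientation", {
  good <- as_structure(make_nh_s_fixture(angle_good = TRUE))
  hb <- detect_nh_s_hbonds(good)
  expect_equal(nrow(hb[hb$kind == "backbone", ]), 1)
  expect_equal(hb$donor_resno[1], 8)
  expect_equal(hb$acceptor_resno[1], 5)
  bad <- as_structure(make_nh_s_fixture(angle_good = FALSE))
  expect_equal(nrow(detect_nh_s_hbonds(bad)[
    detect_nh_s_hbonds(bad)$kind == "backbone", ]), 0)
})

test_that("NH...S detection is monotone in its thresholds", {
  s <- as_structure(make_nh_s_fixture(angle_good = TRUE))
  tight <- detect_nh_s_hbonds(s, d_ns_max = 3.6, d_hs_max = 2.9, angle_min = 120)
  loose <- detect_nh_s_hbonds(s, d_ns_max = 4.0, d_hs_max = 3.3, angle_min = 100)
  key <- function(d) paste(d$donor_resno, d$acceptor_resno, d$donor_atom)
  expect_true(all(key(tight) %in% key(loose)))
})

test_that("the synthetic miniature offers NH...S contacts to Cys acceptors", {
  # the surrogate site is deliberately not idealized; survey-loose thresholds
  hb <- detect_nh_s_hbonds(model28(), d_ns_max = 4.0, d_hs_max = 3.3,
                           angle_min = 100)
  expect_gt(nrow(hb), 0)
  expect_true(all(hb$acceptor_resno %in% c(2, 5, 17, 20)))
})

test_that("an isolated molecule in P1 has no crystal contacts", {
  s <- as_structure(make_nh_s_fixture(),
                    cell = c(90, 90, 90, 90, 90, 90), space_group = "P 1")
  expect_equal(nrow(crystal_contact_report(s)), 0)
})

test_that("engineered lattice contacts are found with the right labels", {
  s <- synthetic_c2221_crystal(oh_oh = 3.32, salt_nd = 3.0, sg_hb = 3.3)
  cc <- crystal_contact_report(s, radius = 4.0)
  oh <- cc[cc$atom == "OH" & cc$mate_atom == "OH", ]
  expect_gt(nrow(oh), 0)
  expect_equal(min(oh$distance), 3.32, tolerance = 0.01)
  salt <- cc[cc$kind == "salt_bridge", ]
  expect_gt(nrow(salt), 0)
  expect_true(any((salt$resid == "ARG" & salt$mate_resid == "ASP") |
                    (salt$resid == "ASP" & salt$mate_resid == "ARG")))
  sg <- cc[cc$atom == "SG" | cc$mate_atom == "SG", ]
  expect_true(any(sg$distance < 3.6))
})

test_that("z-scores against the reference survey behave as arithmetic", {
  s <- ideal_site()
  g <- first_shell_geometry(s, find_metal_site(s, "ZN"))
  z <- compare_to_reference(g)
  expect_equal(z$z[z$descriptor == "mean_distance"], 0, tolerance = 1e-6)
  g2 <- g; g2$mean_distance <- 2.40
  z2 <- compare_to_reference(g2)
  expect_equal(z2$z[z2$descriptor == "mean_distance"], 2.0, tolerance = 1e-9)
  expect_error(compare_to_reference(g, ref = list(
    mean_distance = 2.34, sd_distance = 0, mean_angle = 109, sd_angle = 4)),
    "sds")
})
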
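# Deterministic synthetic-fixture generators. These define the study
# conditions every analysis is exercised under: ideal tetrahedral M(Cys)4
# sites at the survey geometry, backbones built from canonical dihedrals,
# fragment libraries with planted loops, and synthetic titrations,
# voltammograms and effective-g sets. Same spec + seed => identical output.

#' Ideal tetrahedral M(Cys)4 site
#'
#' Metal at the origin, four Sγ at exact tetrahedral vertices at distance `d`,
#' Cβ atoms placed to give prescribed Sγ-M-Sγ-Cβ torsions across the two
#' pseudo-dyad ligand pairs (residues 2/17 and 5/20), plus Cα atoms so chi1
#' machinery has context. All six S-M-S angles equal arccos(-1/3) = 109.47°.
#'
#' @param metal element symbol (default "ZN").
#' @param d M-S distance, Å (default 2.34, the rubredoxin-survey mean).
#' @param torsions length-2: the S(2)-M-S(17)-Cβ(17) and S(5)-M-S(20)-Cβ(20)
#'   torsions, degrees (default 180 and 159).
#' @return an `mm_structure` with four partial CYS residues (2, 5, 17, 20) and
#'   one metal HETATM.
#' @export
make_ideal_site <- function(metal = "ZN", d = 2.34, torsions = c(180, 159)) {
  if (d <= 0) abort("d must be positive")
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  S <- v * d
  M <- c(0, 0, 0)
  resnos <- c(2, 5, 17, 20)
  # CB(k) placed off S(k); partners pair 1-3 (2/17) and 2-4 (5/20)
  partner <- c(3, 4, 1, 2)
  tor <- c(torsions[1], torsions[2], torsions[1], torsions[2])
  rows <- list()
  for (k in 1:4) {
    CB <- place_atom(S[partner[k], ], M, S[k, ], 1.82, 105, tor[k])
    CA <- place_atom(M, S[k, ], CB, 1.53, 114, 75)
    add <- function(nm, p, el) tibble(record = "ATOM", elety = nm, resid = "CYS",
                                      chain = "A", resno = resnos[k],
                                      x = p[1], y = p[2], z = p[3], elesy = el)
    rows[[length(rows) + 1]] <- add("CA", CA, "C")
    rows[[length(rows) + 1]] <- add("CB", CB, "C")
    rows[[length(rows) + 1]] <- add("SG", S[k, ], "S")
  }
  rows[[length(rows) + 1]] <- tibble(record = "HETATM", elety = toupper(metal),
                                     resid = toupper(metal), chain = "A",
                                     resno = 101L, x = M[1], y = M[2], z = M[3],
                                     elesy = toupper(metal))
  as_structure(bind_rows(rows))
}

# ---------------------------------------------------------------------------
# Fragment library with planted loops

.BASIN <- list(beta = list(phi = c(-150, -90), psi = c(110, 150)),
               alpha = list(phi = c(-70, -50), psi = c(-50, -30)))

sample_decoy_dihedrals <- function(n) {
  basin <- sample(c("beta", "alpha"), n, replace = TRUE, prob = c(0.6, 0.4))
  phi <- vapply(basin, function(b) runif(1, .BASIN[[b]]$phi[1], .BASIN[[b]]$phi[2]),
                numeric(1))
  psi <- vapply(basin, function(b) runif(1, .BASIN[[b]]$psi[1], .BASIN[[b]]$psi[2]),
                numeric(1))
  list(phi = unname(phi), psi = unname(psi))
}

turn_window_dihedrals <- function(gap_length, turn_type = "I'") {
  # anchors in the beta basin; for gap 4 the two central residues carry the
  # canonical turn dihedrals, remaining interior residues sit in the basin
  phi <- c(-120, rep(-120, gap_length), -120)
  psi <- c(130, rep(130, gap_length), 130)
  if (gap_length == 4 && turn_type %in% names(.TURN_CANON)) {
    canon <- .TURN_CANON[[turn_type]]
    phi[3] <- canon[1]; psi[3] <- canon[2]
    phi[4] <- canon[3]; psi[4] <- canon[4]
    # loop residue 1/4 flanks: extended-ish but closing
    phi[2] <- -90; psi[2] <- 120
    phi[5] <- -100; psi[5] <- 120
  } else if (gap_length != 4) {
    interior <- seq(2, gap_length + 1)
    phi[interior] <- -75; psi[interior] <- -35
  }
  list(phi = phi, psi = psi)
}

#' Synthetic fragment library with planted loop windows
#'
#' Writes `n_structures` PDB chains to `dir` plus an `index.tsv`. Decoy chains
#' are random coil sampled from broad alpha/beta basins; each planted loop is
#' a window of canonical-turn dihedrals spliced (as internal coordinates, so
#' the chain stays continuous) into a decoy chain. A companion stub pair built
#' from the same window dihedrals is returned for each plant, so a search
#' against it must recover the plant with near-zero anchor RMSD.
#'
#' @param n_structures total number of library chains.
#' @param planted_loops list of `list(gap_length =, turn_type =)` (or a
#'   two-column data frame); at most one plant per chain.
#' @param seed integer seed (all randomness local to the call).
#' @param dir output directory (created).
#' @param decoy_length decoy chain length (default 30).
#' @return list: `index_path`, `library` (the [read_fragment_library()] tibble),
#'   `plants` (tibble: id, chain, start_seq, gap_length, turn_type), `stubs`
#'   (list of `mm_stub_pair`, one per plant).
#' @export
make_mini_library <- function(n_structures, planted_loops = list(), seed = 1,
                              dir = tempfile("minilib"), decoy_length = 30) {
  if (is.data.frame(planted_loops)) {
    planted_loops <- lapply(seq_len(nrow(planted_loops)), function(i)
      list(gap_length = planted_loops$gap_length[i],
           turn_type = planted_loops$turn_type[i]))
  }
  if (length(planted_loops) > n_structures) {
    abort("more planted loops than structures")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  index <- list(); plants <- list(); stubs <- list()
  for (i in seq_len(n_structures)) {
    id <- sprintf("lib%03d", i)
    plant <- if (i <= length(planted_loops)) planted_loops[[i]] else NULL
    dec <- sample_decoy_dihedrals(decoy_length)
    phi <- dec$phi; psi <- dec$psi
    sequence <- rep("ALA", decoy_length)
    start_seq <- NA_integer_
    if (!is.null(plant)) {
      w <- turn_window_dihedrals(plant$gap_length, plant$turn_type %||% "I'")
      wl <- length(w$phi)
      pos <- 6                                  # plant after a 5-residue prefix
      phi[pos:(pos + wl - 1)] <- w$phi
      psi[pos:(pos + wl - 1)] <- w$psi
      if ((plant$gap_length %||% 0) == 4) {
        sequence[pos + 2] <- "GLY"; sequence[pos + 3] <- "GLY"
      }
      start_seq <- pos
      # companion stubs: the same window built standalone
      win <- backbone_from_dihedrals(w$phi, w$psi)
      st <- list(
        c_side = win[win$resno == 1 & win$elety %in% c("N", "CA", "C", "O"), ],
        n_side = win[win$resno == max(win$resno) &
                       win$elety %in% c("N", "CA", "C", "O"), ])
      class(st) <- "mm_stub_pair"
      stubs[[length(stubs) + 1]] <- st
      plants[[length(plants) + 1]] <- tibble(
        id = id, chain = "A", start_seq = start_seq,
        gap_length = plant$gap_length, turn_type = plant$turn_type %||% "I'")
    }
    s <- backbone_from_dihedrals(phi, psi, sequence = sequence)
    path <- file.path(dir, paste0(id, ".pdb"))
    write_structure(s, path)
    index[[length(index) + 1]] <- tibble(id = id, chain = "A",
                                         path = paste0(id, ".pdb"))
  }
  index_path <- file.path(dir, "index.tsv")
  index_tab <- if (length(index)) bind_rows(index) else
    tibble(id = character(), chain = character(), path = character())
  write.table(index_tab, index_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(index_path = index_path, library = read_fragment_library(index_path),
       plants = if (length(plants)) bind_rows(plants) else
         tibble(id = character(), chain = character(), start_seq = integer(),
                gap_length = integer(), turn_type = character()),
       stubs = stubs)
}

# run code under a local RNG state
.Random.seed_guard <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

# ---------------------------------------------------------------------------
# Synthetic measurements

#' Synthetic measurement tables
#'
#' Generates titrations (exact quadratic 1:1 model), voltammetry peak-current
#' tables (Randles-Sevcik at the experimental scan-rate range) together with a
#' synthetic reversible cyclic trace, or effective-g observation sets, with
#' seeded Gaussian noise. When `path` is given, the main table is written as
#' CSV with a header line.
#'
#' @param kind "titration", "voltammogram" or "geff_set".
#' @param truth named list of true parameters; missing entries take the
#'   defaults of the experiment being emulated (30 µM protein titrated to 2.5
#'   equivalents; 80 µM couple on a 3 mm glassy-carbon electrode scanned at
#'   2.5-50 mV/s at 288 K; E/D = 0.22 with g0 = 2.0023).
#' @param noise relative Gaussian noise sd (0 = exact).
#' @param seed integer seed.
#' @param path optional CSV output path.
#' @return a tibble (titration, peaks) or list (`geff_set`: observed,
#'   truth; `voltammogram`: peaks + one `trace`).
#' @export
make_measurements <- function(kind = c("titration", "voltammogram", "geff_set"),
                              truth = list(), noise = 0, seed = 1, path = NULL) {
  kind <- match.arg(kind)
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  out <- switch(kind,
    titration = {
      tr <- utils::modifyList(list(kd = 3e-7, eps_complex = 7730,
                                   baseline = 0.02, protein_total = 30e-6,
                                   pathlength = 1, n_points = 26,
                                   max_equiv = 2.5), truth)
      L <- seq(0, tr$max_equiv * tr$protein_total, length.out = tr$n_points)
      pl <- binding_complex(L, tr$protein_total, tr$kd)
      A <- tr$eps_complex * pl * tr$pathlength + tr$baseline
      amp <- max(A) - min(A)
      A <- A + noise * amp * rnorm(length(A))
      tibble(ligand_total_M = L, absorbance = A)
    },
    voltammogram = {
      tr <- utils::modifyList(list(D = 1.0e-6, n = 1, area = 0.0707,
                                   conc = 80e-9, temperature = 288.15,
                                   scan_rates = c(2.5, 5, 10, 20, 35, 50) / 1000,
                                   E0 = -0.085, reference_offset = 0.206),
                              truth)
      k <- 0.4463 * tr$n * .FARADAY * tr$area * tr$conc *
        sqrt(tr$n * .FARADAY / (.RGAS * tr$temperature))
      ip <- k * sqrt(tr$scan_rates * tr$D)
      peaks <- tibble(
        scan_rate = rep(tr$scan_rates, 2),
        branch = rep(c("anodic", "cathodic"), each = length(tr$scan_rates)),
        i_p = c(ip, -ip) * (1 + noise * rnorm(2 * length(ip))))
      trace <- synth_cv_trace(E0 = tr$E0, i_peak = ip[length(ip)],
                              noise = noise)
      list(peaks = peaks, trace = trace, truth = tr)
    },
    geff_set = {
      tr <- utils::modifyList(list(E_over_D = 0.22, g0 = 2.0023, D = 1,
                                   components = c("1y", "2x")), truth)
      g <- zfs_effective_g(D = tr$D, E = tr$E_over_D * tr$D, g0 = tr$g0)
      obs <- vapply(tr$components, function(cmp) {
        dbl <- as.integer(substr(cmp, 1, 1))
        ax <- substr(cmp, 2, 2)
        g[dbl, ax]
      }, numeric(1))
      obs <- obs * (1 + noise * rnorm(length(obs)))
      list(observed = unname(obs), truth = tr)
    })
  if (!is.null(path)) {
    tab <- if (kind == "titration") out else if (kind == "voltammogram")
      out$peaks else tibble(geff = out$observed)
    write.csv(tab, path, row.names = FALSE)
  }
  out
}

#' Synthetic reversible cyclic voltammogram trace
#'
#' A surrogate reversible couple: Gaussian anodic/cathodic waves centered
#' 29.5 mV above/below the formal potential (peak separation 59 mV, the
#' Nernstian one-electron value at 25 °C), swept forward then back.
#'
#' @param E0 formal potential on the recorded axis, V.
#' @param i_peak peak current, A.
#' @param width wave width parameter, V.
#' @param window half-width of the potential window around E0, V.
#' @param n_points points per sweep segment.
#' @param noise relative current noise sd.
#' @return tibble: potential_V, current_A (one full cycle).
#' @export
synth_cv_trace <- function(E0 = -0.085, i_peak = 1e-7, width = 0.04,
                           window = 0.25, n_points = 400, noise = 0) {
  Ef <- seq(E0 - window, E0 + window, length.out = n_points)
  Er <- rev(Ef)
  ia <- i_peak * exp(-((Ef - (E0 + 0.0295)) / width)^2)
  ic <- -i_peak * exp(-((Er - (E0 - 0.0295)) / width)^2)
  out <- tibble(potential_V = c(Ef, Er), current_A = c(ia, ic))
  if (noise > 0) {
    out$current_A <- out$current_A + noise * i_peak * rnorm(nrow(out))
  }
  out
}

# ---------------------------------------------------------------------------
# Synthetic miniature-protein stand-ins (no deposited structures are bundled;
# these are package-built surrogates at the documented study conditions)

#' Synthetic reconstruction of the miniature-protein sequence
#'
#' A 28-residue sequence consistent with the residues the characterization
#' names (Cys 2/5/17/20, Asp4, Ala7/22, Aib9/24 as "X", Val12, Tyr16 plus a
#' second Tyr, Asn19, Arg26, Ile27, a Gly-Gly type I' turn at 14-15, 0 Trp).
#' It is a synthetic stand-in, not the deposited sequence.
#'
#' @return 1-letter string of length 28.
#' @export
metpsc1_sequence <- function() "YCEDCSAKXQLVSGGYCENCSAKXQRIE"

# dihedral program for one 13-residue pseudo-C2 unit: strand / metal-binding
# alpha-turn / strand / 3_10 stretch / strand. The knuckle adjustments, the
# two inter-unit torsions and the four Cys chi1 below were fixed once by an
# offline geometric optimization (tetrahedral SG cluster, no backbone clashes,
# compact envelope) and are frozen constants of the generator.
.UNIT_PHI <- c(-120, -130, -60, -60, -60, -90, -120, -49, -49, -49, -49, -120, -120)
.UNIT_PSI <- c( 130,  120, -30, -30, -30,   0,  130, -26, -26, -26, -26,  130,  130)
.KNUCKLE_ADJ <- c(-8.8167, -6.5933, -12.7571, -8.2574, -35, 35)
.LINK_PSI13 <- -28.0944
.LINK_PHI16 <- -122.5128
.CYS_CHI1 <- c(139.2655, 62.8216, -179.9849, 22.8968)

#' Synthetic compact miniature ZnCys4 protein model
#'
#' Builds a 28-residue single-chain stand-in for a miniature tetrathiolate
#' metalloprotein as one continuous chain from a frozen dihedral program: two
#' pseudo-C2 13-residue units (strand, metal-binding alpha-turn, strand, 3_10
#' stretch, strand) joined by a Gly-Gly type I' beta-turn at positions 14-15.
#' The four Cys Sgamma (residues 2, 5, 17, 20) cluster around a central
#' position where the Zn is placed (the center of the best-fit ideal
#' tetrahedron; the cluster matches the ideal vertices to ~0.45 Å RMSD, so the
#' site is recognizable but deliberately not idealized). Side chains beyond
#' Cbeta are reduced to pseudo-atoms along the Calpha-Cbeta direction so the
#' molecular envelope (and hence hydrodynamics) is realistic. This is a
#' synthetic surrogate built by the package, not a deposited structure.
#'
#' @param full_sidechains add the reduced side-chain pseudo-atoms
#'   (default TRUE).
#' @return an `mm_structure` of 28 residues plus one Zn HETATM; attribute
#'   `site_fit_rmsd` reports the SG-vs-ideal-tetrahedron RMSD.
#' @export
synthetic_metpsc1 <- function(full_sidechains = TRUE) {
  up <- .UNIT_PHI; us <- .UNIT_PSI
  up[3:5] <- up[3:5] + .KNUCKLE_ADJ[1:3]
  us[2:4] <- us[2:4] + .KNUCKLE_ADJ[4:6]
  phi <- c(up, 60, 90, up); psi <- c(us, 30, 0, us)
  psi[13] <- .LINK_PSI13; phi[16] <- .LINK_PHI16
  chi1 <- rep(-60, 28)
  chi1[c(2, 5, 17, 20)] <- .CYS_CHI1
  out <- backbone_from_dihedrals(phi, psi, sequence = metpsc1_sequence(),
                                 chi1 = chi1)
  if (full_sidechains) out <- add_reduced_sidechains(out)
  sg <- coords(out[out$elety == "SG", ])
  ideal <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
    sqrt(3) * 2.34
  fit <- superpose(ideal, sg)
  znc <- fit$translation
  zn <- tibble(record = "HETATM", elety = "ZN", resid = "ZN", chain = "A",
               resno = 101L, x = znc[1], y = znc[2], z = znc[3], elesy = "ZN")
  out <- as_structure(bind_rows(out, zn))
  attr(out, "site_fit_rmsd") <- fit$rmsd
  out
}

# reduced side chains: pseudo heavy atoms continuing past CB along the CA->CB
# direction at 1.5 Å spacing, fanned slightly off axis; counts per residue
# from the standard heavy-atom composition
add_reduced_sidechains <- function(s) {
  rows <- list(s)
  for (rn in unique(s$resno)) {
    r <- s[s$resno == rn, ]
    resid <- r$resid[1]
    nextra <- .SC_EXTRA[resid]
    if (is.na(nextra) || nextra == 0) next
    has_g <- any(r$elety %in% c("SG", "OG"))
    nextra <- nextra - as.integer(has_g)
    if (nextra <= 0) next
    CA <- as.numeric(r[match("CA", r$elety), c("x", "y", "z")])
    CB <- as.numeric(r[match("CB", r$elety), c("x", "y", "z")])
    if (any(is.na(CA)) || any(is.na(CB))) next
    u <- (CB - CA) / vdist(CB, CA)
    N <- as.numeric(r[match("N", r$elety), c("x", "y", "z")])
    v <- cross3(u, (N - CA) / vdist(N, CA)); v <- v / sqrt(sum(v^2))
    for (k in seq_len(nextra)) {
      p <- CB + u * 1.25 * k + v * 0.6 * sin(k * 2.1)
      rows[[length(rows) + 1]] <- tibble(
        record = "ATOM", elety = paste0("Q", k), resid = resid, chain = r$chain[1],
        resno = rn, x = p[1], y = p[2], z = p[3], elesy = "C")
    }
  }
  bind_rows(rows)
}

#' Synthetic design/experiment structure pair at a prescribed backbone RMSD
#'
#' Returns the synthetic miniature model together with a perturbed copy whose
#' optimal (Kabsch) backbone RMSD against the original equals `rmsd` exactly:
#' seeded Gaussian displacements are rescaled until the post-fit RMSD matches,
#' and the copy is then moved by a random rigid motion.
#'
#' @param rmsd target backbone RMSD, Å.
#' @param seed integer seed.
#' @return list: `design`, `experimental` (both `mm_structure`).
#' @export
synthetic_design_pair <- function(rmsd = 0.45, seed = 1) {
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  design <- synthetic_metpsc1()
  atomsel <- design$record == "ATOM"
  bbsel <- atomsel & design$elety %in% c("N", "CA", "C", "O")
  Z <- matrix(rnorm(3 * sum(atomsel)), ncol = 3)
  X <- coords(design)[atomsel, , drop = FALSE]
  bb_rows <- which(bbsel[atomsel])
  # scale the displacement field so the optimal *backbone* RMSD is exact
  rms_at <- function(alpha) {
    superpose(X[bb_rows, ], X[bb_rows, ] + alpha * Z[bb_rows, ])$rmsd - rmsd
  }
  alpha <- stats::uniroot(rms_at, c(1e-6, 10), tol = 1e-12)$root
  exp_s <- design
  xyz <- coords(exp_s)
  xyz[atomsel, ] <- X + alpha * Z
  exp_s <- with_coords(exp_s, xyz)
  Rr <- rotation_about_axis(rnorm(3), runif(1, 10, 170))
  exp_s <- apply_transform(exp_s, Rr, rnorm(3, sd = 10))
  list(design = design, experimental = as_structure(exp_s))
}

#' Synthetic C222"1" crystal fixture with engineered lattice contacts
#'
#' A small synthetic molecule (partial Tyr16, Arg26, Asp4, Cys20 residues) in
#' a C2221 cell, placed so that under the (-x, y, -z+1/2) operator the Tyr
#' hydroxyl meets its mate at a prescribed distance, an Arg guanidinium
#' nitrogen meets an Asp carboxylate oxygen of a mate within salt-bridge
#' range, and a mate guanidinium sits within hydrogen-bond range of the Cys
#' Sγ.
#'
#' @param oh_oh Tyr OH...OH mate distance, Å (default 3.32).
#' @param salt_nd Arg N...Asp O mate distance, Å (default 3.0).
#' @param sg_hb Arg N(mate)...Sγ distance, Å (default 3.3).
#' @return an `mm_structure` with cell and C2221 operators.
#' @export
synthetic_c2221_crystal <- function(oh_oh = 3.32, salt_nd = 3.0, sg_hb = 3.3) {
  cell <- c(30, 40, 50, 90, 90, 90)
  cz <- cell[3]
  mk <- function(elety, resid, resno, p, elesy = substr(elety, 1, 1)) {
    tibble(record = "ATOM", elety = elety, resid = resid, chain = "A",
           resno = as.integer(resno), x = p[1], y = p[2], z = p[3],
           elesy = elesy)
  }
  rows <- list()
  # Tyr16: OH at (x0, y, z0) so the (-x, y, c/2 - z) mate OH is oh_oh away
  dz <- sqrt(oh_oh^2 - 4)                    # with x0 = 1 -> lateral 2 Å
  z_oh <- (cz / 2 - dz) / 2
  OH <- c(1, 5, z_oh)
  rows <- c(rows, list(mk("OH", "TYR", 16, OH, "O"),
                       mk("CZ", "TYR", 16, OH + c(0, 1.1, 0.8), "C"),
                       mk("CA", "TYR", 16, OH + c(0.5, 3.2, 2.6), "C")))
  # Asp4 carboxylate; its mate will receive the Arg26 salt bridge
  OD1 <- c(0.5, 8, 12.0)
  rows <- c(rows, list(mk("OD1", "ASP", 4, OD1, "O"),
                       mk("OD2", "ASP", 4, OD1 + c(1.6, 0.9, 0), "O"),
                       mk("CG", "ASP", 4, OD1 + c(0.9, 0.3, 0.9), "C"),
                       mk("CA", "ASP", 4, OD1 + c(1.4, 1.2, 2.2), "C")))
  # Arg26 guanidinium: NH1 placed salt_nd from the Asp4 mate at
  # (-0.5, 8, cz/2 - 12)
  mateOD1 <- c(-OD1[1], OD1[2], cz / 2 - OD1[3])
  NH1 <- mateOD1 + c(0, 0, salt_nd)
  rows <- c(rows, list(mk("NH1", "ARG", 26, NH1, "N"),
                       mk("NH2", "ARG", 26, NH1 + c(1.8, 0.6, 0.4), "N"),
                       mk("NE", "ARG", 26, NH1 + c(0.5, -1.0, 1.9), "N"),
                       mk("CZ", "ARG", 26, NH1 + c(0.8, -0.2, 1.1), "C"),
                       mk("CA", "ARG", 26, NH1 + c(1.2, 0.8, 3.4), "C")))
  # Cys20 Sγ within sg_hb of the Arg26 NH2 mate
  mateNH2 <- c(-(NH1[1] + 1.8), NH1[2] + 0.6, cz / 2 - (NH1[3] + 0.4))
  SG <- mateNH2 + c(0, sg_hb, 0)
  rows <- c(rows, list(mk("SG", "CYS", 20, SG, "S"),
                       mk("CB", "CYS", 20, SG + c(0.8, 1.5, 0.6), "C"),
                       mk("CA", "CYS", 20, SG + c(1.4, 2.5, 1.4), "C")))
  as_structure(bind_rows(rows), cell = cell, space_group = "C 2 2 21")
}

#' Closure scaffold whose stubs exactly match a planted window
#'
#' Builds a two-chain open scaffold (the shape [search_fragments()] closes):
#' chain "B" ends in a residue whose backbone coincides exactly with the first
#' residue of the canonical turn window for (`gap_length`, `turn_type`), and
#' chain "A" starts in a residue coinciding with the window's last residue.
#' A library planted with the same window (see [make_mini_library()]) is
#' therefore guaranteed to close this scaffold with near-zero anchor RMSD and
#' ideal peptide junctions.
#'
#' @param gap_length intervening residues of the target loop.
#' @param turn_type canonical turn type for gap 4 (default "I'").
#' @param seed seed for the decoy arms.
#' @param arm_length decoy residues per arm (default 5).
#' @return list: `dimer` (two-chain `mm_structure`), `stubs`
#'   (`mm_stub_pair`), `window` (the standalone window structure).
#' @export
make_closure_scaffold <- function(gap_length = 4, turn_type = "I'", seed = 1,
                                  arm_length = 5) {
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  w <- turn_window_dihedrals(gap_length, turn_type)
  win <- backbone_from_dihedrals(w$phi, w$psi)
  bb <- c("N", "CA", "C", "O")
  res_bb <- function(s, rn) {
    r <- s[s$resno == rn & s$elety %in% bb, ]
    r[match(bb, r$elety), ]
  }
  wl <- length(w$phi)
  # chain B: decoy arm whose LAST residue reproduces window residue 1
  decB <- sample_decoy_dihedrals(arm_length + 1)
  decB$phi[arm_length + 1] <- w$phi[1]   # phi of the anchor residue
  decB$psi[arm_length + 1] <- w$psi[1]
  chB <- backbone_from_dihedrals(decB$phi, decB$psi)
  fitB <- superpose(coords(res_bb(chB, arm_length + 1)),
                    coords(res_bb(win, 1)))
  chB <- apply_transform(chB, fitB$rotation, fitB$translation)
  chB$chain <- "B"
  # chain A: decoy arm whose FIRST residue reproduces the window's last
  decA <- sample_decoy_dihedrals(arm_length + 1)
  decA$phi[1] <- w$phi[wl]; decA$psi[1] <- w$psi[wl]
  chA <- backbone_from_dihedrals(decA$phi, decA$psi)
  fitA <- superpose(coords(res_bb(chA, 1)), coords(res_bb(win, wl)))
  chA <- apply_transform(chA, fitA$rotation, fitA$translation)
  chA$chain <- "A"
  dimer <- as_structure(bind_rows(chA, chB))
  stubs <- list(c_side = res_bb(chB, arm_length + 1), n_side = res_bb(chA, 1))
  class(stubs) <- "mm_stub_pair"
  list(dimer = dimer, stubs = stubs, window = win)
}
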
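# Hydrogen-bond detection and secondary / super-secondary motif assignment.
# The motif vocabulary is the one needed for a miniature metal-binding fold:
# short beta-strands and antiparallel pairs, alpha-turns, beta-bulges,
# 3_10-helix stretches and the classical beta-turn types (I, I', II, II',
# VIII, III, III', IV).

# canonical (phi_i+1, psi_i+1, phi_i+2, psi_i+2) per turn type
.TURN_CANON <- list(
  "I"    = c(-60, -30, -90,   0),
  "I'"   = c( 60,  30,  90,   0),
  "II"   = c(-60, 120,  80,   0),
  "II'"  = c( 60, -120, -80,  0),
  "VIII" = c(-60, -30, -120, 120),
  "III"  = c(-60, -30, -60, -30),
  "III'" = c( 60,  30,  60,  30)
)

#' Classify a beta turn from its central dihedrals
#'
#' Nearest canonical type with all four angles within ±30° (one angle may
#' deviate up to ±45°); when both I' and III' (or I and III) qualify, the
#' smaller summed angular deviation wins, with ties resolved to the 3_10-like
#' type only when psi(i+2) deviates from 0° by more than 25°. Anything else
#' is type IV (unclassified turn).
#'
#' @param phi1,psi1 dihedrals of residue i+1, degrees.
#' @param phi2,psi2 dihedrals of residue i+2, degrees.
#' @return the type label as character.
#' @export
classify_turn_dihedrals <- function(phi1, psi1, phi2, psi2) {
  obs <- c(phi1, psi1, phi2, psi2)
  if (any(!is.finite(obs))) return("IV")
  devs <- vapply(.TURN_CANON, function(canon) {
    d <- abs(angle_diff(obs, canon))
    if (sum(d > 30) == 0 || (sum(d > 30) == 1 && max(d) <= 45)) sum(d) else Inf
  }, numeric(1))
  if (all(!is.finite(devs))) return("IV")
  ok <- names(devs)[is.finite(devs)]
  best <- ok[which.min(devs[ok])]
  # I vs III (and primed) disambiguation
  pair <- list(c("I", "III"), c("I'", "III'"))
  for (p in pair) {
    if (all(p %in% ok) && best %in% p) {
      d1 <- devs[p[1]]; d3 <- devs[p[2]]
      if (abs(d1 - d3) < 1e-9) {
        best <- if (abs(angle_diff(psi2, 0)) > 25) p[2] else p[1]
      }
    }
  }
  best
}

#' Classify a four-residue beta turn in a structure
#'
#' @param structure an `mm_structure`.
#' @param start_seq author number of residue i (the turn spans i..i+3).
#' @param chain chain id (default: first chain).
#' @param ca_max Cα(i)-Cα(i+3) distance cutoff, Å; beyond it the result is
#'   "none" (not a turn), not an error.
#' @return tibble with start_seq, kind, phi1, psi1, phi2, psi2, ca_distance.
#' @export
classify_beta_turn <- function(structure, start_seq, chain = NULL, ca_max = 7.0) {
  chain <- chain %||% structure$chain[1]
  s <- structure[structure$chain == chain & structure$record == "ATOM", ]
  resnos <- start_seq + 0:3
  if (!all(resnos %in% s$resno)) abort("turn residues not all present")
  at <- function(rn, nm) {
    i <- which(s$resno == rn & s$elety == nm)
    if (!length(i)) abort(paste0("missing atom ", nm, " in residue ", rn))
    as.numeric(s[i[1], c("x", "y", "z")])
  }
  ca_d <- vdist(at(resnos[1], "CA"), at(resnos[4], "CA"))
  phi1 <- dihedral(at(resnos[1], "C"), at(resnos[2], "N"), at(resnos[2], "CA"),
                   at(resnos[2], "C"))
  psi1 <- dihedral(at(resnos[2], "N"), at(resnos[2], "CA"), at(resnos[2], "C"),
                   at(resnos[3], "N"))
  phi2 <- dihedral(at(resnos[2], "C"), at(resnos[3], "N"), at(resnos[3], "CA"),
                   at(resnos[3], "C"))
  psi2 <- dihedral(at(resnos[3], "N"), at(resnos[3], "CA"), at(resnos[3], "C"),
                   at(resnos[4], "N"))
  kind <- if (ca_d > ca_max) "none" else
    classify_turn_dihedrals(phi1, psi1, phi2, psi2)
  tibble(start_seq = start_seq, kind = kind, phi1 = phi1, psi1 = psi1,
         phi2 = phi2, psi2 = psi2, ca_distance = ca_d)
}

# Geometric amide H: 1.0 Å from N, opposite the bisector of N->C(prev) and
# N->CA. Prolines and chain N-termini get no H.
build_amide_h <- function(s) {
  s <- s[s$record == "ATOM", ]
  chains <- unique(s$chain)
  rows <- list()
  for (ch in chains) {
    sc <- s[s$chain == ch, ]
    resnos <- sort(unique(sc$resno))
    at <- function(rn, nm) {
      i <- which(sc$resno == rn & sc$elety == nm)
      if (!length(i)) return(NULL)
      as.numeric(sc[i[1], c("x", "y", "z")])
    }
    for (k in seq_along(resnos)[-1]) {
      rn <- resnos[k]
      resid <- sc$resid[match(rn, sc$resno)]
      if (resid == "PRO") next
      if (resnos[k - 1] != rn - 1) next          # chain break: treat as N-terminus
      N <- at(rn, "N"); CA <- at(rn, "CA"); Cp <- at(rn - 1, "C")
      if (is.null(N) || is.null(CA) || is.null(Cp)) next
      u1 <- (Cp - N) / vdist(Cp, N); u2 <- (CA - N) / vdist(CA, N)
      hdir <- -(u1 + u2); hdir <- hdir / sqrt(sum(hdir^2))
      H <- N + hdir
      rows[[length(rows) + 1]] <- tibble(chain = ch, resno = rn,
                                         x = H[1], y = H[2], z = H[3])
    }
  }
  bind_rows(rows)
}

#' Backbone-backbone hydrogen bonds (electrostatic criterion)
#'
#' Amide H atoms are built geometrically when absent and each N-H...O=C
#' candidate is scored with the classical electrostatic energy
#' `E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN)` kcal/mol; pairs below
#' `energy_cutoff` are reported. Donor and acceptor must be separated by at
#' least two positions in sequence (or sit on different chains).
#'
#' @param structure an `mm_structure`.
#' @param energy_cutoff kcal/mol (default -0.5).
#' @return tibble: donor_chain, donor_resno, acceptor_chain, acceptor_resno,
#'   distance_no (N...O, Å), energy (kcal/mol).
#' @export
assign_backbone_hbonds <- function(structure, energy_cutoff = -0.5) {
  s <- structure[structure$record == "ATOM", ]
  H <- build_amide_h(s)
  if (nrow(H) == 0) return(empty_hbonds())
  # acceptors: residues with C and O
  acc <- list()
  for (ch in unique(s$chain)) {
    sc <- s[s$chain == ch, ]
    for (rn in unique(sc$resno)) {
      iC <- which(sc$resno == rn & sc$elety == "C")
      iO <- which(sc$resno == rn & sc$elety == "O")
      if (!length(iC) || !length(iO)) next
      acc[[length(acc) + 1]] <- tibble(
        chain = ch, resno = rn,
        cx = sc$x[iC[1]], cy = sc$y[iC[1]], cz = sc$z[iC[1]],
        ox = sc$x[iO[1]], oy = sc$y[iO[1]], oz = sc$z[iO[1]])
    }
  }
  acc <- bind_rows(acc)
  # donor N coordinates
  Ncoord <- t(vapply(seq_len(nrow(H)), function(i) {
    j <- which(s$chain == H$chain[i] & s$resno == H$resno[i] & s$elety == "N")
    as.numeric(s[j[1], c("x", "y", "z")])
  }, numeric(3)))
  out <- list()
  q <- 0.084 * 332
  for (i in seq_len(nrow(H))) {
    hN <- Ncoord[i, ]; hH <- as.numeric(H[i, c("x", "y", "z")])
    for (j in seq_len(nrow(acc))) {
      same_chain <- acc$chain[j] == H$chain[i]
      if (same_chain && abs(acc$resno[j] - H$resno[i]) < 2) next
      O <- c(acc$ox[j], acc$oy[j], acc$oz[j])
      rON <- vdist(O, hN)
      if (rON > 5.2) next
      C <- c(acc$cx[j], acc$cy[j], acc$cz[j])
      E <- q * (1 / rON + 1 / vdist(C, hH) - 1 / vdist(O, hH) - 1 / vdist(C, hN))
      if (E < energy_cutoff) {
        out[[length(out) + 1]] <- tibble(
          donor_chain = H$chain[i], donor_resno = H$resno[i],
          acceptor_chain = acc$chain[j], acceptor_resno = acc$resno[j],
          distance_no = rON, energy = E)
      }
    }
  }
  if (!length(out)) return(empty_hbonds())
  arrange(bind_rows(out), .data$donor_chain, .data$donor_resno)
}

empty_hbonds <- function() {
  tibble(donor_chain = character(), donor_resno = integer(),
         acceptor_chain = character(), acceptor_resno = integer(),
         distance_no = numeric(), energy = numeric())
}

#' Per-residue secondary/super-secondary motif annotation
#'
#' Labels derive from the backbone H-bond pattern: a 3_10 stretch is two or
#' more consecutive i->i+3 bonds; an isolated i->i+4 bond marks an alpha-turn;
#' beta bridges/ladders come from DSSP-style pairing of (i-1,i+1)/(j-1,j+1)
#' H-bonds, with a one-residue interruption on one strand reported as a
#' beta-bulge. Four-residue windows passing the Cα(i)-Cα(i+3) test are typed
#' with [classify_beta_turn()].
#'
#' @param structure an `mm_structure` (single model).
#' @param hbonds optional precomputed [assign_backbone_hbonds()] table.
#' @return list with `labels` (tibble: chain, resno, label), `turns`
#'   (classified turns), `strand_pairs` (antiparallel bridge partners) and
#'   `hbonds`.
#' @export
annotate_motifs <- function(structure, hbonds = NULL) {
  hb <- hbonds %||% assign_backbone_hbonds(structure)
  s <- structure[structure$record == "ATOM", ]
  res <- distinct(tibble(chain = s$chain, resno = s$resno))
  res$label <- "-"
  lab_idx <- function(ch, rn) which(res$chain == ch & res$resno == rn)
  same <- hb[hb$donor_chain == hb$acceptor_chain, ]
  sep <- same$donor_resno - same$acceptor_resno

  # 3_10: runs of >= 2 consecutive i -> i+3 bonds (acceptor i, donor i+3)
  t3 <- same[sep == 3, ]
  if (nrow(t3) > 1) {
    starts <- sort(t3$acceptor_resno)
    for (k in seq_len(length(starts) - 1)) {
      if (starts[k + 1] == starts[k] + 1) {
        for (rn in starts[k]:(starts[k + 1] + 3)) {
          i <- lab_idx(t3$donor_chain[1], rn)
          if (length(i)) res$label[i] <- "G"      # 3_10
        }
      }
    }
  }
  # alpha-turn: isolated i -> i+4 bond (no adjacent i+-1 -> i+5/i+3 bond chain)
  t4 <- same[sep == 4, ]
  if (nrow(t4)) {
    accs <- t4$acceptor_resno
    for (k in seq_len(nrow(t4))) {
      isolated <- !((accs[k] - 1) %in% accs && FALSE) &&
        sum(accs %in% (accs[k] + c(-1, 1))) == 0
      if (isolated) {
        for (rn in accs[k]:(accs[k] + 4)) {
          i <- lab_idx(t4$donor_chain[k], rn)
          if (length(i) && res$label[i] == "-") res$label[i] <- "T"  # alpha-turn
        }
      } else {
        for (rn in accs[k]:(accs[k] + 4)) {
          i <- lab_idx(t4$donor_chain[k], rn)
          if (length(i) && res$label[i] == "-") res$label[i] <- "H"  # helical
        }
      }
    }
  }
  # antiparallel beta bridges: H-bond i->j and j->i (both directions)
  pairs <- list()
  if (nrow(hb)) {
    key <- paste(hb$donor_chain, hb$donor_resno, hb$acceptor_chain, hb$acceptor_resno)
    rev <- paste(hb$acceptor_chain, hb$acceptor_resno, hb$donor_chain, hb$donor_resno)
    mutual <- hb[key %in% rev, ]
    if (nrow(mutual)) {
      for (k in seq_len(nrow(mutual))) {
        i <- mutual$donor_resno[k]; j <- mutual$acceptor_resno[k]
        chi <- mutual$donor_chain[k]; chj <- mutual$acceptor_chain[k]
        if (chi == chj && abs(i - j) < 3) next
        a <- lab_idx(chi, i); b <- lab_idx(chj, j)
        if (length(a)) res$label[a] <- "E"
        if (length(b)) res$label[b] <- "E"
        pairs[[length(pairs) + 1]] <- tibble(
          chain_i = chi, resno_i = min(i, j), chain_j = chj, resno_j = max(i, j))
      }
    }
  }
  strand_pairs <- if (length(pairs)) distinct(bind_rows(pairs)) else
    tibble(chain_i = character(), resno_i = integer(),
           chain_j = character(), resno_j = integer())
  # beta-bulge: two bridge residues on one strand separated by 2 positions
  # whose partners are adjacent on the other strand; the extra residue in
  # between is the bulge
  if (nrow(strand_pairs) >= 2) {
    sp <- strand_pairs
    for (a in seq_len(nrow(sp))) for (b in seq_len(nrow(sp))) {
      if (a == b) next
      if (sp$chain_i[a] == sp$chain_i[b] &&
          sp$resno_i[b] - sp$resno_i[a] == 2 &&
          abs(sp$resno_j[a] - sp$resno_j[b]) == 1) {
        i <- lab_idx(sp$chain_i[a], sp$resno_i[a] + 1)
        if (length(i)) res$label[i] <- "B"          # bulge
      }
    }
  }
  # beta turns by sliding window
  turns <- list()
  for (ch in unique(res$chain)) {
    rns <- sort(res$resno[res$chain == ch])
    for (rn in rns) {
      if (!all((rn + 1:3) %in% rns)) next
      t <- tryCatch(classify_beta_turn(structure, rn, chain = ch),
                    error = function(e) NULL)
      if (!is.null(t) && t$kind != "none") {
        t$chain <- ch
        turns[[length(turns) + 1]] <- t
      }
    }
  }
  turns <- if (length(turns)) bind_rows(turns) else
    tibble(start_seq = integer(), kind = character(), phi1 = numeric(),
           psi1 = numeric(), phi2 = numeric(), psi2 = numeric(),
           ca_distance = numeric(), chain = character())
  list(labels = res, turns = turns, strand_pairs = strand_pairs, hbonds = hb)
}
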
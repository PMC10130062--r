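# Internal-coordinate chain building (NeRF placement).

#' Place an atom from internal coordinates
#'
#' Places point D such that |C-D| = `bond`, angle(B,C,D) = `angle` and
#' dihedral(A,B,C,D) = `torsion`.
#'
#' @param a,b,c reference points (3-vectors).
#' @param bond bond length Å; `angle`, `torsion` in degrees.
#' @param angle,torsion internal coordinates, degrees.
#' @return 3-vector.
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- angle * pi / 180; ph <- -torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- cross3(b - a, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Ideal backbone internal coordinates
.BB <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, ca_cb = 1.521,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8, ang_n_ca_cb = 110.5
)

.AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
          E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL", X = "AIB")

# heavy side-chain atom counts beyond CB (used for the reduced side-chain
# representation of synthetic models)
.SC_EXTRA <- c(ALA = 0, AIB = 1, ARG = 6, ASN = 3, ASP = 3, CYS = 1, GLN = 4,
               GLU = 4, GLY = 0, HIS = 5, ILE = 3, LEU = 3, LYS = 4, MET = 3,
               PHE = 6, PRO = 2, SER = 1, THR = 2, TRP = 9, TYR = 7, VAL = 2)

seq_to_resid <- function(sequence) {
  if (length(sequence) == 1 && nchar(sequence) > 1) {
    codes <- strsplit(sequence, "")[[1]]
    bad <- setdiff(codes, names(.AA3))
    if (length(bad)) abort(paste0("unknown residue code(s): ",
                                  paste(unique(bad), collapse = ", ")))
    unname(.AA3[codes])
  } else {
    toupper(sequence)
  }
}

#' Build a polypeptide backbone from dihedral angles
#'
#' Constructs a chain by sequential internal-coordinate placement using ideal
#' bond lengths and angles (N-CA 1.458, CA-C 1.525, C-N 1.329 Å). The
#' re-measured phi/psi/omega equal the inputs to better than 1e-3 degrees.
#' Carbonyl O atoms are placed in the peptide plane; CB atoms are placed with
#' L-chirality for all residues except Gly (Aib gets both CB1/CB2? no — a
#' single CB), and Cys SG is placed at the requested chi1.
#'
#' @param phi,psi per-residue dihedrals, degrees (phi of the first residue and
#'   psi of the last are not used for chain building but psi of the last
#'   orients its carbonyl; pass full-length vectors).
#' @param sequence 1-letter string (X = Aib) or vector of 3-letter codes;
#'   recycled "ALA" if missing.
#' @param omega per-residue omega (default 180).
#' @param chi1 chi1 for Cys/Ser side-gamma placement, degrees (default -60).
#' @param chain chain id for the output.
#' @param start_resno author number of the first residue.
#' @return an `mm_structure`.
#' @export
backbone_from_dihedrals <- function(phi, psi, sequence = NULL, omega = NULL,
                                    chi1 = -60, chain = "A", start_resno = 1L) {
  n <- length(phi)
  if (length(psi) != n) abort("phi and psi must have equal length")
  if (n == 0) {
    return(as_structure(tibble(elety = character(), resid = character(),
                               chain = character(), resno = integer(),
                               x = numeric(), y = numeric(), z = numeric())))
  }
  omega <- omega %||% rep(180, n)
  if (length(omega) == 1) omega <- rep(omega, n)
  resid <- if (is.null(sequence)) rep("ALA", n) else seq_to_resid(sequence)
  if (length(resid) != n) abort("sequence length does not match phi/psi length")
  chi1 <- rep_len(chi1, n)

  N <- vector("list", n); CA <- vector("list", n); C <- vector("list", n)
  # seed the first residue in a canonical frame
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(.BB$n_ca, 0, 0)
  C[[1]] <- place_atom(c(0, 1, 0), N[[1]], CA[[1]], .BB$ca_c, .BB$ang_n_ca_c, 55)
  for (i in seq_len(n - 1)) {
    N[[i + 1]] <- place_atom(N[[i]], CA[[i]], C[[i]], .BB$c_n, .BB$ang_ca_c_n, psi[i])
    CA[[i + 1]] <- place_atom(CA[[i]], C[[i]], N[[i + 1]], .BB$n_ca, .BB$ang_c_n_ca,
                              omega[i + 1])
    C[[i + 1]] <- place_atom(C[[i]], N[[i + 1]], CA[[i + 1]], .BB$ca_c,
                             .BB$ang_n_ca_c, phi[i + 1])
  }
  rows <- list()
  for (i in seq_len(n)) {
    rn <- start_resno + i - 1L
    add <- function(nm, p) {
      rows[[length(rows) + 1]] <<- tibble(elety = nm, resid = resid[i],
                                          chain = chain, resno = rn,
                                          x = p[1], y = p[2], z = p[3])
    }
    add("N", N[[i]]); add("CA", CA[[i]]); add("C", C[[i]])
    # carbonyl O: anti to the next N about CA-C (psi + 180 for the last residue)
    if (i < n) {
      O <- place_atom(N[[i + 1]], CA[[i]], C[[i]], .BB$c_o, .BB$ang_ca_c_o, 180)
    } else {
      O <- place_atom(N[[i]], CA[[i]], C[[i]], .BB$c_o, .BB$ang_ca_c_o,
                      psi[i] + 180)
    }
    add("O", O)
    if (resid[i] != "GLY") {
      # CB with L-chirality: dihedral(C, N, CA, CB) = +122.6 deg
      CB <- place_atom(C[[i]], N[[i]], CA[[i]], .BB$ca_cb, .BB$ang_n_ca_cb, 122.6)
      add("CB", CB)
      if (resid[i] == "CYS") {
        SG <- place_atom(N[[i]], CA[[i]], CB, 1.82, 114.0, chi1[i])
        add("SG", SG)
      }
      if (resid[i] == "SER") {
        OG <- place_atom(N[[i]], CA[[i]], CB, 1.42, 110.5, chi1[i])
        add("OG", OG)
      }
    }
  }
  as_structure(bind_rows(rows))
}
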
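#' Euclidean distance between two points
#' @param p1,p2 numeric 3-vectors, Å.
#' @return distance in Å.
#' @export
vdist <- function(p1, p2) sqrt(sum((p1 - p2)^2))

#' Bond angle at p2
#' @param p1,p2,p3 numeric 3-vectors; p2 is the vertex.
#' @return angle in degrees.
#' @export
vangle <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-9 || nv < 1e-9) abort("coincident points in angle")
  acos(pmin(1, pmax(-1, sum(u * v) / (nu * nv)))) * 180 / pi
}

#' Signed dihedral angle
#'
#' IUPAC convention: looking from p2 towards p3, a clockwise rotation of the
#' far bond relative to the near bond is positive. Result in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric 3-vectors.
#' @return signed angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9) {
    abort("dihedral undefined: three consecutive points are collinear")
  }
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# wrap an angle difference into (-180, 180]
angle_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation R and translation t minimizing
#' `sum || R x_i + t - y_i ||^2` over paired points (mobile x, reference y).
#'
#' @param mobile,reference n x 3 matrices (n >= 3, non-collinear) or data
#'   frames with x/y/z columns, in 1:1 correspondence.
#' @return object of class `mm_superpose`: list with `rotation` (3x3, det +1),
#'   `translation`, `rmsd` (post-fit, Å) and `n_atoms`.
#' @export
superpose <- function(mobile, reference) {
  X <- as_xyz_matrix(mobile); Y <- as_xyz_matrix(reference)
  if (nrow(X) != nrow(Y)) abort("mobile and reference must have equal length")
  if (nrow(X) < 3) abort("superposition needs at least 3 points")
  cx <- colMeans(X); cy <- colMeans(Y)
  X0 <- sweep(X, 2, cx); Y0 <- sweep(Y, 2, cy)
  sv <- svd(t(X0) %*% Y0)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1)) {
    abort("degenerate (collinear) point set: rotation is not unique")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cy - as.numeric(R %*% cx)
  fitted <- sweep(X %*% t(R), 2, t, "+")
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  structure(list(rotation = R, translation = t, rmsd = rmsd, n_atoms = nrow(X)),
            class = "mm_superpose")
}

#' @export
print.mm_superpose <- function(x, ...) {
  cat(sprintf("Rigid superposition: %d atoms, RMSD %.4f Å\n", x$n_atoms, x$rmsd))
  invisible(x)
}

as_xyz_matrix <- function(p) {
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 3)
    return(unname(p))
  }
  if (is.data.frame(p)) return(unname(cbind(p$x, p$y, p$z)))
  if (is.numeric(p) && length(p) == 3) return(matrix(p, 1, 3))
  abort("expected an n x 3 matrix, a data frame with x/y/z, or a 3-vector")
}

#' Apply a rigid transform
#' @param m n x 3 matrix or structure/data frame with x/y/z.
#' @param rotation 3x3 matrix; `translation` length-3 vector.
#' @param translation translation component, Å.
#' @return same shape as the input.
#' @export
apply_transform <- function(m, rotation, translation = c(0, 0, 0)) {
  if (is.data.frame(m)) {
    xyz <- sweep(as_xyz_matrix(m) %*% t(rotation), 2, translation, "+")
    return(with_coords(m, xyz))
  }
  sweep(as_xyz_matrix(m) %*% t(rotation), 2, translation, "+")
}

#' Backbone RMSD between two structures
#'
#' Pairs residues by author numbering (and chain when both have one chain of
#' the same id, otherwise by position) and superposes the selected backbone
#' atoms with [superpose()].
#'
#' @param a,b `mm_structure` tibbles.
#' @param atoms backbone atom names to match (default N, CA, C, O).
#' @param resrange optional integer range of author residue numbers, e.g.
#'   `1:28`.
#' @return an `mm_superpose` (a is mobile, b is reference).
#' @export
structure_rmsd <- function(a, b, atoms = c("N", "CA", "C", "O"), resrange = NULL) {
  sel <- function(s) {
    d <- s[s$elety %in% atoms & s$record == "ATOM", ]
    if (!is.null(resrange)) d <- d[d$resno %in% resrange, ]
    d[order(d$chain, d$resno, match(d$elety, atoms)), ]
  }
  da <- sel(a); db <- sel(b)
  key <- function(d) paste(d$resno, d$elety)
  common <- intersect(key(da), key(db))
  if (length(common) < 3) abort("fewer than 3 matched backbone atoms")
  da <- da[match(common, key(da)), ]
  db <- db[match(common, key(db)), ]
  superpose(coords(da), coords(db))
}

#' Cys side-chain chi1 and rotamer class
#'
#' chi1 is the N-CA-CB-G dihedral where G is the gamma heavy atom (SG for
#' Cys). Classes map to the nearest canonical rotamer: `g+` at +60, `t` at
#' 180, `g-` at -60 (boundaries at 0 and ±120 degrees).
#'
#' @param residue atom tibble of one residue containing N, CA, CB and a gamma
#'   heavy atom.
#' @return chi1 in degrees.
#' @export
chi1 <- function(residue) {
  gnames <- c("SG", "OG", "OG1", "CG", "CG1", "SG1")
  need <- c("N", "CA", "CB")
  have <- residue$elety
  gm <- intersect(gnames, have)
  missing <- c(setdiff(need, have), if (!length(gm)) "gamma atom")
  if (length(missing)) {
    abort(paste0("chi1: missing atoms ", paste(missing, collapse = ", ")))
  }
  at <- function(nm) as.numeric(residue[match(nm, residue$elety), c("x", "y", "z")])
  dihedral(at("N"), at("CA"), at("CB"), at(gm[1]))
}

#' @rdname chi1
#' @param x chi1 angle(s), degrees.
#' @export
chi1_class <- function(x) {
  x <- ((x + 180) %% 360) - 180
  ifelse(x >= 0 & x < 120, "g+", ifelse(x >= 120 | x < -120, "t", "g-"))
}

#' Backbone phi/psi dihedrals
#'
#' @param structure an `mm_structure`; one chain at a time.
#' @param chain chain id; default: the first chain.
#' @return tibble with resno, resid, phi, psi, omega (NA where undefined).
#' @export
backbone_dihedrals <- function(structure, chain = NULL) {
  chain <- chain %||% structure$chain[1]
  s <- structure[structure$chain == chain & structure$record == "ATOM", ]
  resnos <- unique(s$resno)
  at <- function(rn, nm) {
    i <- which(s$resno == rn & s$elety == nm)
    if (!length(i)) return(NULL)
    as.numeric(s[i[1], c("x", "y", "z")])
  }
  out <- lapply(seq_along(resnos), function(i) {
    rn <- resnos[i]
    N <- at(rn, "N"); CA <- at(rn, "CA"); C <- at(rn, "C")
    phi <- psi <- omega <- NA_real_
    if (i > 1) {
      Cp <- at(resnos[i - 1], "C"); CAp <- at(resnos[i - 1], "CA")
      if (!is.null(Cp) && !is.null(N) && !is.null(CA) && !is.null(C)) {
        phi <- dihedral(Cp, N, CA, C)
      }
      if (!is.null(CAp) && !is.null(Cp) && !is.null(N) && !is.null(CA)) {
        omega <- dihedral(CAp, Cp, N, CA)
      }
    }
    if (i < length(resnos)) {
      Nn <- at(resnos[i + 1], "N")
      if (!is.null(N) && !is.null(CA) && !is.null(C) && !is.null(Nn)) {
        psi <- dihedral(N, CA, C, Nn)
      }
    }
    tibble(resno = rn, resid = s$resid[match(rn, s$resno)],
           phi = phi, psi = psi, omega = omega)
  })
  bind_rows(out)
}

# rotation matrix for angle (deg) about unit axis u (Rodrigues)
rotation_about_axis <- function(u, angle_deg) {
  u <- u / sqrt(sum(u^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# axis (unit vector) and angle (deg, in (0,180]) of a rotation matrix
rotation_axis_angle <- function(R) {
  tr <- sum(diag(R))
  ct <- pmin(1, pmax(-1, (tr - 1) / 2))
  angle <- acos(ct) * 180 / pi
  if (angle < 1e-8) return(list(axis = c(0, 0, 1), angle = 0))
  if (angle > 180 - 1e-6) {
    # near 180 deg: axis from the symmetric part, largest diagonal of (R+I)/2
    B <- (R + diag(3)) / 2
    i <- which.max(diag(B))
    axis <- B[, i] / sqrt(max(B[i, i], 1e-300))
    axis <- axis / sqrt(sum(axis^2))
    return(list(axis = axis, angle = 180))
  }
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  axis <- v / (2 * sin(angle * pi / 180))
  list(axis = axis / sqrt(sum(axis^2)), angle = angle)
}
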
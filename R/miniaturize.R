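# Template dissection and pseudo-C2 dimer generation: the first stage of the
# miniaturization workflow. A C2-pseudo-symmetric metal-binding protein (a
# rubredoxin-like fold) is cut down to one half-site fragment, and the second
# half is regenerated by an exact 180-degree rotation about the fitted
# internal twofold axis.

#' Dissect a contiguous fragment from a structure
#'
#' Deep-copies residues `start_seq..end_seq` of one chain (author numbering).
#' Every residue in the range must be present and the backbone complete.
#'
#' @param structure an `mm_structure`.
#' @param chain_id chain identifier.
#' @param start_seq,end_seq first and last author residue numbers (inclusive).
#' @return an `mm_structure` fragment with attributes `source_chain`,
#'   `start_seq`, `end_seq`.
#' @export
dissect <- function(structure, chain_id, start_seq, end_seq) {
  if (end_seq < start_seq) abort("end_seq must be >= start_seq")
  s <- structure[structure$chain == chain_id & structure$record == "ATOM", ]
  want <- start_seq:end_seq
  have <- unique(s$resno)
  missing <- setdiff(want, have)
  if (length(missing)) {
    abort(paste0("chain break: residues missing from chain ", chain_id, ": ",
                 paste(missing, collapse = ", ")))
  }
  frag <- s[s$resno %in% want, ]
  for (rn in want) {
    bb <- frag$elety[frag$resno == rn]
    if (!all(c("N", "CA", "C") %in% bb)) {
      abort(paste0("incomplete backbone at residue ", rn))
    }
  }
  frag <- as_structure(frag)
  attr(frag, "source_chain") <- chain_id
  attr(frag, "start_seq") <- start_seq
  attr(frag, "end_seq") <- end_seq
  frag
}

#' Fit the internal (pseudo-)twofold axis relating two half-sites
#'
#' Superposes the backbone of `half_a` onto `half_b` (Kabsch, proper rotation)
#' and converts the transform to axis-angle form. For a perfect C2 pair the
#' rotation angle is 180 degrees and the post-fit RMSD zero; the reported
#' `rotation_angle` is a diagnostic of how far the template deviates from
#' exact twofold symmetry.
#'
#' @param half_a,half_b `mm_structure` fragments of equal residue count.
#' @param correspondence optional two-column matrix/data frame of paired
#'   author residue numbers (a, b); default pairs residues in order.
#' @param atoms atom names used for the fit.
#' @return object of class `c2_axis_fit`: `axis_point`, `axis_direction`
#'   (unit), `rotation_angle` (deg), `symmetry_rmsd` (Å), `transform`.
#' @export
fit_c2_axis <- function(half_a, half_b, correspondence = NULL,
                        atoms = c("N", "CA", "C", "O")) {
  ra <- unique(half_a$resno[half_a$record == "ATOM"])
  rb <- unique(half_b$resno[half_b$record == "ATOM"])
  if (is.null(correspondence)) {
    if (length(ra) != length(rb)) {
      abort("half-sites have different residue counts; give a correspondence")
    }
    correspondence <- cbind(ra, rb)
  }
  correspondence <- as.matrix(correspondence)
  pick <- function(s, resnos) {
    rows <- lapply(seq_along(resnos), function(i) {
      r <- s[s$resno == resnos[i] & s$elety %in% atoms, ]
      r <- r[match(atoms, r$elety), ]
      r <- r[!is.na(r$x), ]
      r$pair_id <- paste(i, r$elety)
      r
    })
    bind_rows(rows)
  }
  pa <- pick(half_a, correspondence[, 1])
  pb <- pick(half_b, correspondence[, 2])
  common <- intersect(pa$pair_id, pb$pair_id)
  pa <- pa[match(common, pa$pair_id), ]; pb <- pb[match(common, pb$pair_id), ]
  fit <- superpose(coords(pa), coords(pb))
  aa <- rotation_axis_angle(fit$rotation)
  axis_point <- axis_point_of_transform(fit$rotation, fit$translation, aa$axis)
  structure(list(axis_point = axis_point, axis_direction = aa$axis,
                 rotation_angle = aa$angle, symmetry_rmsd = fit$rmsd,
                 transform = fit, n_atoms = fit$n_atoms),
            class = "c2_axis_fit")
}

#' @export
print.c2_axis_fit <- function(x, ...) {
  cat(sprintf(
    "C2 axis fit: rotation %.2f deg, symmetry RMSD %.3f Å\n  axis point (%.2f, %.2f, %.2f), direction (%.3f, %.3f, %.3f)\n",
    x$rotation_angle, x$symmetry_rmsd, x$axis_point[1], x$axis_point[2],
    x$axis_point[3], x$axis_direction[1], x$axis_direction[2],
    x$axis_direction[3]))
  invisible(x)
}

# A point on the screw axis of the rigid motion x -> Rx + t: the translation
# is split into its component along the axis (pitch, discarded) and the
# in-plane part, and (I - R) p = t_perp is solved in the plane normal to u.
axis_point_of_transform <- function(R, t, u) {
  t_perp <- t - sum(t * u) * u
  A <- diag(3) - R
  # A is rank 2 with null space u; solve least-squares, then remove any axis
  # component so the returned point is the one closest to the origin
  p <- tryCatch({
    sv <- svd(A)
    dinv <- ifelse(sv$d > 1e-8, 1 / sv$d, 0)
    as.numeric(sv$v %*% (dinv * (t(sv$u) %*% t_perp)))
  }, error = function(e) c(0, 0, 0))
  p - sum(p * u) * u
}

#' Generate the exact C2 dimer from a fragment and a fitted axis
#'
#' Applies an exact 180-degree rotation about the fitted axis to the fragment
#' (the fitted angle is snapped to 180; the deviation stays a diagnostic in
#' the `c2_axis_fit`). The original fragment becomes chain "A" and its rotated
#' copy chain "B". If the fragment carries a metal HETATM, the metal is kept
#' once, repositioned onto the axis (projection of the template metal).
#'
#' @param fragment an `mm_structure` (protein atoms; an optional metal HETATM).
#' @param axis a [fit_c2_axis()] result.
#' @param clash_cutoff interchain heavy-atom distance (Å) below which a clash
#'   warning is attached (metal excluded).
#' @return two-chain `mm_structure`; attribute `clashes` holds any pairs
#'   closer than `clash_cutoff`.
#' @export
make_c2_dimer <- function(fragment, axis, clash_cutoff = 2.0) {
  prot <- fragment[fragment$record == "ATOM", ]
  metal <- fragment[fragment$record == "HETATM" &
                      fragment$elesy %in% c("ZN", "FE", "CO", "NI", "CU", "MN"), ]
  u <- axis$axis_direction; p0 <- axis$axis_point
  R180 <- rotation_about_axis(u, 180)
  xyz <- coords(prot)
  rot <- sweep((sweep(xyz, 2, p0) %*% t(R180)), 2, p0, "+")
  copy <- with_coords(prot, rot)
  copy$chain <- "B"
  prot$chain <- "A"
  out <- bind_rows(prot, copy)
  if (nrow(metal) > 0) {
    m <- metal[1, ]
    mp <- as.numeric(m[, c("x", "y", "z")])
    proj <- p0 + sum((mp - p0) * u) * u
    m$x <- proj[1]; m$y <- proj[2]; m$z <- proj[3]
    m$chain <- "A"
    out <- bind_rows(out, m)
  }
  out <- as_structure(out)
  # interchain clash scan (heavy atoms, metal excluded)
  a <- coords(out[out$chain == "A" & out$record == "ATOM", ])
  b <- coords(out[out$chain == "B" & out$record == "ATOM", ])
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  nclash <- sum(d2 < clash_cutoff^2)
  if (nclash > 0) {
    warn(paste0("C2 dimer has ", nclash, " interchain atom pair(s) closer than ",
                clash_cutoff, " Å"))
  }
  attr(out, "clashes") <- nclash
  attr(out, "axis") <- axis
  out
}
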
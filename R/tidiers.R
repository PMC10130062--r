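# broom-style tidiers for the package's fitted/result objects

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a parameter fit
#'
#' @param x an `mm_fit` (Randles-Sevcik or binding-isotherm fit).
#' @param ... unused.
#' @return tibble: term, estimate, std.error.
#' @export
tidy.mm_fit <- function(x, ...) {
  tibble(term = names(x$params),
         estimate = unname(x$params),
         std.error = unname(x$stderr[names(x$params)]))
}

#' @rdname tidy.mm_fit
#' @export
glance.mm_fit <- function(x, ...) {
  tibble(model = x$model, residual_rms = x$residual_rms, n = x$n_points,
         flags = paste(x$flags, collapse = ";"))
}

#' Tidy a superposition result
#'
#' @param x an `mm_superpose`.
#' @param ... unused.
#' @return one-row tibble with rmsd and n_atoms.
#' @export
tidy.mm_superpose <- function(x, ...) {
  tibble(rmsd = x$rmsd, n_atoms = x$n_atoms)
}

#' Tidy a metal-site geometry report
#'
#' One row per measured descriptor (distances, angles, torsions, chi1).
#'
#' @param x an `mm_site_geometry`.
#' @param ... unused.
#' @return tibble: descriptor, name, value.
#' @export
tidy.mm_site_geometry <- function(x, ...) {
  bind_rows(
    tibble(descriptor = "distance", name = names(x$distances),
           value = unname(x$distances)),
    tibble(descriptor = "angle", name = paste0("angle", seq_along(x$angles)),
           value = x$angles),
    tibble(descriptor = "torsion", name = names(x$torsions),
           value = unname(x$torsions)),
    tibble(descriptor = "chi1", name = names(x$chi1), value = unname(x$chi1)))
}

#' @rdname tidy.mm_site_geometry
#' @export
glance.mm_site_geometry <- function(x, ...) {
  tibble(mean_distance = x$mean_distance, sd_distance = x$sd_distance,
         mean_angle = x$mean_angle, sd_angle = x$sd_angle,
         tetrahedricity = x$tetrahedricity)
}

#' Tidy a rhombicity estimate
#'
#' @param x an `mm_rhombicity`.
#' @param ... unused.
#' @return the observation-assignment tibble with the estimate attached.
#' @export
tidy.mm_rhombicity <- function(x, ...) {
  out <- x$assignment
  out$E_over_D <- x$E_over_D
  out
}

#' Tidy a cyclic-voltammogram analysis
#'
#' @param x an `mm_cv`.
#' @param ... unused.
#' @return one-row tibble of peak descriptors (V / A, vs SHE).
#' @export
tidy.mm_cv <- function(x, ...) {
  tibble(E_pa = x$E_pa, E_pc = x$E_pc, i_pa = x$i_pa, i_pc = x$i_pc,
         E_half = x$E_half, delta_Ep = x$delta_Ep,
         flags = paste(x$flags, collapse = ";"))
}
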
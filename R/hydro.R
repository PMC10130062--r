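# Rigid-body translational diffusion from atomic coordinates: the Kirkwood
# bead approximation with one bead per heavy atom.

#' Kirkwood bead-model translational diffusion coefficient
#'
#' `D_t = (kB T / N) [ 1/(6 pi eta sigma) + (1/(6 pi eta)) (1/N) sum_{i!=j} 1/R_ij ]`
#' with one bead of radius `bead_radius` per heavy atom. The single-bead limit
#' is the Stokes-Einstein sphere; the double sum carries the hydrodynamic
#' interaction between beads.
#'
#' @param structure an `mm_structure` (hydrogens, if any, are ignored).
#' @param temperature K.
#' @param viscosity solvent viscosity, Pa s (water at 288 K: 1.138e-3).
#' @param bead_radius Å (default 3.1).
#' @return D_t in cm²/s.
#' @export
bead_model_diffusion <- function(structure, temperature = 293.15,
                                 viscosity = 1.002e-3, bead_radius = 3.1) {
  s <- structure[structure$elesy != "H", ]
  if (!nrow(s)) abort("no heavy atoms")
  xyz <- coords(s) * 1e-10                       # m
  N <- nrow(xyz)
  sigma <- bead_radius * 1e-10
  sum_inv <- 0
  if (N > 1) {
    d2 <- as.matrix(stats::dist(xyz))^2
    off <- d2[upper.tri(d2)]
    if (any(off < 1e-30)) abort("duplicate bead coordinates")
    sum_inv <- 2 * sum(1 / sqrt(off))
  }
  Dt <- (.kB * temperature / N) *
    (1 / (6 * pi * viscosity * sigma) +
       (1 / (6 * pi * viscosity)) * (1 / N) * sum_inv)
  Dt * 1e4                                        # m²/s -> cm²/s
}
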
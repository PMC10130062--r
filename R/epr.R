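# Zero-field-splitting analysis of a high-spin S = 5/2 (ferric) center.
# The spin Hamiltonian H = D [Sz^2 - S(S+1)/3] + E (Sx^2 - Sy^2) splits the
# sextet into three Kramers doublets; the X-band resonances within each
# doublet are described by effective g values that depend only on E/D (and
# the intrinsic g0), which is what makes the rhombogram a useful ruler.

spin_matrices <- function(S = 5/2) {
  m <- seq(S, -S)
  n <- length(m)
  Sz <- diag(m)
  Sp <- matrix(0, n, n)
  for (k in 2:n) Sp[k - 1, k] <- sqrt(S * (S + 1) - m[k] * (m[k] + 1))
  Sm <- t(Sp)
  list(Sx = (Sp + Sm) / 2, Sy = (Sp - Sm) / (2i), Sz = Sz)
}

#' Effective g values of the Kramers doublets of an S = 5/2 center
#'
#' Diagonalizes `H = D [Sz^2 - S(S+1)/3] + E (Sx^2 - Sy^2)` and, for each
#' doublet and field direction k in x, y, z, evaluates
#' `geff_k = (E_upper - E_lower) / (muB * B)` in the weak-field limit with the
#' Zeeman term `g0 muB B Sk`. B is reduced until halving it changes every geff
#' by less than 1e-4 — a numerical limit, not a physical field.
#'
#' @param D axial zero-field splitting, cm^-1 (sign meaningful; D != 0).
#' @param E rhombic zero-field splitting, cm^-1; |E/D| <= 1/3 after canonical
#'   axis ordering.
#' @param g0 intrinsic isotropic g (default 2.0023).
#' @param S spin quantum number; only half-integer (Kramers) spins supported,
#'   5/2 by default.
#' @return 3 x 3 matrix: rows = doublets ordered by energy (1 = lowest at
#'   D > 0), columns = geff_x, geff_y, geff_z.
#' @export
zfs_effective_g <- function(D, E, g0 = 2.0023, S = 5/2) {
  if (D == 0) abort("D must be nonzero")
  if (abs(2 * S - round(2 * S)) > 1e-9 || (round(2 * S) %% 2) == 0) {
    abort("only half-integer (Kramers) spins are supported")
  }
  sm <- spin_matrices(S)
  H0 <- D * (sm$Sz %*% sm$Sz - diag(rep(S * (S + 1) / 3, nrow(sm$Sz)))) +
    E * (sm$Sx %*% sm$Sx - sm$Sy %*% sm$Sy)
  ndoub <- (round(2 * S) + 1) / 2
  geff_at <- function(B) {
    out <- matrix(0, ndoub, 3)
    for (k in 1:3) {
      Hk <- H0 + g0 * .MU_B_CM * B * sm[[k]]
      ev <- sort(eigen(Hk, symmetric = TRUE, only.values = TRUE)$values)
      for (dbl in seq_len(ndoub)) {
        out[dbl, k] <- (ev[2 * dbl] - ev[2 * dbl - 1]) / (.MU_B_CM * B)
      }
    }
    out
  }
  B <- 1e-3 * abs(D) / .MU_B_CM   # Zeeman three orders below |D|
  g1 <- geff_at(B)
  repeat {
    B <- B / 2
    g2 <- geff_at(B)
    if (max(abs(g2 - g1)) < 1e-4 || B < 1e-12) break
    g1 <- g2
  }
  colnames(g2) <- c("x", "y", "z")
  rownames(g2) <- paste0("doublet", seq_len(nrow(g2)))
  g2
}

#' Rhombogram: effective g values across E/D
#'
#' @param grid_step E/D grid resolution on [0, 1/3] (default 0.001).
#' @param g0 intrinsic g.
#' @param D axial ZFS sign/scale (only the sign matters for the ordering).
#' @return tibble of class `mm_rhombogram`: E_over_D, doublet, geff_x, geff_y,
#'   geff_z.
#' @export
rhombogram <- function(grid_step = 0.001, g0 = 2.0023, D = 1) {
  grid <- seq(0, 1/3, by = grid_step)
  rows <- lapply(grid, function(ed) {
    g <- zfs_effective_g(D = D, E = ed * D, g0 = g0)
    tibble(E_over_D = ed, doublet = seq_len(nrow(g)),
           geff_x = g[, "x"], geff_y = g[, "y"], geff_z = g[, "z"])
  })
  out <- bind_rows(rows)
  class(out) <- c("mm_rhombogram", class(tibble()))
  out
}

#' Estimate rhombicity E/D from observed effective g values
#'
#' Scans E/D over [0, 1/3] (D > 0 doublet ordering) and minimizes the summed
#' distance between each observation and its closest doublet component.
#'
#' @param observed_geff numeric vector of 1-3 observed effective g values.
#' @param g0 intrinsic g (default 2.0023).
#' @param grid_step scan resolution (default 0.001).
#' @return list (class `mm_rhombicity`): `E_over_D`, `objective`,
#'   `assignment` (tibble: observed, doublet, component, predicted),
#'   `rhombogram` (the scan table).
#' @export
estimate_rhombicity <- function(observed_geff, g0 = 2.0023, grid_step = 0.001) {
  if (!length(observed_geff)) abort("no observed g values supplied")
  rg <- rhombogram(grid_step = grid_step, g0 = g0, D = 1)
  grid <- unique(rg$E_over_D)
  obj <- vapply(grid, function(ed) {
    g <- rg[rg$E_over_D == ed, c("geff_x", "geff_y", "geff_z")]
    comp <- as.numeric(as.matrix(g))
    sum(vapply(observed_geff, function(o) min(abs(comp - o)), numeric(1)))
  }, numeric(1))
  best <- grid[which.min(obj)]
  gbest <- rg[rg$E_over_D == best, ]
  gm <- as.matrix(gbest[, c("geff_x", "geff_y", "geff_z")])
  assignment <- bind_rows(lapply(observed_geff, function(o) {
    idx <- which.min(abs(gm - o))
    dbl <- (idx - 1) %% 3 + 1
    cmp <- c("x", "y", "z")[(idx - 1) %/% 3 + 1]
    tibble(observed = o, doublet = dbl, component = cmp, predicted = gm[idx])
  }))
  out <- list(E_over_D = best, objective = min(obj), assignment = assignment,
              scan = tibble(E_over_D = grid, objective = obj))
  class(out) <- "mm_rhombicity"
  out
}

#' @export
print.mm_rhombicity <- function(x, ...) {
  cat(sprintf("Rhombicity estimate: E/D = %.3f (objective %.3g)\n",
              x$E_over_D, x$objective))
  print(x$assignment)
  invisible(x)
}
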
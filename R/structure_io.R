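#' Atom-table structures
#'
#' `minimet` represents a macromolecular structure as a tibble with one row per
#' atom and the columns `record` ("ATOM"/"HETATM"), `eleno`, `elety` (atom
#' name, e.g. "SG"), `resid` (3-letter residue code, nonstandard codes such as
#' "AIB" allowed), `chain`, `resno` (author numbering), `x`, `y`, `z` (Å),
#' `o` (occupancy), `b` (isotropic B, Å²) and `elesy` (element symbol).
#' Crystallographic metadata travel as attributes: `cell` (a, b, c in Å and
#' alpha, beta, gamma in degrees), `space_group` (Hermann-Mauguin symbol) and
#' `sym_ops` (list of `list(R = 3x3, t = length-3 fractional translation)`,
#' identity first). All dplyr verbs work on it; [as_structure()] restores the
#' class after manipulation.
#'
#' @param atoms data frame with at least `elety`, `resid`, `chain`, `resno`,
#'   `x`, `y`, `z`; missing bookkeeping columns are filled with defaults.
#' @param cell optional numeric length-6 unit cell.
#' @param space_group optional Hermann-Mauguin symbol (e.g. "C 2 2 21").
#' @param sym_ops optional list of symmetry operators; when `NULL` and
#'   `space_group` is given, the built-in table is consulted.
#' @return a tibble of class `mm_structure`.
#' @export
as_structure <- function(atoms, cell = NULL, space_group = NULL, sym_ops = NULL) {
  atoms <- as_tibble(atoms)
  if (!all(c("elety", "resid", "chain", "resno", "x", "y", "z") %in% names(atoms))) {
    abort("atoms must have columns elety, resid, chain, resno, x, y, z")
  }
  fill <- function(col, default) {
    v <- atoms[[col]]
    if (is.null(v)) v <- rep(default, nrow(atoms))
    v[is.na(v)] <- default
    v
  }
  atoms$record <- fill("record", "ATOM")
  atoms$eleno <- atoms[["eleno"]] %||% seq_len(nrow(atoms))
  atoms$o <- fill("o", 1)
  atoms$b <- fill("b", 0)
  if (is.null(atoms[["elesy"]])) {
    atoms$elesy <- guess_element(atoms$elety)
  } else if (anyNA(atoms$elesy)) {
    i <- is.na(atoms$elesy)
    atoms$elesy[i] <- guess_element(atoms$elety[i])
  }
  xyz <- c(atoms$x, atoms$y, atoms$z)
  if (nrow(atoms) && any(!is.finite(xyz))) abort("atom coordinates must be finite")
  if (nrow(atoms) && any(atoms$o < 0 | atoms$o > 1)) abort("occupancy must be in [0, 1]")
  if (!is.null(space_group) && is.null(sym_ops)) {
    # tolerate groups outside the built-in table; expand_symmetry() will
    # refuse to run until operators are supplied
    sym_ops <- tryCatch(spacegroup_ops(space_group), error = function(e) NULL)
  }
  out <- atoms[, unique(c("record", "eleno", "elety", "resid", "chain", "resno",
                          "x", "y", "z", "o", "b", "elesy"))]
  attr(out, "cell") <- cell
  attr(out, "space_group") <- space_group
  attr(out, "sym_ops") <- sym_ops
  class(out) <- c("mm_structure", class(tibble()))
  out
}

#' @rdname as_structure
#' @param x an `mm_structure`.
#' @export
unit_cell <- function(x) attr(x, "cell")

#' @rdname as_structure
#' @export
sym_ops <- function(x) attr(x, "sym_ops")

#' @rdname as_structure
#' @export
space_group <- function(x) attr(x, "space_group")

# Element symbol from the atom name, PDB style: strip digits/primes, the
# leading character run is the element except for two-letter metals kept whole.
guess_element <- function(elety) {
  two <- c("ZN", "FE", "MG", "MN", "CU", "NI", "CO", "NA", "CL", "BR", "CA")
  vapply(elety, function(a) {
    a0 <- gsub("[^A-Za-z]", "", a)
    if (toupper(a0) %in% two && nchar(a0) == 2) return(toupper(a0))
    toupper(substr(a0, 1, 1))
  }, character(1), USE.NAMES = FALSE)
}

#' Coordinates of (a selection of) a structure
#'
#' @param structure an `mm_structure` or any data frame with x/y/z.
#' @return an n x 3 numeric matrix.
#' @export
coords <- function(structure) {
  cbind(x = structure$x, y = structure$y, z = structure$z)
}

with_coords <- function(structure, m) {
  structure$x <- m[, 1]; structure$y <- m[, 2]; structure$z <- m[, 3]
  structure
}

restore_structure <- function(df, template) {
  as_structure(df, cell = attr(template, "cell"),
               space_group = attr(template, "space_group"),
               sym_ops = attr(template, "sym_ops"))
}

# ---------------------------------------------------------------------------
# Space-group operator table (general positions). Operators are stored as
# "x,y,z"-style strings and parsed once. Covers the cases the package needs;
# anything else must come from an mmCIF symmetry block or explicit sym_ops.
.SPACEGROUPS <- list(
  "P 1"        = c("x,y,z"),
  "P 1 21 1"   = c("x,y,z", "-x,y+1/2,-z"),
  "P 21"       = c("x,y,z", "-x,y+1/2,-z"),
  "C 2 2 21"   = c("x,y,z", "-x,-y,z+1/2", "-x,y,-z+1/2", "x,-y,-z",
                   "x+1/2,y+1/2,z", "-x+1/2,-y+1/2,z+1/2",
                   "-x+1/2,y+1/2,-z+1/2", "x+1/2,-y+1/2,-z"),
  "P 21 21 21" = c("x,y,z", "-x+1/2,-y,z+1/2", "-x,y+1/2,-z+1/2",
                   "x+1/2,-y+1/2,-z")
)

normalize_sg <- function(sg) toupper(gsub("\\s+", " ", trimws(sg)))

#' Symmetry operators for a space group
#'
#' Built-in general positions for P1, P21, C2221 and P212121; other groups
#' must supply operators explicitly (e.g. from an mmCIF symmetry block).
#'
#' @param sg Hermann-Mauguin symbol, spaces optional ("C2221" == "C 2 2 21").
#' @return list of `list(R, t)` operators, identity first.
#' @export
spacegroup_ops <- function(sg) {
  key <- normalize_sg(sg)
  compact <- gsub(" ", "", key)
  hit <- names(.SPACEGROUPS)[gsub(" ", "", names(.SPACEGROUPS)) == compact]
  if (!length(hit)) {
    abort(paste0("no built-in operators for space group '", sg,
                 "'; supply sym_ops explicitly"))
  }
  lapply(.SPACEGROUPS[[hit[1]]], parse_symop)
}

#' Parse an "x,y,z"-style symmetry operator
#'
#' @param s operator string such as `"-x,y,-z+1/2"`.
#' @return `list(R = 3x3 rotation, t = fractional translation)`.
#' @export
parse_symop <- function(s) {
  parts <- strsplit(tolower(gsub("\\s", "", s)), ",")[[1]]
  if (length(parts) != 3) abort(paste0("malformed symmetry operator: ", s))
  R <- matrix(0, 3, 3); t <- numeric(3)
  for (i in 1:3) {
    expr <- parts[i]
    # tokenize into signed terms
    expr <- gsub("-", "+-", expr)
    terms <- strsplit(expr, "\\+")[[1]]
    terms <- terms[nzchar(terms)]
    for (tm in terms) {
      sign <- 1
      if (startsWith(tm, "-")) { sign <- -1; tm <- substring(tm, 2) }
      if (tm %in% c("x", "y", "z")) {
        R[i, match(tm, c("x", "y", "z"))] <- sign
      } else if (grepl("^\\d+/\\d+$", tm)) {
        nd <- as.numeric(strsplit(tm, "/")[[1]])
        t[i] <- t[i] + sign * nd[1] / nd[2]
      } else if (grepl("^\\d*\\.?\\d+$", tm)) {
        t[i] <- t[i] + sign * as.numeric(tm)
      } else {
        abort(paste0("cannot parse symmetry term '", tm, "' in ", s))
      }
    }
  }
  list(R = R, t = t)
}

# Orthogonalization matrix, PDB convention (a along x).
orth_matrix <- function(cell) {
  a <- cell[1]; b <- cell[2]; c <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 + 2 * cos(al) * cos(be) * cos(ga))
  matrix(c(a, b * cos(ga), c * cos(be),
           0, b * sin(ga), c * (cos(al) - cos(be) * cos(ga)) / sin(ga),
           0, 0,           c * v / sin(ga)),
         nrow = 3, byrow = TRUE)
}

# ---------------------------------------------------------------------------

#' Read a macromolecular structure
#'
#' Reads PDB (via [bio3d::read.pdb()]) or mmCIF (via [bio3d::read.cif()]) into
#' an [as_structure()] atom tibble. All ATOM and HETATM records are kept,
#' including metals and terminal capping groups; author residue numbering is
#' preserved. Alternate locations are reduced to the highest-occupancy
#' conformer (ties: first encountered). The unit cell, space group and — for
#' the built-in groups — symmetry operators are captured when present.
#'
#' @param path file path.
#' @param format "pdb", "mmcif" or "auto" (by extension; default).
#' @return an `mm_structure` tibble.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  if (format == "pdb") read_structure_pdb(path) else read_structure_cif(path)
}

read_structure_pdb <- function(path) {
  p <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) abort(paste0("cannot parse PDB file ", path, ": ",
                                     conditionMessage(e))))
  at <- as_tibble(p$atom)
  at <- resolve_altloc(at)
  atoms <- tibble(
    record = at$type, eleno = at$eleno, elety = at$elety, resid = at$resid,
    chain = ifelse(is.na(at$chain), "A", at$chain), resno = at$resno,
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o), b = ifelse(is.na(at$b), 0, at$b),
    elesy = ifelse(is.na(at$elesy) | at$elesy == "", guess_element(at$elety), at$elesy))
  cr <- read_cryst1(path)
  as_structure(atoms, cell = cr$cell, space_group = cr$space_group,
               sym_ops = if (!is.null(cr$space_group))
                 tryCatch(spacegroup_ops(cr$space_group), error = function(e) NULL))
}

# keep the highest-occupancy altloc per (chain, resno, resid, elety); tie -> first
resolve_altloc <- function(at) {
  if (all(is.na(at$alt))) return(at)
  key <- paste(at$chain, at$resno, at$resid, at$elety, sep = "|")
  keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx) {
    if (length(idx) == 1) return(idx)
    occ <- at$o[idx]; occ[is.na(occ)] <- 1
    idx[which.max(occ)]
  }), use.names = FALSE)
  at[sort(keep), ]
}

read_cryst1 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cl)) return(list(cell = NULL, space_group = NULL))
  l <- cl[1]
  cell <- as.numeric(c(substr(l, 7, 15), substr(l, 16, 24), substr(l, 25, 33),
                       substr(l, 34, 40), substr(l, 41, 47), substr(l, 48, 54)))
  sg <- trimws(substr(l, 56, 66))
  # a 1 Å P1 placeholder cell means "no cell"
  if (all(abs(cell[1:3] - 1) < 1e-6)) return(list(cell = NULL, space_group = NULL))
  list(cell = cell, space_group = if (nzchar(sg)) sg else NULL)
}

read_structure_cif <- function(path) {
  p <- tryCatch(
    suppressWarnings(bio3d::read.cif(path, verbose = FALSE)),
    error = function(e) abort(paste0("cannot parse mmCIF file ", path, ": ",
                                     conditionMessage(e))))
  at <- as_tibble(p$atom)
  at <- resolve_altloc(at)
  atoms <- tibble(
    record = at$type, eleno = at$eleno, elety = at$elety, resid = at$resid,
    chain = ifelse(is.na(at$chain), "A", at$chain), resno = at$resno,
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o), b = ifelse(is.na(at$b), 0, at$b),
    elesy = ifelse(is.na(at$elesy) | at$elesy == "", guess_element(at$elety), at$elesy))
  meta <- read_cif_cell(path)
  ops <- meta$ops
  if (is.null(ops) && !is.null(meta$space_group)) {
    ops <- tryCatch(spacegroup_ops(meta$space_group), error = function(e) NULL)
  }
  as_structure(atoms, cell = meta$cell, space_group = meta$space_group, sym_ops = ops)
}

read_cif_cell <- function(path) {
  lines <- readLines(path, warn = FALSE)
  grab <- function(tag) {
    l <- grep(paste0("^", tag, "\\s"), lines, value = TRUE)
    if (!length(l)) return(NA)
    val <- trimws(sub(paste0("^", tag, "\\s+"), "", l[1]))
    gsub("^['\"]|['\"]$", "", val)
  }
  cellv <- suppressWarnings(as.numeric(c(
    grab("_cell.length_a"), grab("_cell.length_b"), grab("_cell.length_c"),
    grab("_cell.angle_alpha"), grab("_cell.angle_beta"), grab("_cell.angle_gamma"))))
  sg <- grab("_symmetry.space_group_name_H-M")
  if (is.na(sg)) sg <- grab("_space_group.name_H-M_alt")
  ops <- read_cif_symops(lines)
  list(cell = if (all(is.finite(cellv))) cellv else NULL,
       space_group = if (!is.na(sg)) sg else NULL,
       ops = ops)
}

# pull operator strings out of a symmetry_equiv / space_group_symop loop
read_cif_symops <- function(lines) {
  idx <- grep("_symmetry_equiv\\.pos_as_xyz|_space_group_symop\\.operation_xyz", lines)
  if (!length(idx)) return(NULL)
  ops <- character(0)
  for (i in seq(idx[1] + 1, length(lines))) {
    l <- trimws(lines[i])
    if (!nzchar(l) || startsWith(l, "_") || startsWith(l, "loop_") ||
        startsWith(l, "#")) break
    l <- gsub("^\\d+\\s+", "", l)           # optional leading id
    l <- gsub("^['\"]|['\"]$", "", l)
    ops <- c(ops, l)
  }
  if (!length(ops)) return(NULL)
  lapply(ops, parse_symop)
}

# ---------------------------------------------------------------------------

#' Write a structure as PDB
#'
#' Emits standards-conformant fixed-width ATOM/HETATM records (coordinates to
#' 3 decimals) preceded by a CRYST1 record when the structure carries a unit
#' cell. Chain, residue identity (including nonstandard codes such as "AIB")
#' and author numbering are preserved.
#'
#' @param structure an `mm_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  if (nrow(structure) == 0) abort("refusing to write an empty structure")
  if (nrow(structure) > 99999) abort("PDB format supports at most 99999 atoms")
  lines <- character(0)
  cell <- unit_cell(structure)
  if (!is.null(cell)) {
    sg <- space_group(structure) %||% "P 1"
    lines <- c(lines, sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
      cell[1], cell[2], cell[3], cell[4], cell[5], cell[6], sg,
      length(sym_ops(structure) %||% list(1))))
  }
  s <- structure
  name4 <- vapply(seq_len(nrow(s)), function(i) pdb_atom_name(s$elety[i], s$elesy[i]),
                  character(1))
  recs <- sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                  s$record, (seq_len(nrow(s)) - 1) %% 99999 + 1, name4, "",
                  substr(s$resid, 1, 3), substr(s$chain, 1, 1), s$resno, "",
                  s$x, s$y, s$z, s$o, s$b, s$elesy)
  lines <- c(lines, recs, "END")
  writeLines(lines, path)
  invisible(path)
}

# PDB columns 13-16: element right-justified in 13-14 for 1-letter elements.
pdb_atom_name <- function(elety, elesy) {
  if (nchar(elesy) == 2 || nchar(elety) == 4) {
    sprintf("%-4s", substr(elety, 1, 4))
  } else {
    sprintf(" %-3s", elety)
  }
}

# ---------------------------------------------------------------------------

#' Crystallographic symmetry expansion
#'
#' Applies every symmetry operator of the structure's space group, with lattice
#' translations of -1..+1 cell along each axis, and returns the symmetry mates
#' (excluding the trivial identity copy) that have at least one atom within
#' `radius` of the input molecule. Each mate is a rigid copy: intra-mate
#' distances equal those of the input to numerical precision.
#'
#' @param structure an `mm_structure` with unit cell and symmetry operators.
#' @param radius contact search radius, Å.
#' @return list of `mm_structure` mates; each carries attributes `operator`
#'   (the "x,y,z" index applied) and `shift` (the lattice translation).
#' @export
expand_symmetry <- function(structure, radius = 5) {
  cell <- unit_cell(structure)
  ops <- sym_ops(structure)
  if (is.null(cell) || is.null(ops)) {
    abort("expand_symmetry needs a unit cell and symmetry operators")
  }
  M <- orth_matrix(cell)
  Minv <- solve(M)
  xyz <- coords(structure)
  frac <- xyz %*% t(Minv)
  shifts <- as.matrix(expand.grid(sx = -1:1, sy = -1:1, sz = -1:1))
  mates <- list()
  for (k in seq_along(ops)) {
    op <- ops[[k]]
    f2 <- frac %*% t(op$R)
    f2 <- sweep(f2, 2, op$t, "+")
    for (si in seq_len(nrow(shifts))) {
      sh <- as.numeric(shifts[si, ])
      if (k == 1 && all(sh == 0)) next  # identity copy of itself
      f3 <- sweep(f2, 2, sh, "+")
      x3 <- f3 %*% t(M)
      dmin <- min_cross_distance(xyz, x3)
      if (dmin <= radius) {
        mate <- with_coords(structure, x3)
        attr(mate, "operator") <- k
        attr(mate, "shift") <- sh
        attr(mate, "min_distance") <- dmin
        mates[[length(mates) + 1]] <- mate
      }
    }
  }
  mates
}

min_cross_distance <- function(a, b) {
  # min over pairs without forming a huge matrix when unnecessary
  best <- Inf
  blocks <- split(seq_len(nrow(b)), ceiling(seq_len(nrow(b)) / 512))
  for (idx in blocks) {
    d2 <- outer(rowSums(a^2), rowSums(b[idx, , drop = FALSE]^2), "+") -
      2 * a %*% t(b[idx, , drop = FALSE])
    best <- min(best, min(d2))
    if (best <= 0) return(0)
  }
  sqrt(max(best, 0))
}
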
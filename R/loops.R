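# Loop-closure fragment search: find library segments whose two terminal
# residues superpose onto the open termini of the C2 dimer, then graft the
# best hit to produce a single chain. Gap length counts the intervening
# residues only; the matched window spans gap + 2 residues.

#' Read a fragment-library index
#'
#' A library is a directory of PDB files plus a whitespace/tab-separated index
#' with columns `id`, `chain`, `path` (paths relative to the index file).
#'
#' @param index_path path to the index file.
#' @return tibble (id, chain, path) of class `mm_fragment_library`.
#' @export
read_fragment_library <- function(index_path) {
  if (!file.exists(index_path)) abort(paste0("index not found: ", index_path))
  idx <- read.table(index_path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("id", "chain", "path") %in% names(idx))) {
    abort("library index needs columns: id, chain, path")
  }
  idx$path <- file.path(dirname(index_path), idx$path)
  out <- as_tibble(idx)
  class(out) <- c("mm_fragment_library", class(out))
  out
}

#' Anchor stubs of an open dimer
#'
#' The loop search closes the gap between the C-terminus of the second chain
#' (which will precede the loop in the final single chain) and the N-terminus
#' of the first chain (which will follow it). `c_side` is the backbone
#' (N, CA, C, O) of the last residue of chain 2; `n_side` that of the first
#' residue of chain 1.
#'
#' @param dimer a two-chain `mm_structure` (e.g. from [make_c2_dimer()]).
#' @return object of class `mm_stub_pair`: list of two 4-atom tibbles.
#' @export
extract_stubs <- function(dimer) {
  chains <- unique(dimer$chain[dimer$record == "ATOM"])
  if (length(chains) < 2) abort("extract_stubs needs a two-chain structure")
  bb <- c("N", "CA", "C", "O")
  grab <- function(ch, which_end) {
    sc <- dimer[dimer$chain == ch & dimer$record == "ATOM", ]
    rn <- if (which_end == "last") max(sc$resno) else min(sc$resno)
    r <- sc[sc$resno == rn & sc$elety %in% bb, ]
    r <- r[match(bb, r$elety), ]
    if (any(is.na(r$x))) {
      abort(paste0("incomplete anchor backbone at ", ch, " ", rn))
    }
    r
  }
  out <- list(c_side = grab(chains[2], "last"), n_side = grab(chains[1], "first"))
  class(out) <- "mm_stub_pair"
  out
}

stub_matrix <- function(stubs) rbind(coords(stubs$c_side), coords(stubs$n_side))

#' Systematic loop-closure fragment search
#'
#' For every library chain and every gap length `L` in `1..max_gap`, each
#' contiguous window of `L + 2` residues is rigidly fitted by its two terminal
#' residues' N/CA/C/O (8 atoms, one joint fit) onto the stub pair; windows
#' with post-fit RMSD at or below `rmsd_cutoff` are hits. Gap-4 hits are typed
#' with the beta-turn classifier. Windows straddling backbone breaks are
#' skipped (and counted).
#'
#' @param library an [read_fragment_library()] tibble.
#' @param stubs an [extract_stubs()] pair.
#' @param max_gap maximum number of intervening residues (default 7).
#' @param rmsd_cutoff anchor backbone RMSD cutoff, Å (default 1.0).
#' @return tibble of hits sorted by `anchor_rmsd`: source, chain, start_seq,
#'   gap_length, anchor_rmsd, turn_type, sequence, transform (list-column);
#'   attributes `histogram` (per-gap-length counts; see [hit_histogram()]) and
#'   `n_skipped` (windows skipped at breaks).
#' @export
search_fragments <- function(library, stubs, max_gap = 7, rmsd_cutoff = 1.0) {
  if (rmsd_cutoff < 0) abort("rmsd_cutoff must be >= 0")
  target <- stub_matrix(stubs)
  hits <- list()
  n_skipped <- 0L
  if (nrow(library) == 0) {
    return(finish_hits(hits, max_gap, n_skipped))
  }
  for (li in seq_len(nrow(library))) {
    s <- read_structure(library$path[li])
    sc <- s[s$chain == library$chain[li] & s$record == "ATOM", ]
    if (!nrow(sc)) next
    resnos <- sort(unique(sc$resno))
    bb <- c("N", "CA", "C", "O")
    # per-residue backbone coordinate lookup
    bbc <- lapply(resnos, function(rn) {
      r <- sc[sc$resno == rn & sc$elety %in% bb, ]
      r <- r[match(bb, r$elety), ]
      if (any(is.na(r$x))) return(NULL)
      coords(r)
    })
    names(bbc) <- as.character(resnos)
    seqmap <- sc$resid[match(resnos, sc$resno)]
    for (L in 1:max_gap) {
      w <- L + 2
      for (k in seq_len(max(0, length(resnos) - w + 1))) {
        win <- resnos[k:(k + w - 1)]
        if (any(diff(win) != 1)) { n_skipped <- n_skipped + 1L; next }
        first <- bbc[[as.character(win[1])]]
        last <- bbc[[as.character(win[w])]]
        if (is.null(first) || is.null(last)) { n_skipped <- n_skipped + 1L; next }
        # peptide continuity inside the window
        cn <- vapply(seq_len(w - 1), function(j) {
          vdist(bbc[[as.character(win[j])]][3, ], bbc[[as.character(win[j + 1])]][1, ])
        }, numeric(1))
        if (any(!is.finite(cn)) || any(cn > 1.8)) { n_skipped <- n_skipped + 1L; next }
        fit <- superpose(rbind(first, last), target)
        if (fit$rmsd <= rmsd_cutoff) {
          loop_res <- win[2:(w - 1)]
          hits[[length(hits) + 1]] <- tibble(
            source = library$id[li], chain = library$chain[li],
            start_seq = win[1], gap_length = L, anchor_rmsd = fit$rmsd,
            turn_type = NA_character_,
            sequence = paste(seqmap[match(loop_res, resnos)], collapse = "-"),
            transform = list(fit))
        }
      }
    }
    # classify gap-4 hits from this structure while it is loaded
    if (length(hits)) {
      for (hi in seq_along(hits)) {
        h <- hits[[hi]]
        if (h$source == library$id[li] && h$gap_length == 4 &&
            is.na(h$turn_type)) {
          tt <- tryCatch(
            classify_beta_turn(sc, h$start_seq + 1, chain = library$chain[li])$kind,
            error = function(e) "IV")
          hits[[hi]]$turn_type <- tt
        }
      }
    }
  }
  finish_hits(hits, max_gap, n_skipped)
}

finish_hits <- function(hits, max_gap, n_skipped) {
  out <- if (length(hits)) arrange(bind_rows(hits), .data$anchor_rmsd) else
    tibble(source = character(), chain = character(), start_seq = integer(),
           gap_length = integer(), anchor_rmsd = numeric(),
           turn_type = character(), sequence = character(), transform = list())
  histo <- tibble(gap_length = seq_len(max_gap),
                  n_hits = vapply(seq_len(max_gap),
                                  function(L) sum(out$gap_length == L), integer(1)))
  attr(out, "histogram") <- histo
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("mm_loop_hits", class(tibble()))
  out
}

#' @rdname search_fragments
#' @param hits a hit table from `search_fragments()`.
#' @export
hit_histogram <- function(hits) attr(hits, "histogram")

#' Graft a loop hit onto the dimer
#'
#' Builds the single-chain model: the residues of chain 2, then the hit's
#' intervening residues (transformed by the hit's anchor fit), then the
#' residues of chain 1, renumbered from 1. Anchor residues keep the scaffold
#' coordinates. Peptide-bond C-N distances at the two junctions are checked:
#' outside [1.2, 1.45] Å a geometry warning is attached; above 2.0 Å the hit
#' is ungraftable and an error is raised.
#'
#' @param dimer the two-chain scaffold.
#' @param hit one row of a [search_fragments()] result.
#' @param library the fragment library the hit came from.
#' @param trim_terminal residues to drop from each outer terminus of the
#'   grafted chain (default 0).
#' @param keep_metal keep HETATM metal atoms from the dimer (default TRUE).
#' @return single-chain `mm_structure`, renumbered 1..N; attribute
#'   `junction_cn` holds the two C-N distances, `geometry_warning` is TRUE
#'   when a junction is outside the peptide-bond band.
#' @export
graft <- function(dimer, hit, library, trim_terminal = 0, keep_metal = TRUE) {
  if (nrow(hit) != 1 || is.na(hit$source)) abort("graft takes exactly one hit row")
  lib_row <- library[library$id == hit$source & library$chain == hit$chain, ]
  if (!nrow(lib_row)) abort("hit does not reference a library entry")
  s <- read_structure(lib_row$path[1])
  sc <- s[s$chain == hit$chain & s$record == "ATOM", ]
  w <- hit$gap_length + 2
  win <- hit$start_seq + seq_len(w) - 1
  loop <- sc[sc$resno %in% win[2:(w - 1)], ]
  fit <- hit$transform[[1]]
  loop <- apply_transform(loop, fit$rotation, fit$translation)

  chains <- unique(dimer$chain[dimer$record == "ATOM"])
  ch2 <- dimer[dimer$chain == chains[2] & dimer$record == "ATOM", ]
  ch1 <- dimer[dimer$chain == chains[1] & dimer$record == "ATOM", ]
  ch2 <- ch2[order(ch2$resno), ]; ch1 <- ch1[order(ch1$resno), ]
  loop <- loop[order(loop$resno), ]

  renumber <- function(d, offset) {
    old <- sort(unique(d$resno))
    d$resno <- offset + match(d$resno, old)
    d
  }
  n2 <- length(unique(ch2$resno)); nl <- length(unique(loop$resno))
  out <- bind_rows(renumber(ch2, 0L), renumber(loop, n2),
                   renumber(ch1, n2 + nl))
  out$chain <- "A"
  # junction peptide bonds
  atof <- function(d, rn, nm) {
    as.numeric(d[which(d$resno == rn & d$elety == nm)[1], c("x", "y", "z")])
  }
  j1 <- vdist(atof(out, n2, "C"), atof(out, n2 + 1, "N"))
  j2 <- vdist(atof(out, n2 + nl, "C"), atof(out, n2 + nl + 1, "N"))
  if (max(j1, j2) > 2.0) {
    abort(sprintf("ungraftable hit: junction C-N distance %.2f Å exceeds 2.0 Å",
                  max(j1, j2)))
  }
  warn_geom <- any(c(j1, j2) < 1.2 | c(j1, j2) > 1.45)
  if (trim_terminal > 0) {
    keep <- setdiff(sort(unique(out$resno)),
                    c(seq_len(trim_terminal),
                      max(out$resno) - seq_len(trim_terminal) + 1))
    out <- out[out$resno %in% keep, ]
    out$resno <- match(out$resno, keep)
  }
  if (keep_metal) {
    het <- dimer[dimer$record == "HETATM", ]
    if (nrow(het)) {
      het$resno <- max(out$resno) + seq_len(nrow(het))
      out <- bind_rows(out, het)
    }
  }
  out <- as_structure(out)
  attr(out, "junction_cn") <- c(j1, j2)
  attr(out, "geometry_warning") <- warn_geom
  if (warn_geom) {
    warn(sprintf("graft junction C-N distances %.2f / %.2f Å outside [1.2, 1.45]",
                 j1, j2))
  }
  out
}

#' Turn-type census of four-residue loop hits
#'
#' Counts the beta-turn types among gap-4 hits and the frequency of Gly at the
#' two central turn positions (i+1, i+2).
#'
#' @param hits a [search_fragments()] result.
#' @return list with `counts` (tibble: turn_type, n) and `gly_fraction`
#'   (named vector for i+1 and i+2).
#' @export
tabulate_turns <- function(hits) {
  h4 <- hits[hits$gap_length == 4 & !is.na(hits$turn_type), ]
  if (!nrow(h4)) {
    return(list(counts = tibble(turn_type = character(), n = integer()),
                gly_fraction = c(`i+1` = NA_real_, `i+2` = NA_real_)))
  }
  counts <- count(as_tibble(h4), .data$turn_type, name = "n")
  seqs <- strsplit(h4$sequence, "-")
  g1 <- mean(vapply(seqs, function(x) x[2] == "GLY", logical(1)))
  g2 <- mean(vapply(seqs, function(x) x[3] == "GLY", logical(1)))
  list(counts = counts, gly_fraction = c(`i+1` = g1, `i+2` = g2))
}
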
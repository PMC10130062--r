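test_that("extract_stubs returns the terminal anchor residues", {
  sc <- make_closure_scaffold(gap_length = 4, seed = 2)
  stubs <- extract_stubs(sc$dimer)
  chains <- unique(sc$dimer$chain)
  b <- sc$dimer[sc$dimer$chain == chains[2], ]
  expect_equal(unique(stubs$c_side$resno), max(b$resno))
  expect_equal(sort(stubs$c_side$elety), sort(c("N", "CA", "C", "O")))
  single <- as_structure(sc$dimer[sc$dimer$chain == chains[1], ])
  expect_error(extract_stubs(single), "two-chain")
})

test_that("a planted loop is recovered with near-zero anchor RMSD", {
  sc <- make_closure_scaffold(gap_length = 4, turn_type = "I'", seed = 3)
  lib <- make_mini_library(8, list(list(gap_length = 4, turn_type = "I'")),
                           seed = 3)
  hits <- search_fragments(lib$library, extract_stubs(sc$dimer))
  expect_gt(nrow(hits), 0)
  best <- hits[1, ]
  expect_equal(best$gap_length, 4)
  expect_lt(best$anchor_rmsd, 0.01)
  expect_equal(best$turn_type, "I'")
  expect_equal(best$source, lib$plants$id[1])
  histo <- hit_histogram(hits)
  expect_equal(nrow(histo), 7)
  expect_gte(histo$n_hits[histo$gap_length == 4], 1)
})

test_that("empty libraries and zero cutoff behave as limiting cases", {
  sc <- make_closure_scaffold(gap_length = 4, seed = 2)
  stubs <- extract_stubs(sc$dimer)
  empty <- make_mini_library(0, list(), seed = 1)
  hits0 <- search_fragments(empty$library, stubs)
  expect_equal(nrow(hits0), 0)
  expect_equal(sum(hit_histogram(hits0)$n_hits), 0)
  # decoys only at a tight cutoff: nothing survives
  dec <- make_mini_library(10, list(), seed = 4)
  expect_equal(nrow(search_fragments(dec$library, stubs, rmsd_cutoff = 0.1)), 0)
})

test_that("hit counts are monotone in the RMSD cutoff", {
  sc <- make_closure_scaffold(gap_length = 4, seed = 5)
  lib <- make_mini_library(6, list(list(gap_length = 4, turn_type = "I'")),
                           seed = 5)
  stubs <- extract_stubs(sc$dimer)
  n <- vapply(c(0.2, 0.6, 1.0, 1.5), function(ct)
    nrow(search_fragments(lib$library, stubs, rmsd_cutoff = ct)), integer(1))
  expect_true(all(diff(n) >= 0))
})

test_that("the search is invariant under rigid motion of the scaffold", {
  sc <- make_closure_scaffold(gap_length = 3, seed = 6)
  lib <- make_mini_library(4, list(list(gap_length = 3, turn_type = "I'")),
                           seed = 6)
  h1 <- search_fragments(lib$library, extract_stubs(sc$dimer))
  rr <- random_rigid(8)
  moved <- apply_transform(sc$dimer, rr$R, rr$t)
  h2 <- search_fragments(lib$library, extract_stubs(as_structure(moved)))
  expect_equal(nrow(h1), nrow(h2))
  expect_lt(max(abs(h1$anchor_rmsd - h2$anchor_rmsd)), 1e-6)
})

test_that("planted loops survive coordinate noise up to 3 sigma", {
  sc <- make_closure_scaffold(gap_length = 4, seed = 9)
  lib <- make_mini_library(1, list(list(gap_length = 4, turn_type = "I'")),
                           seed = 9)
  stubs <- extract_stubs(sc$dimer)
  for (sigma in c(0.05, 0.2)) {
    worst <- 0
    for (seed in 1:15) {
      set.seed(seed * 100 + sigma * 1000)
      noisy <- sc$dimer
      noisy <- with_coords(noisy, coords(noisy) +
                             matrix(rnorm(nrow(noisy) * 3, sd = sigma), ncol = 3))
      h <- search_fragments(lib$library, extract_stubs(as_structure(noisy)),
                            rmsd_cutoff = 1.0)
      h4 <- h[h$gap_length == 4 & h$source == lib$plants$id[1] &
                h$start_seq == lib$plants$start_seq[1], ]
      expect_gt(nrow(h4), 0)
      worst <- max(worst, min(h4$anchor_rmsd))
    }
    expect_lt(worst, 3 * sigma)
  }
})

test_that("graft produces a renumbered single chain with sound junctions", {
  sc <- make_closure_scaffold(gap_length = 4, seed = 3, arm_length = 13)
  lib <- make_mini_library(3, list(list(gap_length = 4, turn_type = "I'")),
                           seed = 3)
  hits <- search_fragments(lib$library, extract_stubs(sc$dimer))
  best <- hits[hits$anchor_rmsd < 0.01, ][1, ]
  model <- graft(sc$dimer, best, lib$library)
  nres <- length(unique(model$resno[model$record == "ATOM"]))
  expect_equal(nres, 14 + 4 + 14)   # 13+1 arm residues per side + loop
  expect_equal(sort(unique(model$resno[model$record == "ATOM"])), 1:nres)
  expect_true(all(abs(attr(model, "junction_cn") - 1.33) < 0.02))
  expect_false(attr(model, "geometry_warning"))
  # trimming the outer termini gives the designed 28-mer arithmetic
  trimmed <- graft(sc$dimer, best, lib$library, trim_terminal = 2)
  expect_equal(length(unique(trimmed$resno[trimmed$record == "ATOM"])), 28)
})

test_that("a displaced hit is ungraftable", {
  sc <- make_closure_scaffold(gap_length = 4, seed = 3)
  lib <- make_mini_library(3, list(list(gap_length = 4, turn_type = "I'")),
                           seed = 3)
  hits <- search_fragments(lib$library, extract_stubs(sc$dimer))
  bad <- hits[1, ]
  tr <- bad$transform[[1]]
  tr$translation <- tr$translation + c(5, 0, 0)
  bad$transform <- list(tr)
  expect_error(graft(sc$dimer, bad, lib$library), "ungraftable")
})

test_that("turn tabulation counts planted types and Gly enrichment", {
  plants <- c(rep("I'", 5), rep("III'", 3))
  all_hits <- list()
  for (k in seq_along(plants)) {
    sck <- make_closure_scaffold(gap_length = 4, turn_type = plants[k],
                                 seed = 20 + k)
    libk <- make_mini_library(1, list(list(gap_length = 4,
                                           turn_type = plants[k])),
                              seed = 20 + k)
    h <- search_fragments(libk$library, extract_stubs(sck$dimer),
                          rmsd_cutoff = 0.3)
    all_hits[[k]] <- h[h$gap_length == 4, ]
  }
  hits <- dplyr::bind_rows(all_hits)
  class(hits) <- c("mm_loop_hits", class(tibble::tibble()))
  tab <- tabulate_turns(hits)
  expect_equal(tab$counts$n[tab$counts$turn_type == "I'"], 5)
  expect_equal(tab$counts$n[tab$counts$turn_type == "III'"], 3)
  expect_equal(unname(tab$gly_fraction["i+1"]), 1)
  expect_equal(unname(tab$gly_fraction["i+2"]), 1)
  empty <- tabulate_turns(hits[0, ])
  expect_equal(nrow(empty$counts), 0)
})
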
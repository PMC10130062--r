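# shared fixtures, built once per test run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

model28 <- function() cached("model28", synthetic_metpsc1())

ideal_site <- function() cached("ideal_site", make_ideal_site())

alpha_helix <- function(n = 10) {
  backbone_from_dihedrals(rep(-57, n), rep(-47, n))
}

# random rigid motion with seeded RNG
random_rigid <- function(seed) {
  set.seed(seed)
  list(R = rotation_about_axis(rnorm(3), runif(1, 5, 175)),
       t = rnorm(3, sd = 20))
}

expect_rigid_copy <- function(a, b, tol = 1e-6) {
  da <- as.matrix(dist(a)); db <- as.matrix(dist(b))
  expect_lt(max(abs(da - db)), tol)
}
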
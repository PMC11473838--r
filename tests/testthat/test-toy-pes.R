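# Analytic toy surfaces: exactness of derivatives, rigid-motion behaviour,
# and the structure of their stationary points.

test_that("geometry constructor enforces its invariants", {
  expect_error(geometry(c("H", "H"), rbind(c(0, 0, 0))), "does not match")
  expect_error(geometry("H", c(0, 0, Inf)), "finite")
  expect_error(geometry("H", c(0, 0, 0), masses = -1), "positive")
  expect_error(geometry("Zz", c(0, 0, 0)), "no tabulated mass")
  g <- geometry(c("O", "H"), rbind(c(0, 0, 0), c(0.96, 0, 0)))
  expect_equal(g$masses, c(15.999, 1.008))
  expect_equal(coords_vector(g), c(0, 0, 0, 0.96, 0, 0))
})

test_that("analytic gradients match central finite differences of the energy", {
  for (nm in all_surfaces) {
    pot <- toy_potential(nm)
    for (s in 1:12) {
      g <- random_geometry(nm, seed = 100 + s)
      ev <- pes_eval(pot, g)
      gfd <- fd_gradient(pot, g)
      expect_lt(max(abs(gfd - ev$gradient)) /
                  max(1, max(abs(ev$gradient))), 1e-6)
    }
  }
})

test_that("analytic Hessians match finite differences of the gradient and are symmetric", {
  for (nm in all_surfaces) {
    pot <- toy_potential(nm)
    for (s in 1:12) {
      g <- random_geometry(nm, seed = 200 + s)
      ev <- pes_eval(pot, g, hessian = TRUE)
      expect_equal(ev$hessian, t(ev$hessian))
      Hfd <- fd_hessian_of(pot, g)
      expect_lt(max(abs(Hfd - ev$hessian)) / max(1, max(abs(ev$hessian))),
                1e-5)
    }
  }
})

test_that("molecular toys are invariant to rigid translation with >=3 near-zero Hessian modes", {
  for (nm in c("morse_exchange_abc", "torsion_tetramer")) {
    pot <- toy_potential(nm)
    g <- random_geometry(nm, seed = 7)
    e0 <- pes_eval(pot, g)$energy
    shift <- rep(c(1.7, -0.4, 2.2), n_atoms(g))
    e1 <- pes_eval(pot, set_coords(g, coords_vector(g) + shift))$energy
    expect_lt(abs(e1 - e0), 1e-10)
    H <- pes_eval(pot, g, hessian = TRUE)$hessian
    vals <- sort(abs(eigen(H, symmetric = TRUE)$values))
    expect_gte(sum(vals <= 1e-6), 3)
  }
})

test_that("dimension and name errors are explicit", {
  pot <- toy_potential("morse_exchange_abc")
  expect_error(pes_eval(pot, reference_geometry(
    toy_potential("torsion_tetramer"))), "dimension error")
  expect_error(toy_potential("no_such_surface"), "unknown potential")
  expect_error(toy_potential("mueller_brown_2d", list(bogus = 1)),
               "unknown parameter")
})

test_that("the 2D surface has 3 minima and 2 saddles, all verified stationary", {
  pot <- toy_potential("mueller_brown_2d")
  mins <- oracle_minima("mueller_brown_2d")
  sads <- oracle_saddles("mueller_brown_2d")
  expect_length(mins, 3)
  expect_length(sads, 2)
  for (m in mins) {
    ev <- pes_eval(pot, m, hessian = TRUE)
    expect_lte(max(abs(ev$gradient)), 1e-8)
    expect_true(all(eigen(ev$hessian, symmetric = TRUE)$values > 0))
  }
  for (s in sads) {
    ev <- pes_eval(pot, s, hessian = TRUE)
    expect_lte(max(abs(ev$gradient)), 1e-8)
    expect_equal(sum(eigen(ev$hessian, symmetric = TRUE)$values < 0), 1)
  }
})

test_that("the exchange surface has an index-1 bond-exchange saddle and two wells with different graphs", {
  sads <- oracle_saddles("morse_exchange_abc")
  expect_gte(length(sads), 1)
  ex <- exchange_saddle()
  r <- as.matrix(dist(ex$coords))
  expect_lt(abs(r[1, 2] - r[2, 3]), 1e-6)   # symmetric partial bonds
  expect_equal(sum(attr(ex, "eigenvalues") < -1e-6), 1)
  mins <- oracle_minima("morse_exchange_abc")
  expect_gte(length(mins), 2)
  g1 <- build_graph(mins[[1]]); g2 <- build_graph(mins[[2]])
  expect_false(graphs_isomorphic(g1, g2))
})

test_that("separated diatomic limit: energy approaches the isolated-pair value, far atom feels no force", {
  pot <- toy_potential("morse_exchange_abc")
  p <- potential_params(pot)
  g <- geometry(c("F", "H", "O"),
                rbind(c(0, 0, 0), c(p$r0, 0, 0), c(60, 0, 0)))
  ev <- pes_eval(pot, g)
  expect_lt(abs(ev$energy - (-p$D)), 1e-8)     # isolated F-H Morse minimum
  expect_lt(max(abs(ev$gradient[7:9])), 1e-8)  # no force on distant O
})

test_that("the tetramer torsional barrier top has exactly one negative mode after projection", {
  pot <- toy_potential("torsion_tetramer")
  sad <- oracle_saddles("torsion_tetramer")[[1]]
  H <- pes_eval(pot, sad, hessian = TRUE)$hessian
  Hp <- mass_weight_and_project(hessian_matrix(H), sad,
                                mass_weight = FALSE, remove_tr = TRUE)
  md <- normal_modes(Hp)
  expect_equal(md$n_negative, 1L)
})

test_that("oracle results are reproducible under a fixed seed", {
  # clear the session cache so the second search recomputes from scratch
  first <- find_stationary_oracle(toy_potential("torsion_tetramer"),
                                  "saddle", seed = 3L)
  rm(list = ls(envir = hesstate:::.oracle_cache),
     envir = hesstate:::.oracle_cache)
  second <- find_stationary_oracle(toy_potential("torsion_tetramer"),
                                   "saddle", seed = 3L)
  expect_identical(lapply(first, coords_vector),
                   lapply(second, coords_vector))
})

test_that("an empty region yields an empty result with a warning", {
  pot <- toy_potential("mueller_brown_2d")
  expect_warning(
    out <- find_stationary_oracle(pot, "saddle",
                                  region = list(lower = c(5, 5),
                                                upper = c(6, 6))),
    "no stationary point")
  expect_length(out, 0)
})
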
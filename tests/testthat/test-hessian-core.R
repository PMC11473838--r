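# Hessian construction, mass weighting, projection, normal modes and the
# eigenpair-assignment comparison metrics.

test_that("finite differences recover a quadratic Hessian exactly", {
  k <- 3.7
  g <- geometry("X", c(0.2, -0.1, 0.4), masses = 1)
  H <- finite_difference_hessian(function(gm) k * coords_vector(gm), g)
  expect_lt(max(abs(H$matrix - k * diag(3))), 1e-8 * k)
  expect_equal(H$gradient_calls, 6L)
})

test_that("finite-difference Hessians match the analytic ones with second-order convergence", {
  pot <- toy_potential("mueller_brown_2d")
  g <- random_geometry("mueller_brown_2d", seed = 3)
  Ha <- pes_eval(pot, g, hessian = TRUE)$hessian
  err <- function(h) {
    Hf <- finite_difference_hessian(
      function(gm) pes_eval(pot, gm)$gradient, g, step = h)$matrix
    max(abs(Hf - Ha))
  }
  e1 <- err(1e-3)       # larger steps so truncation dominates roundoff
  e2 <- err(5e-4)
  expect_lt(e1 / max(abs(Ha)), 1e-5)
  expect_gt(e1 / e2, 2.5)     # halving the step shrinks the error ~4x
  expect_lt(e1 / e2, 6)
})

test_that("finite differences refuse non-finite gradients", {
  g <- geometry("X", c(0, 0, 0), masses = 1)
  expect_error(finite_difference_hessian(function(gm) rep(NaN, 3), g),
               "non-finite")
})

test_that("mass weighting gives the reduced-mass stretching eigenvalue for a diatomic", {
  k <- 5.0; m <- 2.5
  g <- geometry(c("X", "X"), rbind(c(0, 0, 0), c(1, 0, 0)),
                masses = c(m, m))
  u <- c(1, 0, 0)
  blk <- k * tcrossprod(u)
  H <- rbind(cbind(blk, -blk), cbind(-blk, blk))   # harmonic bond Hessian
  Hw <- mass_weight_and_project(hessian_matrix(H), g)
  vals <- normal_modes(Hw)$eigenvalues
  expect_equal(max(vals), 2 * k / m, tolerance = 1e-10)
  # all-unit masses leave the matrix unchanged
  g1 <- geometry(c("X", "X"), g$coords, masses = c(1, 1))
  Hw1 <- mass_weight_and_project(hessian_matrix(H), g1, remove_tr = FALSE)
  expect_equal(Hw1$matrix, H)
})

test_that("projection zeroes exactly the rigid modes at oracle minima", {
  for (nm in c("morse_exchange_abc", "torsion_tetramer")) {
    g <- oracle_minima(nm)[[1]]
    H <- pes_eval(toy_potential(nm), g, hessian = TRUE)$hessian
    Hp <- mass_weight_and_project(hessian_matrix(H), g,
                                  mass_weight = FALSE)
    vals <- normal_modes(Hp)$eigenvalues
    n <- 3 * n_atoms(g)
    # linear molecules keep 3N-5 vibrations, bent ones 3N-6
    n_rigid <- n - sum(vals > 1e-6)
    expect_true(n_rigid %in% c(5L, 6L))
    expect_lte(max(abs(sort(abs(vals))[seq_len(n_rigid)])), 1e-8)
  }
})

test_that("normal modes order, count and sign-fix deterministically", {
  md <- normal_modes(hessian_matrix(diag(c(2, -1, 3))))
  expect_equal(md$eigenvalues, c(-1, 2, 3))
  expect_equal(md$n_negative, 1L)
  expect_equal(abs(md$eigenvectors[, 1]), c(0, 1, 0))
  expect_gt(md$eigenvectors[which.max(abs(md$eigenvectors[, 1])), 1], 0)
  expect_equal(as.numeric(md$frequencies), c(-1, sqrt(2), sqrt(3)))
  # eigen-residual property on a random symmetric matrix
  set.seed(11)
  A <- matrix(rnorm(64), 8); A <- A + t(A)
  md2 <- normal_modes(hessian_matrix(A))
  for (k in 1:8)
    expect_lt(max(abs(A %*% md2$eigenvectors[, k] -
                        md2$eigenvalues[k] * md2$eigenvectors[, k])),
              1e-8 * max(abs(A)))
})

test_that("oracle saddles have one negative mode, minima none (projected)", {
  sad <- exchange_saddle()
  H <- pes_eval(toy_potential("morse_exchange_abc"), sad,
                hessian = TRUE)$hessian
  md <- normal_modes(mass_weight_and_project(hessian_matrix(H), sad,
                                             mass_weight = FALSE))
  expect_equal(md$n_negative, 1L)
  mn <- oracle_minima("morse_exchange_abc")[[1]]
  Hm <- pes_eval(toy_potential("morse_exchange_abc"), mn,
                 hessian = TRUE)$hessian
  mdm <- normal_modes(mass_weight_and_project(hessian_matrix(Hm), mn,
                                              mass_weight = FALSE))
  expect_equal(mdm$n_negative, 0L)
})

test_that("the assignment solver matches brute-force enumeration", {
  perms <- function(n) {
    if (n == 1) return(matrix(1))
    do.call(rbind, lapply(seq_len(n), function(k) {
      p <- perms(n - 1)
      cbind(k, matrix(setdiff(seq_len(n), k)[p], nrow(p)))
    }))
  }
  set.seed(17)
  for (t in 1:20) {
    n <- sample(2:6, 1)
    C <- matrix(runif(n * n), n)
    a <- hesstate:::solve_assignment(C)
    expect_setequal(a, seq_len(n))
    pm <- perms(n)
    best <- min(apply(pm, 1, function(p) sum(C[cbind(seq_len(n), p)])))
    expect_equal(sum(C[cbind(seq_len(n), a)]), best, tolerance = 1e-12)
  }
})

test_that("identical Hessians compare to RMSE 0 and MCS 1", {
  set.seed(5)
  A <- matrix(rnorm(81), 9); A <- A + t(A)
  cmp <- compare_hessians(A, A)
  expect_equal(cmp$eigenvalue_rmse, 0, tolerance = 1e-10)
  expect_equal(cmp$mean_cosine_similarity, 1, tolerance = 1e-10)
  expect_equal(cmp$assignment, 1:9)
})

test_that("assignment recovers permuted and sign-flipped eigenvectors exactly", {
  set.seed(6)
  A <- matrix(rnorm(64), 8); A <- A + t(A)
  eg <- eigen(A, symmetric = TRUE)
  perm <- sample(8)
  signs <- sample(c(-1, 1), 8, replace = TRUE)
  B <- eg$vectors[, perm] %*% diag(signs) %*% diag(eg$values[perm]) %*%
    diag(signs) %*% t(eg$vectors[, perm])
  cmp <- compare_hessians(B, A)
  expect_equal(cmp$eigenvalue_rmse, 0, tolerance = 1e-8)
  expect_equal(cmp$mean_cosine_similarity, 1, tolerance = 1e-10)
  expect_equal(cmp$leftmost_cosine, 1, tolerance = 1e-10)
})

test_that("a uniformly scaled spectrum keeps MCS 1 with the closed-form eigenvalue RMSE", {
  set.seed(7)
  A <- matrix(rnorm(100), 10); A <- A + t(A)
  cmp <- compare_hessians(0.8 * A, A)
  expect_equal(cmp$mean_cosine_similarity, 1, tolerance = 1e-10)
  vals <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(cmp$eigenvalue_rmse, 0.2 * sqrt(mean(vals^2)),
               tolerance = 1e-8)
  expect_error(compare_hessians(A, diag(4)), "dimension mismatch")
})

test_that("hessian text files round-trip with metadata", {
  set.seed(8)
  A <- matrix(rnorm(36), 6); A <- A + t(A)
  H <- hessian_matrix(A, projected = TRUE)
  path <- tempfile(fileext = ".txt")
  write_hessian(H, path)
  H2 <- read_hessian(path)
  expect_equal(H2$matrix, H$matrix, tolerance = 1e-15)
  expect_equal(H2$frame, "cartesian")
  expect_true(H2$projected)
  expect_error(hessian_matrix(matrix(rnorm(16), 4)), "not symmetric")
})
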
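# RS-PRFO stepping, trust-radius control, TS-BFGS updates, Davidson
# leftmost eigenpairs and the saddle optimizer.

test_that("the partitioned RFO step solves both augmented eigenproblems", {
  md <- normal_modes(hessian_matrix(diag(c(-1, 2))))
  st <- prfo_step(c(0.1, 0.2), md, trust = 1e9)
  # higher root of [[-1, .1], [.1, 0]] and lowest of [[2, .2], [.2, 0]]
  lam_max <- (-1 + sqrt(1 + 4 * 0.01)) / 2
  lam_min <- (2 - sqrt(4 + 4 * 0.04)) / 2
  expect_equal(as.numeric(st),
               c(-0.1 / (-1 - lam_max), -0.2 / (2 - lam_min)),
               tolerance = 1e-10)
  expect_equal(as.numeric(st), c(0.09902, -0.09902), tolerance = 1e-4)
})

test_that("a zero gradient gives a zero step", {
  md <- normal_modes(hessian_matrix(diag(c(-2, 1, 3))))
  st <- prfo_step(c(0, 0, 0), md, trust = 0.1)
  expect_equal(as.numeric(st), c(0, 0, 0))
})

test_that("every restricted step honours the trust radius", {
  set.seed(23)
  for (t in 1:25) {
    n <- sample(2:8, 1)
    A <- matrix(rnorm(n * n), n); A <- A + t(A)
    md <- normal_modes(hessian_matrix(A))
    g <- rnorm(n, sd = 5)
    r <- runif(1, 0.01, 0.5)
    st <- prfo_step(g, md, trust = r)
    expect_lte(sqrt(sum(st^2)), r + 1e-10)
  }
})

test_that("iterated PRFO converges to the exact saddle of an index-1 quadratic", {
  set.seed(24)
  Q <- qr.Q(qr(matrix(rnorm(25), 5)))
  H <- Q %*% diag(c(-2.5, 0.8, 1.7, 3.1, 4.2)) %*% t(Q)
  x_star <- rnorm(5)
  grad <- function(x) as.numeric(H %*% (x - x_star))
  x <- x_star + rnorm(5, sd = 0.5)
  md <- normal_modes(hessian_matrix(H))
  for (it in 1:10) {
    x <- x + as.numeric(prfo_step(grad(x), md, trust = 1e6))
    if (max(abs(grad(x))) <= 1e-10) break
  }
  expect_lte(max(abs(grad(x))), 1e-10)
  expect_lt(max(abs(x - x_star)), 1e-9)
})

test_that("PRFO reduces to the Newton step in the small-gradient limit", {
  set.seed(25)
  Q <- qr.Q(qr(matrix(rnorm(36), 6)))
  A <- Q %*% diag(c(-2, 0.6, 1.1, 2.3, 3.4, 5.2)) %*% t(Q)  # index 1
  md <- normal_modes(hessian_matrix(A))
  g <- rnorm(6); g <- 1e-6 * g / sqrt(sum(g^2))
  st <- prfo_step(g, md, trust = 1e9)
  newton <- -solve(A, g)
  expect_lt(max(abs(st - newton)) / max(abs(newton)), 1e-4)
})

test_that("trust-radius control applies the printed factors at the printed thresholds", {
  expect_equal(update_trust_radius(trust_state(0.1), -1.00, -1.00)$radius,
               0.115)                       # ratio 1 < 1.035: grow by 1.15
  expect_equal(update_trust_radius(trust_state(0.1), -6.0, -1.0)$radius,
               0.065)                       # ratio 6 > 5: shrink by 0.65
  expect_equal(update_trust_radius(trust_state(0.1), -2.0, -1.0)$radius,
               0.1)                         # ratio 2: unchanged
  # sign mismatch is worst-case (shrink); double zero is perfect (grow)
  expect_equal(update_trust_radius(trust_state(0.1), 1, -1)$radius, 0.065)
  expect_equal(update_trust_radius(trust_state(0.1), 0, 0)$radius, 0.115)
  # clamping
  ts <- trust_state(0.29)
  expect_equal(update_trust_radius(ts, -1, -1)$radius, 0.3)
})

test_that("TS-BFGS satisfies the secant condition, stays symmetric and permits indefiniteness", {
  set.seed(26)
  for (t in 1:10) {
    A <- matrix(rnorm(36), 6); A <- A + t(A)
    s <- rnorm(6); y <- rnorm(6)
    Hn <- ts_bfgs_update(A, s, y)
    expect_lt(max(abs(Hn %*% s - y)), 1e-10 * max(1, max(abs(y))))
    expect_lt(max(abs(Hn - t(Hn))), 1e-12)
  }
  # an exact secant pair leaves the matrix unchanged
  A <- diag(c(-1, 2, 3))
  s <- c(1, 1, 1)
  expect_equal(ts_bfgs_update(A, s, as.numeric(A %*% s)), A)
  # updates are allowed to produce indefinite matrices
  H0 <- diag(3)
  Hn <- ts_bfgs_update(H0, c(1, 0, 0), c(-5, 0, 0))
  expect_lt(min(eigen(Hn, symmetric = TRUE)$values), 0)
  expect_warning(ts_bfgs_update(H0, rep(0, 3), c(1, 1, 1)), "skipped")
})

test_that("repeated TS-BFGS updates on a quadratic recover the true Hessian", {
  set.seed(27)
  Q <- qr.Q(qr(matrix(rnorm(36), 6)))
  Hstar <- Q %*% diag(c(-3, -0.5, 1, 2, 4, 6)) %*% t(Q)
  H <- diag(6)
  for (sweep in 1:10) for (k in 1:6) {
    s <- rnorm(6)
    H <- ts_bfgs_update(H, s, as.numeric(Hstar %*% s))
  }
  expect_lt(max(abs(H - Hstar)) / max(abs(Hstar)), 1e-4)
})

test_that("Davidson iteration finds the leftmost eigenpair from gradient calls", {
  H <- diag(c(-2, 1, 3))
  g <- geometry("X", c(0.3, -0.2, 0.5), masses = 1)
  grad_fn <- function(gm) as.numeric(H %*% coords_vector(gm))
  dv <- davidson_leftmost(grad_fn, g, initial_vector = c(1, 1, 1) / sqrt(3),
                          tol = 1e-3)
  expect_true(dv$converged)
  expect_equal(dv$eigenvalue, -2, tolerance = 1e-3)
  expect_gt(abs(dv$eigenvector[1]), 0.99)
  expect_equal(dv$gradient_calls %% 2, 0)
  # starting at the exact eigenvector converges immediately
  dv2 <- davidson_leftmost(grad_fn, g, initial_vector = c(1, 0, 0),
                           tol = 1e-3)
  expect_true(dv2$converged)
  expect_equal(dv2$gradient_calls, 2L)
})

test_that("Davidson agrees with the analytic leftmost eigenvalue at the exchange saddle", {
  pot <- toy_potential("morse_exchange_abc")
  sad <- exchange_saddle()
  dv <- davidson_leftmost(function(gm) pes_eval(pot, gm)$gradient, sad,
                          tol = 0.1, project = TRUE)
  lam_true <- attr(sad, "eigenvalues")[1]
  expect_lt(abs(dv$eigenvalue - lam_true), 0.1 * abs(lam_true))
})

test_that("the optimizer converges to the reference saddle from a displaced guess", {
  for (nm in all_surfaces) {
    pot <- toy_potential(nm)
    sad <- if (nm == "morse_exchange_abc") exchange_saddle() else
      oracle_saddles(nm)[[1]]
    lv <- attr(sad, "eigenvalues")
    # displace 0.05 along a seeded random direction
    guess <- perturb_guess(sad, 5, seed = 60)
    full <- optimize_saddle(pot, guess, "exact_every_step")
    expect_true(full$converged)
    expect_equal(full$n_negative, 1L)
    expect_lt(geom_dist(nm, full$final_geometry, sad), 1e-4)
    qn <- optimize_saddle(pot, guess, "qn")
    expect_true(qn$converged)
    expect_lt(geom_dist(nm, qn$final_geometry, sad), 1e-4)
    expect_gte(qn$counts$steps, full$counts$steps)
    expect_gt(qn$counts$gradient_calls_incl,
              qn$counts$gradient_calls_excl)
  }
})

test_that("a guess already at the saddle converges with a zero-norm step", {
  pot <- toy_potential("mueller_brown_2d")
  sad <- oracle_saddles("mueller_brown_2d")[[1]]
  fit <- optimize_saddle(pot, sad)
  expect_true(fit$converged)
  expect_lte(fit$counts$steps, 1L)
  expect_lt(geom_dist("mueller_brown_2d", fit$final_geometry, sad), 1e-9)
})

test_that("accepted optimizer steps never exceed the trust-radius bound", {
  pot <- toy_potential("morse_exchange_abc")
  guess <- perturb_guess(exchange_saddle(), 20, seed = 61)
  fit <- optimize_saddle(pot, guess, "exact_every_step")
  frames <- fit$trace_frames
  radii <- fit$trace$trust_radius
  for (k in seq_len(length(frames) - 1)) {
    stp <- sqrt(sum((frames[[k + 1]] - frames[[k]])^2))
    expect_lte(stp, max(radii[k], radii[k + 1]) + 1e-10)
  }
})

test_that("trace accounting is monotone and separates the two gradient-call bases", {
  pot <- toy_potential("torsion_tetramer")
  guess <- perturb_guess(oracle_saddles("torsion_tetramer")[[1]], 20,
                         seed = 62)
  qn <- optimize_saddle(pot, guess, "qn")
  expect_true(all(diff(qn$trace$step) == 1))
  expect_gte(qn$counts$gradient_calls_incl, qn$counts$gradient_calls_excl)
  full <- optimize_saddle(pot, guess, "exact_every_step")
  expect_equal(full$counts$gradient_calls_incl,
               full$counts$gradient_calls_excl)
  expect_equal(full$counts$hessian_evals, full$counts$steps)
})
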
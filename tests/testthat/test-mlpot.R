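# Surrogate potential: feature smoothness and cutoff behaviour, exact
# analytic derivatives, symmetry invariances, training behaviour, ensemble
# outlier rejection.

spec3 <- feature_spec(c("F", "H", "O"))

test_that("pair features vanish identically beyond the cutoff and are continuous through it", {
  g_far <- geometry(c("F", "H"), rbind(c(0, 0, 0), c(5.5, 0, 0)))
  expect_true(all(featurize(g_far, spec3) == 0))
  g1 <- geometry(c("F", "H"), rbind(c(0, 0, 0), c(4.999, 0, 0)))
  g2 <- geometry(c("F", "H"), rbind(c(0, 0, 0), c(5.001, 0, 0)))
  expect_lt(max(abs(featurize(g1, spec3) - featurize(g2, spec3))), 1e-6)
  # cutoff polynomial: value and first two derivatives vanish at r_cut
  expect_equal(hesstate:::.cutoff_val(5, 5), 0)
  expect_equal(hesstate:::.cutoff_d1(5 - 1e-9, 5), 0, tolerance = 1e-6)
  expect_equal(hesstate:::.cutoff_d2(5 - 1e-9, 5), 0, tolerance = 1e-4)
})

test_that("permuting atoms permutes per-atom features and leaves the molecular sum unchanged", {
  g <- random_geometry("morse_exchange_abc", seed = 31)
  X <- featurize(g, spec3)
  perm <- c(3, 1, 2)
  gp <- geometry(g$elements[perm], g$coords[perm, ], g$masses[perm])
  Xp <- featurize(gp, spec3)
  expect_equal(Xp, X[perm, ])
  expect_equal(colSums(Xp), colSums(X))
})

test_that("surrogate energy is invariant to permutation, translation and rotation", {
  m <- trained_surrogate()
  g <- random_geometry("morse_exchange_abc", seed = 32)
  e0 <- pes_eval(m, g)$energy
  perm <- c(2, 3, 1)
  gp <- geometry(g$elements[perm], g$coords[perm, ], g$masses[perm])
  expect_lt(abs(pes_eval(m, gp)$energy - e0), 1e-8)
  gt <- set_coords(g, coords_vector(g) + rep(c(3, -1, 2), 3))
  expect_lt(abs(pes_eval(m, gt)$energy - e0), 1e-8)
  th <- 0.83
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  gr <- set_coords(g, as.numeric(t(g$coords %*% R)))
  expect_lt(abs(pes_eval(m, gr)$energy - e0), 1e-8)
  # pure translation: gradient transported unchanged
  expect_lt(max(abs(pes_eval(m, gt)$gradient - pes_eval(m, g)$gradient)),
            1e-8)
})

test_that("predicted gradients are exact derivatives of the predicted energy", {
  m <- trained_surrogate()
  for (s in 1:6) {
    g <- random_geometry("morse_exchange_abc", seed = 40 + s)
    ev <- predict_ef(m, g)
    gfd <- fd_gradient(m, g)
    expect_lt(max(abs(gfd - ev$gradient)) / max(1, max(abs(ev$gradient))),
              1e-6)
  }
})

test_that("analytic model Hessians are symmetric and match finite differences of the gradient", {
  m <- trained_surrogate()
  for (s in 1:6) {
    g <- random_geometry("morse_exchange_abc", seed = 50 + s)
    H <- hessian_autodiff(m, g)
    expect_equal(H, t(H))
    Hfd <- fd_hessian_of(m, g)
    expect_lt(max(abs(Hfd - H)), 1e-5 * max(1, max(abs(H))))
  }
})

test_that("geometries with all pairs beyond the cutoff give bias-only energy and zero derivatives", {
  m <- trained_surrogate()
  g <- geometry(c("F", "H", "O"),
                rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0)))
  ev <- pes_eval(m, g, hessian = TRUE)
  bias <- sum(m$params$bias[match(g$elements, m$spec$elements)]) +
    m$e_scale * sum(crossprod(
      hesstate:::.act_fns("silu")$f(
        m$params$W1 %*% t(hesstate:::.normalize_features(
          m, featurize(g, m$spec))) + m$params$b1), m$params$w2))
  expect_equal(ev$energy, bias)
  expect_true(all(ev$gradient == 0))
  expect_true(all(ev$hessian == 0))
})

test_that("non-C2 activations are refused for Hessian evaluation", {
  pot <- toy_potential("morse_exchange_abc")
  ds <- sample_training_set(pot, n_path = 40, n_compressed = 0, seed = 3)
  m_relu <- train_surrogate(ds, training_config(max_epochs = 3,
                                                activation = "relu",
                                                seed = 1))
  expect_error(hessian_autodiff(m_relu, ds$records[[1]]$geometry),
               "twice continuously")
  expect_silent(predict_ef(m_relu, ds$records[[1]]$geometry))
})

test_that("training requires data with forces and aborts cleanly on empty input", {
  expect_error(train_surrogate(configuration_set(list())), "empty")
  pot <- toy_potential("morse_exchange_abc")
  ds <- sample_training_set(pot, n_path = 5, n_compressed = 0, seed = 1)
  ds$records[[2]]$forces <- NULL
  expect_error(train_surrogate(ds), "forces")
})

test_that("the loss is a per-sample mean: duplicating a batch leaves it unchanged", {
  pot <- toy_potential("morse_exchange_abc")
  ds <- sample_training_set(pot, n_path = 12, n_compressed = 0, seed = 2)
  spec <- feature_spec(c("F", "H", "O"))
  Xall <- do.call(rbind, lapply(ds$records,
                                function(r) featurize(r$geometry, spec)))
  norm <- list(mean = colMeans(Xall), sd = pmax(apply(Xall, 2, sd), 1e-8))
  dd <- hesstate:::.prepare_training_data(ds, spec, norm)
  set.seed(9)
  Hh <- 6
  params <- list(W1 = matrix(rnorm(Hh * spec$n_features, sd = 0.2), Hh),
                 b1 = rnorm(Hh), w2 = rnorm(Hh), bias = rnorm(3))
  cfg <- training_config(seed = 1)
  act <- hesstate:::.act_fns("silu")
  l1 <- hesstate:::.loss_and_grad(params, dd, cfg, act, 3.1, 1:12,
                                  want_grad = FALSE)$loss
  l2 <- hesstate:::.loss_and_grad(params, dd, cfg, act, 3.1,
                                  rep(1:12, 2), want_grad = FALSE)$loss
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("training improves a held-out validation loss with a non-increasing best-so-far envelope", {
  pot <- toy_potential("torsion_tetramer")
  ds <- sample_training_set(pot, n_path = 120, n_compressed = 0, seed = 4)
  m <- train_surrogate(ds, training_config(max_epochs = 300, hidden = 16,
                                           seed = 2))
  h <- m$metadata$history
  expect_true(all(diff(h$best_val) <= 0))
  expect_lt(tail(h$best_val, 1), h$val_loss[1])
  # reproducibility under the same seed
  m2 <- train_surrogate(ds, training_config(max_epochs = 300, hidden = 16,
                                            seed = 2))
  expect_identical(m$params, m2$params)
})

test_that("force-weighted training beats energy-only training on force error", {
  pot <- toy_potential("morse_exchange_abc")
  ds <- sample_training_set(pot, n_path = 200, n_compressed = 0, seed = 21)
  hold <- sample_training_set(pot, n_path = 60, n_compressed = 0,
                              seed = 22)
  frmse <- function(m) {
    sqrt(mean(unlist(lapply(hold$records, function(r)
      (-pes_eval(m, r$geometry)$gradient - r$forces)^2))))
  }
  m_f <- train_surrogate(ds, training_config(max_epochs = 1200, seed = 3))
  m_e <- train_surrogate(ds, training_config(lambda_f = 0,
                                             max_epochs = 1200, seed = 3))
  expect_lt(frmse(m_f) * 3, frmse(m_e))
})

test_that("ensemble consensus applies the Dixon Q rejection exactly as specified", {
  # clear outlier: Q = 0.98 / 1.00 > 0.829
  e1 <- ensemble_predict_with_dixon(c(1.00, 1.01, 1.02, 2.00))
  expect_equal(sum(e1$retained_mask), 3L)
  expect_false(e1$retained_mask[4])
  expect_equal(e1$consensus, 1.01)
  # degenerate range: retain all
  e2 <- ensemble_predict_with_dixon(c(1, 1, 1, 1))
  expect_true(all(e2$retained_mask))
  expect_equal(e2$consensus, 1)
  # evenly spread: Q = 1/3, nothing removed
  e3 <- ensemble_predict_with_dixon(c(1.0, 1.10, 1.20, 1.30))
  expect_true(all(e3$retained_mask))
  expect_equal(e3$q_statistic, 1 / 3, tolerance = 1e-12)
  # low-side outlier is also detected
  e4 <- ensemble_predict_with_dixon(c(0.0, 1.00, 1.01, 1.02))
  expect_false(e4$retained_mask[1])
  expect_error(ensemble_predict_with_dixon(c(1, 2, 3)), "exactly 4")
})
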
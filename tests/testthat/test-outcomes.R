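# Graph construction, isomorphism, outcome classification, Kabsch path
# lengths and benchmark bookkeeping.

test_that("bond perception applies the scaled covalent-radius rule", {
  water <- geometry(c("O", "H", "H"),
                    rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
  g <- build_graph(water)
  expect_equal(nrow(g$edges), 2)
  expect_true(all(g$edges[, 1] == 1))       # both bonds involve the O
  stretched <- geometry(c("O", "H"), rbind(c(0, 0, 0), c(2.5, 0, 0)))
  expect_equal(nrow(build_graph(stretched)$edges), 0)
  expect_error(build_graph(geometry("Zz", c(0, 0, 0), masses = 1)),
               "covalent radius")
})

test_that("isomorphism respects element labels and atom reindexing", {
  g <- geometry(c("F", "H", "O"),
                rbind(c(0, 0, 0), c(0.95, 0, 0), c(4, 0, 0)))
  gr <- build_graph(g)
  perm <- c(3, 1, 2)
  gp <- build_graph(geometry(g$elements[perm], g$coords[perm, ],
                             g$masses[perm]))
  expect_true(graphs_isomorphic(gr, gp))
  # F-H + O vs F + H-O: same elements, different labelled edges
  g2 <- geometry(c("F", "H", "O"),
                 rbind(c(0, 0, 0), c(4, 0, 0), c(4.97, 0, 0)))
  expect_false(graphs_isomorphic(gr, build_graph(g2)))
  # H-H + O vs O-H + H would differ; H-H + F vs H + H-F with relabelled
  # ends of the same element are abstractly isomorphic
  h2a <- geometry(c("H", "H", "F"),
                  rbind(c(0, 0, 0), c(0.7, 0, 0), c(5, 0, 0)))
  h2b <- geometry(c("F", "H", "H"),
                  rbind(c(0, 0, 0), c(5, 0, 0), c(5.7, 0, 0)))
  expect_true(graphs_isomorphic(build_graph(h2a), build_graph(h2b)))
  # empty-edge graphs with equal element multisets are isomorphic
  e1 <- build_graph(geometry(c("H", "O"), rbind(c(0, 0, 0), c(9, 0, 0))))
  e2 <- build_graph(geometry(c("O", "H"), rbind(c(0, 0, 0), c(9, 0, 0))))
  expect_true(graphs_isomorphic(e1, e2))
})

test_that("outcomes classify as 2-end / 1-end / none with chemical vs conformational type", {
  fake_irc <- function(a, b) {
    attr(a, "converged") <- TRUE; attr(b, "converged") <- TRUE
    list(forward = list(endpoint = a), backward = list(endpoint = b))
  }
  R <- geometry(c("F", "H", "O"),
                rbind(c(0, 0, 0), c(0.95, 0, 0), c(4, 0, 0)))   # F-H + O
  P <- geometry(c("F", "H", "O"),
                rbind(c(0, 0, 0), c(4, 0, 0), c(4.96, 0, 0)))   # F + H-O
  X <- geometry(c("F", "H", "O"),
                rbind(c(0, 0, 0), c(8, 0, 0), c(16, 0, 0)))     # no bonds
  two <- classify_outcome(fake_irc(R, P), R, P)
  expect_equal(two$match, "two_end")
  expect_equal(two$ts_type, "chemical")
  one <- classify_outcome(fake_irc(R, X), R, P)
  expect_equal(one$match, "one_end")
  expect_equal(one$ts_type, "chemical")
  none <- classify_outcome(fake_irc(X, X), R, P)
  expect_equal(none$match, "none")
  expect_equal(none$ts_type, "conformational")  # isomorphic endpoints
  # order of endpoints does not matter (unordered pair)
  swapped <- classify_outcome(fake_irc(P, R), R, P)
  expect_equal(swapped$match, "two_end")
  # unconverged endpoints force match = none
  bad <- fake_irc(R, P)
  attr(bad$forward$endpoint, "converged") <- FALSE
  expect_equal(classify_outcome(bad, R, P)$match, "none")
  # invariance to reindexing of the intended structures
  perm <- c(2, 3, 1)
  Rp <- geometry(R$elements[perm], R$coords[perm, ], R$masses[perm])
  expect_equal(classify_outcome(fake_irc(R, P), Rp, P)$match, "two_end")
})

test_that("Kabsch path length ignores rigid motion and adds per segment", {
  set.seed(41)
  A <- matrix(rnorm(12), 4, 3)
  th <- 0.9
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rotated <- A %*% R + matrix(rep(c(5, -2, 1), each = 4), 4, 3)
  expect_lt(kabsch_path_length(list(A, rotated)), 1e-10)
  # one atom moved 0.3, verified against a brute-force rotation search
  B <- A; B[2, 1] <- B[2, 1] + 0.3
  len <- kabsch_path_length(list(A, B))
  brute <- Inf
  for (a1 in seq(0, 2 * pi, length.out = 60))
    for (a2 in seq(-0.5, 0.5, length.out = 21)) {
      Rz <- matrix(c(cos(a1), -sin(a1), 0, sin(a1), cos(a1), 0, 0, 0, 1),
                   3, 3)
      Ry <- matrix(c(cos(a2), 0, sin(a2), 0, 1, 0, -sin(a2), 0, cos(a2)),
                   3, 3)
      Bc <- sweep(B, 2, colMeans(B)); Ac <- sweep(A, 2, colMeans(A))
      brute <- min(brute, sqrt(sum((Bc %*% (Rz %*% Ry) - Ac)^2)))
    }
  expect_lte(len, brute + 1e-9)
  expect_lt(len, 0.3 + 1e-9)    # alignment can only shrink the distance
  expect_gt(len, 0.1)
  # a retraced path doubles the length
  expect_equal(kabsch_path_length(list(A, B, A)), 2 * len,
               tolerance = 1e-10)
  expect_error(kabsch_path_length(list(A, matrix(0, 3, 3))),
               "shape mismatch")
})

test_that("an empty mode list yields an empty benchmark report", {
  rep <- run_benchmark(list(), modes = character(0))
  expect_s3_class(rep, "benchmark_report")
  expect_equal(nrow(rep$records), 0)
  ag <- benchmark_aggregates(rep)
  expect_equal(nrow(ag$success_rate), 0)
})

test_that("benchmark aggregates are a pure function of the records", {
  suite <- toy_benchmark_suite("mueller_brown_2d")
  rep <- run_benchmark(suite, noise_grid = c(0, 30), n_seeds = 2,
                       seed = 3)
  ag1 <- benchmark_aggregates(rep)
  ag2 <- benchmark_aggregates(rep$records)
  expect_identical(ag1, ag2)
  by_hand <- with(rep$records[rep$records$mode == "full" &
                                rep$records$sigma_pm == 0, ],
                  mean(success))
  expect_equal(ag1$success_rate$success_rate[
    ag1$success_rate$mode == "full" &
      ag1$success_rate$sigma_pm == 0], by_hand)
})

test_that("identical configuration and seeds reproduce the benchmark byte for byte", {
  suite <- toy_benchmark_suite("torsion_tetramer")
  a <- run_benchmark(suite, noise_grid = c(0, 20), n_seeds = 2, seed = 9)
  b <- run_benchmark(suite, noise_grid = c(0, 20), n_seeds = 2, seed = 9)
  expect_identical(a$records, b$records)
})
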
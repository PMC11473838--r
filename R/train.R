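# Training of the surrogate potential: weighted energy + force loss
#   L = (lambda_E / M) sum_m (E_hat - E)^2
#     + (lambda_F / M) sum_m (1 / 3A_m) |F_hat - F|^2  + l2 |theta|^2
# minimized by mini-batch Adam.  Force residuals require the derivative of
# the predicted gradient with respect to every parameter; these mixed second
# derivatives are closed-form for this architecture and are assembled below.

#' Training configuration for the surrogate potential
#'
#' Defaults follow the package's standard recipe: energy weight 1, force
#' weight 20, batch size 100, initial Adam learning rate 1e-4 decayed by 0.7
#' when the validation loss plateaus, and L2 regularization 1e-5.
#'
#' @param lambda_e energy loss weight (>= 0).
#' @param lambda_f force loss weight (>= 0).
#' @param batch_size mini-batch size.
#' @param learning_rate initial Adam learning rate.
#' @param decay_factor learning-rate decay applied on validation plateau.
#' @param l2 L2 regularization strength on all trainable parameters.
#' @param max_epochs maximum training epochs.
#' @param patience epochs without >1e-4 relative validation improvement
#'   before the learning rate is decayed.
#' @param hidden width of the single SiLU hidden layer.
#' @param activation \code{"silu"} (C2, default) or \code{"relu"}
#'   (non-smooth; accepted for energy/force fitting but rejected by
#'   \code{hessian_autodiff}).
#' @param val_fraction fraction of records held out for validation.
#' @param seed integer seed controlling initialization, the train/validation
#'   split and batch shuffling.
#' @return object of class \code{"training_config"}.
#' @export
training_config <- function(lambda_e = 1, lambda_f = 20, batch_size = 100L,
                            learning_rate = 1e-4, decay_factor = 0.7,
                            l2 = 1e-5, max_epochs = 4000L, patience = 150L,
                            hidden = 48L, activation = "silu",
                            val_fraction = 0.1, seed = 1L) {
  if (lambda_e < 0 || lambda_f < 0) stop("loss weights must be >= 0")
  structure(list(lambda_e = lambda_e, lambda_f = lambda_f,
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 decay_factor = decay_factor, l2 = l2,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 hidden = as.integer(hidden), activation = activation,
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "training_config")
}

# precompute fixed stacked tensors: normalized features (F x A*M,
# atom-major within record), scaled feature jacobians (F x n3*A*M), targets
.prepare_training_data <- function(data, spec, norm) {
  recs <- data$records
  M <- length(recs)
  A <- n_atoms(recs[[1]]$geometry)
  n3 <- 3L * A
  Ff <- spec$n_features
  XnT <- matrix(0, Ff, A * M)
  Jbig <- matrix(0, Ff, n3 * A * M)
  E <- numeric(M); G <- matrix(0, n3, M)
  el_idx <- match(recs[[1]]$geometry$elements, spec$elements)
  inv_sd <- 1 / norm$sd
  for (m in seq_len(M)) {
    g <- recs[[m]]$geometry
    if (n_atoms(g) != A)
      stop("all records must share one atom count for batched training")
    X <- featurize(g, spec)
    XnT[, (m - 1L) * A + seq_len(A)] <-
      t(sweep(sweep(X, 2, norm$mean), 2, norm$sd, "/"))
    fj <- .feature_jacobians(g, spec)
    for (i in seq_len(A)) {
      a <- (m - 1L) * A + i
      Jbig[, (a - 1L) * n3 + seq_len(n3)] <- fj$J[[i]] * inv_sd
    }
    E[m] <- recs[[m]]$energy
    G[, m] <- -recs[[m]]$forces
  }
  list(XnT = XnT, Jbig = Jbig, E = E, G = G, M = M, A = A, n3 = n3,
       el_idx = el_idx, n_feat = Ff)
}

# loss and parameter gradient over a set of record indices, vectorized
# across the whole batch (atoms of all batch records stacked columnwise)
.loss_and_grad <- function(params, dd, cfg, act, e_scale, idx,
                           want_grad = TRUE) {
  W1 <- params$W1; b1 <- params$b1; w2 <- params$w2; bias <- params$bias
  n3 <- dd$n3; A <- dd$A
  B <- length(idx)
  AB <- A * B
  atom_cols <- rep((idx - 1L) * A, each = A) + seq_len(A)
  jac_cols <- rep((atom_cols - 1L) * n3, each = n3) + seq_len(n3)
  Xb <- dd$XnT[, atom_cols, drop = FALSE]             # F x AB
  Jb <- dd$Jbig[, jac_cols, drop = FALSE]             # F x n3*AB
  Z <- W1 %*% Xb + b1                                 # H x AB
  Aact <- act$f(Z); S1 <- act$d1(Z)
  T1 <- w2 * S1
  K <- W1 %*% Jb                                      # H x n3*AB
  # predicted energies and gradients
  Ehat <- e_scale * colSums(matrix(as.numeric(w2 %*% Aact), A, B)) +
    sum(bias[dd$el_idx])
  cs <- colSums(K * T1[, rep(seq_len(AB), each = n3), drop = FALSE])
  Ghat <- e_scale *
    apply(array(cs, dim = c(n3, A, B)), c(1, 3), sum)
  if (B == 1L) Ghat <- matrix(Ghat, n3, 1L)
  re <- Ehat - dd$E[idx]
  rf <- Ghat - dd$G[, idx, drop = FALSE]              # n3 x B
  wf <- cfg$lambda_f / (3 * A)
  loss <- (cfg$lambda_e * sum(re^2) + wf * sum(rf^2)) / B +
    cfg$l2 * (sum(W1^2) + sum(b1^2) + sum(w2^2) + sum(bias^2))
  if (!want_grad) return(list(loss = loss))

  S2 <- act$d2(Z)
  rfA <- rf[, rep(seq_len(B), each = A), drop = FALSE] # n3 x AB
  V <- matrix(0, length(b1), AB)                       # v_a = K_a rf
  JRF <- matrix(0, dd$n_feat, AB)                      # J_a rf
  for (al in seq_len(n3)) {
    cols <- seq(al, n3 * AB, by = n3)
    V <- V + K[, cols, drop = FALSE] *
      rep(rfA[al, ], each = length(b1))
    JRF <- JRF + Jb[, cols, drop = FALSE] *
      rep(rfA[al, ], each = dd$n_feat)
  }
  ce <- 2 * cfg$lambda_e * re                          # per record
  ceA <- rep(ce, each = A)                             # per atom
  cf <- 2 * wf
  W2S2V <- w2 * (S2 * V)
  gw2 <- e_scale * (as.numeric(Aact %*% ceA) + cf * rowSums(S1 * V))
  gb1 <- e_scale * (as.numeric(T1 %*% ceA) + cf * rowSums(W2S2V))
  gW1 <- e_scale * (
    (T1 * rep(ceA, each = length(b1))) %*% t(Xb) +
      cf * (T1 %*% t(JRF) + W2S2V %*% t(Xb)))
  counts <- tabulate(dd$el_idx, nbins = length(bias))
  gbias <- sum(ce) * counts
  list(loss = loss,
       grad = list(W1 = gW1 / B + 2 * cfg$l2 * W1,
                   b1 = gb1 / B + 2 * cfg$l2 * b1,
                   w2 = gw2 / B + 2 * cfg$l2 * w2,
                   bias = gbias / B + 2 * cfg$l2 * bias))
}

#' Train the surrogate potential on energies and forces
#'
#' Fits the radial-feature SiLU network by mini-batch Adam on the weighted
#' energy + force mean-squared loss (energy term per configuration, force
#' term per 3A force components) with L2 regularization.  Only energies and
#' forces enter the loss; Hessians are never trained and are obtained
#' afterwards by analytic differentiation of the fitted model.  Training is
#' deterministic for a fixed config seed.
#'
#' @param data a \code{configuration_set} with forces on every record.
#' @param config a \code{training_config}.
#' @param spec optional \code{feature_spec}; defaults to 20 RBFs / 5
#'   Angstrom cutoff over the elements present in the data.
#' @param verbose print progress every 200 epochs.
#' @return a \code{surrogate_model}; \code{$metadata$history} holds the
#'   per-epoch training/validation losses, the learning-rate trajectory and
#'   the running best ("envelope") validation loss.
#' @export
train_surrogate <- function(data, config = training_config(), spec = NULL,
                            verbose = FALSE) {
  if (!length(data$records)) stop("empty training data")
  for (r in data$records)
    if (is.null(r$forces)) stop("every record must carry forces")
  set.seed(config$seed)
  if (is.null(spec))
    spec <- feature_spec(unique(unlist(
      lapply(data$records, function(r) r$geometry$elements))))
  act <- .act_fns(config$activation)

  # feature normalization from the full data set
  Xall <- do.call(rbind, lapply(data$records,
                                function(r) featurize(r$geometry, spec)))
  norm <- list(mean = colMeans(Xall),
               sd = pmax(apply(Xall, 2, stats::sd), 1e-8))

  # per-element energy baseline by (ridge-stabilized) least squares, and an
  # output scale matching the residual energy spread
  el_counts <- t(vapply(data$records, function(r)
    as.numeric(table(factor(r$geometry$elements, levels = spec$elements))),
    numeric(length(spec$elements))))
  if (length(spec$elements) == 1L) el_counts <- t(el_counts)
  E <- vapply(data$records, function(r) r$energy, 0)
  CtC <- crossprod(el_counts) + 1e-8 * diag(ncol(el_counts))
  bias0 <- as.numeric(solve(CtC, crossprod(el_counts, E)))
  resid <- E - as.numeric(el_counts %*% bias0)
  Atoms <- n_atoms(data$records[[1]]$geometry)
  Gd <- vapply(data$records, function(r) max(abs(r$forces)), 0)
  e_scale <- max(stats::sd(resid), stats::median(Gd) / 2, 1e-6)

  Hh <- config$hidden
  Ff <- spec$n_features
  params <- list(
    W1 = matrix(stats::rnorm(Hh * Ff, sd = 1 / sqrt(Ff)), Hh, Ff),
    b1 = stats::rnorm(Hh, sd = 0.1),
    w2 = stats::rnorm(Hh, sd = 1 / sqrt(Hh)),
    bias = bias0)

  dd <- .prepare_training_data(data, spec, norm)
  M <- dd$M
  n_val <- max(1L, min(M - 1L, round(config$val_fraction * M)))
  val_idx <- sort(sample.int(M, n_val))
  train_idx <- setdiff(seq_len(M), val_idx)
  if (!length(train_idx)) { train_idx <- val_idx }

  # Adam state
  zeros_like <- function(p) lapply(p, function(x) x * 0)
  mom <- zeros_like(params); vel <- zeros_like(params)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  step <- 0L

  hist_train <- numeric(config$max_epochs)
  hist_val <- numeric(config$max_epochs)
  hist_lr <- numeric(config$max_epochs)
  hist_best <- numeric(config$max_epochs)
  best_val <- Inf; best_params <- params
  since_improve <- 0L
  n_epochs <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(train_idx)
    nb <- ceiling(length(ord) / config$batch_size)
    ep_loss <- 0
    for (b in seq_len(nb)) {
      bi <- ord[((b - 1L) * config$batch_size + 1L):
                  min(b * config$batch_size, length(ord))]
      lg <- .loss_and_grad(params, dd, config, act, e_scale, bi)
      ep_loss <- ep_loss + lg$loss * length(bi)
      step <- step + 1L
      for (p in names(params)) {
        g <- lg$grad[[p]]
        mom[[p]] <- beta1 * mom[[p]] + (1 - beta1) * g
        vel[[p]] <- beta2 * vel[[p]] + (1 - beta2) * g^2
        mh <- mom[[p]] / (1 - beta1^step)
        vh <- vel[[p]] / (1 - beta2^step)
        params[[p]] <- params[[p]] - lr * mh / (sqrt(vh) + eps)
      }
    }
    vl <- .loss_and_grad(params, dd, config, act, e_scale, val_idx,
                         want_grad = FALSE)$loss
    if (!is.finite(vl) || !is.finite(ep_loss))
      stop("NaN loss encountered at epoch ", epoch,
           "; training aborted (check data scaling)")
    if (vl < best_val * (1 - 1e-4)) {
      best_val <- vl; best_params <- params; since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (vl < best_val) { best_val <- vl; best_params <- params }
    }
    n_epochs <- epoch
    hist_train[epoch] <- ep_loss / length(ord)
    hist_val[epoch] <- vl
    hist_lr[epoch] <- lr
    hist_best[epoch] <- best_val
    if (since_improve >= config$patience) {
      lr <- lr * config$decay_factor
      since_improve <- 0L
      if (lr < 1e-8) break
    }
    if (verbose && epoch %% 200 == 0)
      cat(sprintf("epoch %d  train %.5g  val %.5g  lr %.3g\n",
                  epoch, ep_loss / length(ord), vl, lr))
  }

  history <- data.frame(epoch = seq_len(n_epochs),
                        train_loss = hist_train[seq_len(n_epochs)],
                        val_loss = hist_val[seq_len(n_epochs)],
                        lr = hist_lr[seq_len(n_epochs)],
                        best_val = hist_best[seq_len(n_epochs)])
  .new_surrogate(spec, best_params, norm, config$activation, e_scale,
                 metadata = list(config = config, history = history,
                                 final_val_loss = best_val,
                                 epochs_run = n_epochs,
                                 seed = config$seed))
}

#' Ensemble consensus with Dixon Q outlier rejection
#'
#' Given exactly four member predictions, computes the Dixon Q statistic of
#' the most isolated extreme value, Q = gap(candidate, nearest neighbour) /
#' range, and removes it iff Q exceeds the 95% two-sided critical value for
#' n = 4 (0.829, standard table value).  At most one member is removed; a
#' zero range retains all members.
#'
#' @param values numeric vector of exactly 4 finite member predictions.
#' @return object of class \code{"ensemble_prediction"}: list with
#'   \code{member_values}, \code{retained_mask}, \code{consensus},
#'   \code{q_statistic}.
#' @export
ensemble_predict_with_dixon <- function(values) {
  if (length(values) != 4L || !all(is.finite(values)))
    stop("exactly 4 finite ensemble member values required")
  q_crit <- 0.829
  s <- sort(values)
  rng <- s[4] - s[1]
  retained <- rep(TRUE, 4L)
  q <- NA_real_
  if (rng > 0) {
    q_low <- (s[2] - s[1]) / rng
    q_high <- (s[4] - s[3]) / rng
    if (q_high >= q_low) { q <- q_high; cand <- s[4] }
    else { q <- q_low; cand <- s[1] }
    if (q > q_crit)
      retained[which(values == cand)[1]] <- FALSE
  }
  structure(list(member_values = values, retained_mask = retained,
                 consensus = mean(values[retained]), q_statistic = q),
            class = "ensemble_prediction")
}

#' @export
print.ensemble_prediction <- function(x, ...) {
  cat("<ensemble_prediction> consensus =", format(x$consensus, digits = 8),
      "retained", sum(x$retained_mask), "of 4",
      if (!is.na(x$q_statistic)) paste0("(Q = ",
        format(x$q_statistic, digits = 4), ")"), "\n")
  invisible(x)
}
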
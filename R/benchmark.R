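# Full-Hessian vs quasi-Newton benchmark harness: frozen toy reaction
# suite, Gaussian-noise robustness protocol, outcome classification and
# recomputable aggregates.

#' The frozen toy reaction suite
#'
#' One benchmark reaction per analytic surface: the reference saddle plus
#' the intended reactant/product endpoints, defined as the minima reached by
#' the exact-potential IRC from that saddle (the oracle stands in for
#' template-based intent definitions).  The Mueller-Brown reaction uses its
#' lower saddle; the exchange surface uses its bond-exchange saddle (the
#' highest-energy one, with distinct endpoint graphs); the tetramer uses its
#' torsional barrier (isomorphic endpoint graphs).
#'
#' @param surfaces which surfaces to include.
#' @return list of reactions: each a list with \code{name},
#'   \code{potential}, \code{saddle}, \code{intended_reactant},
#'   \code{intended_product}.
#' @export
toy_benchmark_suite <- function(surfaces = c("mueller_brown_2d",
                                             "morse_exchange_abc",
                                             "torsion_tetramer")) {
  lapply(surfaces, function(nm) {
    pot <- toy_potential(nm)
    sads <- find_stationary_oracle(pot, "saddle")
    sad <- if (nm == "morse_exchange_abc") sads[[length(sads)]] else
      sads[[1]]
    irc <- follow_irc(pot, sad)
    list(name = nm, potential = pot, saddle = sad,
         intended_reactant = irc$forward$endpoint,
         intended_product = irc$backward$endpoint)
  })
}

.mode_to_hessian <- function(mode) {
  switch(mode, full = "exact_every_step", qn = "qn",
         stop("unknown mode: ", mode))
}

#' Run the full-vs-quasi-Newton benchmark
#'
#' For every (reaction, mode, noise level, replicate): perturb the reference
#' saddle with Gaussian coordinate noise, optimize with the requested
#' Hessian source, follow the IRC from the result and classify the outcome
#' against the intended reaction.  The same perturbed guess is used for
#' every mode (guesses depend only on reaction, noise and replicate seed),
#' so the comparison is paired.  "Success" is defined as: converged to a
#' first-order saddle AND a 2-end match of the intended endpoints.
#' Individual failures are recorded, never abort the suite.
#'
#' @param suite reactions from \code{\link{toy_benchmark_suite}}.
#' @param modes subset of \code{c("full", "qn")}.
#' @param noise_grid noise standard deviations in picometres.
#' @param n_seeds replicates per (reaction, noise) cell.
#' @param seed base seed for the replicate streams.
#' @param base_sigma_pm baseline displacement (pm) applied to every guess
#'   before the noise-grid perturbation, emulating an imperfect
#'   template-generated guess (default 5 pm).
#' @param config a \code{saddle_config}.
#' @return object of class \code{"benchmark_report"}: list with
#'   \code{records} (one data.frame row per run) and the arguments;
#'   aggregate with \code{\link{benchmark_aggregates}}.
#' @export
run_benchmark <- function(suite, modes = c("full", "qn"),
                          noise_grid = c(0, 10, 20, 30, 50),
                          n_seeds = 5L, seed = 1L, base_sigma_pm = 5,
                          config = saddle_config()) {
  rows <- list()
  if (length(modes) == 0 || length(suite) == 0)
    return(structure(list(records = data.frame(), modes = modes,
                          noise_grid = noise_grid, n_seeds = n_seeds,
                          seed = seed),
                     class = "benchmark_report"))
  for (ri in seq_along(suite)) {
    rxn <- suite[[ri]]
    for (si in seq_along(noise_grid)) {
      sigma <- noise_grid[si]
      for (rep in seq_len(n_seeds)) {
        guess_seed <- (seed * 1000L + ri * 131L + si * 17L + rep) %%
          .Machine$integer.max
        guess <- perturb_guess(rxn$saddle, base_sigma_pm,
                               seed = guess_seed)
        guess <- perturb_guess(guess, sigma, seed = guess_seed + 7L)
        for (mode in modes) {
          rec <- tryCatch(
            .bench_one(rxn, guess, mode, config),
            error = function(e) list(converged = FALSE, n_negative = NA,
                                     match = "none", ts_type = NA,
                                     steps = NA, g_excl = NA, g_incl = NA,
                                     path_length = NA,
                                     error = conditionMessage(e)))
          rows[[length(rows) + 1L]] <- data.frame(
            reaction = rxn$name, mode = mode, sigma_pm = sigma,
            replicate = rep, converged = rec$converged,
            n_negative = rec$n_negative, match = rec$match,
            ts_type = if (is.null(rec$ts_type)) NA else rec$ts_type,
            steps = rec$steps, gradient_calls_excl = rec$g_excl,
            gradient_calls_incl = rec$g_incl,
            path_length = rec$path_length,
            success = isTRUE(rec$converged) &&
              identical(rec$match, "two_end"),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  structure(list(records = do.call(rbind, rows), modes = modes,
                 noise_grid = noise_grid, n_seeds = n_seeds, seed = seed),
            class = "benchmark_report")
}

.bench_one <- function(rxn, guess, mode, config) {
  fit <- optimize_saddle(rxn$potential, guess,
                         hessian_mode = .mode_to_hessian(mode),
                         config = config)
  out <- list(converged = fit$converged && identical(fit$n_negative, 1L),
              n_negative = fit$n_negative, match = "none", ts_type = NA,
              steps = fit$counts$steps,
              g_excl = fit$counts$gradient_calls_excl,
              g_incl = fit$counts$gradient_calls_incl,
              path_length = NA_real_)
  if (!out$converged) return(out)
  irc <- follow_irc(rxn$potential, fit$final_geometry)
  cls <- classify_outcome(irc, rxn$intended_reactant,
                          rxn$intended_product)
  out$match <- cls$match
  out$ts_type <- cls$ts_type
  if (identical(cls$match, "two_end") && length(fit$trace_frames) >= 2)
    out$path_length <- kabsch_path_length(fit$trace_frames)
  out
}

#' Aggregate a benchmark report
#'
#' Pure function of the per-run records (so aggregates are recomputable and
#' checkable): success rates per mode and noise level, median step counts
#' and gradient-call totals per mode among converged sigma = 0 runs, and
#' median Kabsch path lengths among 2-end matches.
#'
#' @param report a \code{benchmark_report} (or its \code{records}).
#' @return list with \code{success_rate} (data.frame mode x sigma),
#'   \code{median_steps}, \code{median_calls_excl}, \code{median_calls_incl}
#'   (named by mode), \code{median_path_length}.
#' @export
benchmark_aggregates <- function(report) {
  rec <- if (is.data.frame(report)) report else report$records
  if (!nrow(rec))
    return(list(success_rate = data.frame(), median_steps = numeric(),
                median_calls_excl = numeric(),
                median_calls_incl = numeric(),
                median_path_length = numeric()))
  sr <- do.call(rbind, lapply(split(rec, rec[c("mode", "sigma_pm")]),
    function(d) data.frame(mode = d$mode[1], sigma_pm = d$sigma_pm[1],
                           success_rate = mean(d$success), n = nrow(d))))
  sr <- sr[order(sr$mode, sr$sigma_pm), ]
  rownames(sr) <- NULL
  base <- rec[rec$sigma_pm == min(rec$sigma_pm) & rec$converged %in% TRUE, ]
  med <- function(col) vapply(split(base, base$mode),
                              function(d) stats::median(d[[col]]), 0)
  list(success_rate = sr,
       median_steps = med("steps"),
       median_calls_excl = med("gradient_calls_excl"),
       median_calls_incl = med("gradient_calls_incl"),
       median_path_length = vapply(
         split(rec[rec$match == "two_end", ], rec[rec$match == "two_end",
                                                  "mode"]),
         function(d) stats::median(d$path_length, na.rm = TRUE), 0))
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report>", nrow(x$records), "runs;",
      "modes:", paste(x$modes, collapse = ", "), ";",
      "noise (pm):", paste(x$noise_grid, collapse = ", "), "\n")
  ag <- benchmark_aggregates(x)
  if (nrow(ag$success_rate)) {
    print(ag$success_rate, row.names = FALSE)
    cat("median steps (sigma = 0, converged):",
        paste(names(ag$median_steps), round(ag$median_steps, 1),
              sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}
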
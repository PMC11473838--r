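# Run configuration, provenance, model checkpoints and the command-line
# entry point tying the modules into a tool.

#' Assemble a run configuration with provenance flags
#'
#' Constants printed in the method description (initial trust radius 0.1,
#' grow 1.15 below ratio 1.035, shrink 0.65 above 5.0, IRC trust 0.1
#' Angstrom amu^1/2, 1000-step caps, Davidson step 1e-4 / threshold 0.1)
#' are the defaults; every other default is flagged \code{tool_default} in
#' the serialized configuration so provenance is auditable.
#'
#' @param potential potential name or path to a model checkpoint.
#' @param hessian_mode \code{"full"} or \code{"qn"}.
#' @param g_tol gradient convergence tolerance (tool default).
#' @param max_steps step cap.
#' @param irc_trust IRC trust radius.
#' @param seed integer seed.
#' @param out_dir output directory.
#' @return list of class \code{"run_config"}.
#' @export
run_config <- function(potential = "mueller_brown_2d",
                       hessian_mode = "full", g_tol = 1e-6,
                       max_steps = 1000L, irc_trust = 0.1, seed = 1L,
                       out_dir = ".") {
  structure(list(
    potential = potential, hessian_mode = hessian_mode,
    trust = list(radius_init = 0.1, ratio_low = 1.035, ratio_high = 5.0,
                 grow = 1.15, shrink = 0.65),
    g_tol = g_tol, max_steps = as.integer(max_steps),
    irc_trust = irc_trust, seed = as.integer(seed), out_dir = out_dir,
    tool_default = c("g_tol", "radius_min", "radius_max",
                     "qn_init_scale", "qn_restart_after",
                     "irc_displacement", "bond_scale")),
    class = "run_config")
}

#' Write / read a run configuration as YAML
#' @param config a \code{run_config} (or plain list).
#' @param path file path.
#' @return \code{write_run_config}: the path, invisibly;
#'   \code{read_run_config}: a \code{run_config}.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  structure(yaml::read_yaml(path), class = "run_config")
}

# machine-readable provenance block attached to every CLI run
.provenance <- function(config) {
  list(package = "hesstate",
       version = as.character(utils::packageVersion("hesstate")),
       r_version = R.version.string,
       config = unclass(config),
       timestamp = format(Sys.time(), tz = "UTC"))
}

#' Save / load a surrogate model checkpoint
#'
#' One portable JSON file holding weights, feature spec, normalization,
#' activation, output scale and the training seed.
#'
#' @param model a \code{surrogate_model}.
#' @param path checkpoint path (conventionally \code{.ckpt.json}).
#' @return \code{save_surrogate}: the path, invisibly;
#'   \code{load_surrogate}: the \code{surrogate_model}.
#' @export
save_surrogate <- function(model, path) {
  obj <- list(
    spec = list(elements = model$spec$elements, n_rbf = model$spec$n_rbf,
                r_cut = model$spec$r_cut),
    params = lapply(model$params, function(p)
      if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
      else list(dim = NULL, data = as.numeric(p))),
    norm = model$norm, activation = model$activation,
    e_scale = model$e_scale,
    seed = model$metadata$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_surrogate
#' @export
load_surrogate <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- feature_spec(obj$spec$elements, n_rbf = obj$spec$n_rbf,
                       r_cut = obj$spec$r_cut)
  params <- lapply(obj$params, function(p) {
    if (!is.null(p$dim) && length(p$dim)) matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  })
  .new_surrogate(spec, params,
                 list(mean = as.numeric(obj$norm$mean),
                      sd = as.numeric(obj$norm$sd)),
                 obj$activation, obj$e_scale,
                 metadata = list(seed = obj$seed, checkpoint = path))
}

.resolve_potential <- function(spec_str) {
  if (file.exists(spec_str)) load_surrogate(spec_str)
  else toy_potential(spec_str)
}

#' Command-line entry point
#'
#' Thin dispatcher used by the \code{inst/cli/hesstate.R} script.
#' Subcommands: \code{sample}, \code{train}, \code{opt-ts}, \code{irc},
#' \code{classify}, \code{bench}, \code{compare-hessian}.  Every run writes
#' a provenance block (package version, config, seeds) next to its outputs.
#'
#' @param argv character vector of command-line arguments (excluding the
#'   program name).
#' @return integer exit status (0 on success, 2 on usage errors).
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: hesstate <command> [options]",
    "  sample --potential NAME --n-path N [--n-compressed N] [--seed S] --out FILE.xyz",
    "  train --data FILE.xyz [--epochs N] [--seed S] --out MODEL.ckpt.json",
    "  opt-ts GUESS.xyz --potential NAME|MODEL.ckpt.json [--hessian full|qn]",
    "         [--trust0 R] [--gtol G] [--max-steps N] --out PREFIX",
    "  irc TS.xyz --potential NAME|MODEL [--trust R] --out PREFIX",
    "  classify TS.xyz --potential NAME --reactant R.xyz --product P.xyz",
    "  bench [--modes full,qn] [--noise 0,10,20,30,50] [--seeds N] [--seed S] --out PREFIX",
    "  compare-hessian A.txt B.txt [--out FILE.json]",
    sep = "\n")
  if (!length(argv)) { message(usage); return(2L) }
  cmd <- argv[1]
  args <- argv[-1]
  opt <- list(); pos <- character()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (grepl("^--", a)) {
      key <- sub("^--", "", a)
      if (i == length(args) || grepl("^--", args[i + 1]))
        { opt[[key]] <- TRUE; i <- i + 1L }
      else { opt[[key]] <- args[i + 1]; i <- i + 2L }
    } else { pos <- c(pos, a); i <- i + 1L }
  }
  get <- function(key, default = NULL) {
    if (!is.null(opt[[key]])) opt[[key]] else default
  }
  num <- function(key, default) as.numeric(get(key, default))
  res <- tryCatch(switch(cmd,
    "sample" = {
      pot <- toy_potential(get("potential", "morse_exchange_abc"))
      ds <- sample_training_set(pot, n_path = as.integer(num("n-path", 100)),
                                n_compressed = as.integer(num("n-compressed", 0)),
                                seed = as.integer(num("seed", 1)))
      write_xyz(ds, get("out", "training.xyz"))
      message("wrote ", length(ds$records), " configurations")
      0L
    },
    "train" = {
      ds <- read_xyz(get("data"), as = "configuration_set")
      cfg <- training_config(max_epochs = as.integer(num("epochs", 4000)),
                             seed = as.integer(num("seed", 1)))
      model <- train_surrogate(ds, cfg)
      out <- get("out", "model.ckpt.json")
      save_surrogate(model, out)
      message("checkpoint written to ", out)
      0L
    },
    "opt-ts" = {
      pot <- .resolve_potential(get("potential", "mueller_brown_2d"))
      guess <- read_xyz(pos[1])[[1]]
      cfg <- saddle_config(radius_init = num("trust0", 0.1),
                           g_tol = num("gtol", 1e-6),
                           max_steps = as.integer(num("max-steps", 1000)))
      mode <- if (identical(get("hessian", "full"), "qn")) "qn"
              else "exact_every_step"
      fit <- optimize_saddle(pot, guess, mode, cfg)
      prefix <- get("out", "opt_ts")
      jsonlite::write_json(list(
        provenance = .provenance(list(command = "opt-ts", options = opt)),
        converged = fit$converged, energy = fit$energy,
        n_negative = fit$n_negative, counts = fit$counts,
        termination_reason = fit$termination_reason),
        paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
      write_xyz(lapply(fit$trace_frames, function(f)
        geometry(guess$elements, f, masses = guess$masses)),
        paste0(prefix, "_trajectory.xyz"), energies = fit$trace$energy)
      message(if (fit$converged) "converged" else "NOT converged",
              " in ", fit$counts$steps, " steps; results at ", prefix, ".*")
      if (fit$converged) 0L else 1L
    },
    "irc" = {
      pot <- .resolve_potential(get("potential", "mueller_brown_2d"))
      ts <- read_xyz(pos[1])[[1]]
      irc <- follow_irc(pot, ts, trust = num("trust", 0.1))
      prefix <- get("out", "irc")
      write_irc_xyz(irc$forward, paste0(prefix, "_forward.xyz"))
      write_irc_xyz(irc$backward, paste0(prefix, "_backward.xyz"))
      message("IRC branches written to ", prefix, "_{forward,backward}.xyz")
      0L
    },
    "classify" = {
      pot <- .resolve_potential(get("potential"))
      ts <- read_xyz(pos[1])[[1]]
      irc <- follow_irc(pot, ts)
      cls <- classify_outcome(irc, read_xyz(get("reactant"))[[1]],
                              read_xyz(get("product"))[[1]])
      cat(jsonlite::toJSON(cls, auto_unbox = TRUE), "\n")
      0L
    },
    "bench" = {
      modes <- strsplit(get("modes", "full,qn"), ",")[[1]]
      noise <- as.numeric(strsplit(get("noise", "0,10,20,30,50"), ",")[[1]])
      suite <- toy_benchmark_suite()
      rep <- run_benchmark(suite, modes = modes, noise_grid = noise,
                           n_seeds = as.integer(num("seeds", 5)),
                           seed = as.integer(num("seed", 1)))
      prefix <- get("out", "bench")
      utils::write.csv(rep$records, paste0(prefix, "_records.csv"),
                       row.names = FALSE)
      ag <- benchmark_aggregates(rep)
      utils::write.csv(ag$success_rate, paste0(prefix, "_robustness.csv"),
                       row.names = FALSE)
      jsonlite::write_json(list(
        provenance = .provenance(list(command = "bench", options = opt)),
        aggregates = ag), paste0(prefix, "_report.json"),
        auto_unbox = TRUE, digits = NA)
      message("benchmark report written to ", prefix, "_*")
      0L
    },
    "compare-hessian" = {
      cmpn <- compare_hessians(read_hessian(pos[1]), read_hessian(pos[2]))
      out <- get("out")
      js <- jsonlite::toJSON(unclass(cmpn), auto_unbox = TRUE, digits = NA)
      if (is.null(out)) cat(js, "\n") else writeLines(js, out)
      0L
    },
    { message("unknown command: ", cmd, "\n", usage); 2L }),
    error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(res)
}
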
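#' Default run configuration
#'
#' Nested list of the task, network and training defaults (n_t = 1000,
#' sigma_n = 0.001, fs = 8000 Hz, N_h = 100, N_FB = 4, tau = 100,
#' sigma_m_sq = 0.2, batch_size = 32, learning rate 1e-3, ...).
#' @export
default_config <- function() {
  list(
    task = list(n_s = 2, n_t = 1000, sigma_n = 0.001, fs = 8000,
                det_threshold = 0.2, waveform = "chord",
                freqs = list(c(100, 125), c(150, 210))),
    network = list(model = "simple", n_hidden = 100, input_mode = "x_and_y",
                   tau = NULL, N_z = 100, N_FB = 4, sigma_m_sq = 0.2,
                   N_L = 40, N_H = 100, N_I = 20),
    training = list(batch_size = 32, n_batches = 10000, learning_rate = 1e-3,
                    lambda_out = 1e-5, clip = 1, bank_length = 16000),
    protocol = list(n_contexts = 20),
    seed = NULL
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults) && !identical(key, "seed"))
      stop("unknown configuration key '", full, "'", call. = FALSE)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        is.list(user[[key]])) {
      defaults[key] <- list(merge_config(defaults[[key]], user[[key]], full))
    } else {
      defaults[key] <- list(user[[key]])  # keeps explicit NULLs (e.g. tau)
    }
  }
  defaults
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file, checks every key against the known configuration schema
#' (unknown keys are rejected with the offending key named) and fills missing
#' entries from [default_config()].
#' @param path YAML file.
#' @param require_seed error when no seed is given (training runs need one).
#' @export
load_config <- function(path, require_seed = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- merge_config(default_config(), user %||% list())
  if (require_seed && is.null(cfg$seed))
    stop("configuration key 'seed' is required for training runs", call. = FALSE)
  cfg
}

#' Serialise a network to JSON
#'
#' Writes all parameters, dimensions and hyperparameters of a network to a
#' single JSON file at full double precision; [read_network()] restores it.
#' @param net a [modulated_network()].
#' @param path output file.
#' @export
write_network <- function(net, path) {
  obj <- list(architecture = net$architecture, dims = net$dims,
              tau = net$tau, input_mode = net$input_mode,
              N_FB = net$N_FB, sigma_m_sq = net$sigma_m_sq,
              params = lapply(net$params, function(p)
                list(dim = dim(p) %||% length(p), data = as.numeric(p))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Restore a network written by [write_network()]
#' @param path JSON file.
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(obj$params, function(p) {
    d <- unlist(p$dim)
    if (length(d) == 2) matrix(p$data, d[1], d[2]) else as.numeric(p$data)
  })
  structure(list(architecture = obj$architecture,
                 dims = lapply(obj$dims, function(d) as.integer(d)),
                 params = params,
                 tau = obj$tau, input_mode = obj$input_mode,
                 N_FB = obj$N_FB, sigma_m_sq = obj$sigma_m_sq),
            class = "modulated_network")
}

#' Run the full pipeline from a configuration
#'
#' Dispatches generate -> train -> evaluate -> analyse and writes a
#' self-describing result bundle: the resolved configuration snapshot
#' (`config.yaml`), the training history (`history.csv`), per-context metrics
#' (`metrics.csv`), the trained network (`network.json`) and a plain-text log.
#' Identical configuration and seed reproduce identical metric files.
#'
#' @param config a configuration list (see [default_config()]) or a path to a
#'   YAML file.
#' @param out_dir output directory (created if needed).
#' @param dry_run validate the configuration and write nothing.
#' @return invisibly, the list of result paths (or the resolved config for a
#'   dry run).
#' @export
run_pipeline <- function(config, out_dir = NULL, dry_run = FALSE) {
  if (is.character(config)) config <- load_config(config, require_seed = !dry_run)
  else config <- merge_config(default_config(), config)
  if (dry_run) return(invisible(config))
  if (is.null(config$seed)) stop("a seed is required", call. = FALSE)
  if (is.null(out_dir)) stop("out_dir is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "log.txt")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                               append = TRUE)
  set.seed(config$seed)
  logline("seed %d | model %s | started %s", config$seed,
          config$network$model, format(Sys.time()))

  nw <- config$network
  net <- modulated_network(nw$model, n_s = config$task$n_s,
                           n_hidden = nw$n_hidden, input_mode = nw$input_mode,
                           tau = nw$tau, N_z = nw$N_z, N_FB = nw$N_FB,
                           sigma_m_sq = nw$sigma_m_sq, N_L = nw$N_L,
                           N_H = nw$N_H, N_I = nw$N_I)
  tc <- config$training
  cfg <- training_config(batch_size = tc$batch_size, n_batches = tc$n_batches,
                         learning_rate = tc$learning_rate,
                         lambda_out = tc$lambda_out, clip = tc$clip,
                         n_t = config$task$n_t, bank_length = tc$bank_length,
                         sigma_n = config$task$sigma_n,
                         det_threshold = config$task$det_threshold)
  t0 <- Sys.time()
  fit <- train_modulator(net, cfg)
  logline("training: %d batches in %.1f s, final loss %.5f", cfg$n_batches,
          as.numeric(difftime(Sys.time(), t0, units = "secs")),
          tail(fit$history$loss, 1))
  ev <- evaluate_model(fit$net, config$protocol$n_contexts, config$task$n_t,
                       config$task$sigma_n)
  logline("evaluation: mean clarity y = %.3f, x = %.3f",
          mean(ev$metrics$clarity_y), mean(ev$metrics$clarity_x))

  paths <- list(
    config = file.path(out_dir, "config.yaml"),
    history = file.path(out_dir, "history.csv"),
    metrics = file.path(out_dir, "metrics.csv"),
    network = file.path(out_dir, "network.json"),
    log = logf
  )
  yaml::write_yaml(config, paths$config)
  write.csv(fit$history, paths$history, row.names = FALSE)
  write.csv(ev$metrics, paths$metrics, row.names = FALSE)
  write_network(fit$net, paths$network)
  invisible(paths)
}

#' Write the canonical small fixtures
#'
#' Generates the plain-text fixtures the test-suite and examples use: a
#' 2000-sample chord source bank (CSV), six accepted mixing matrices (CSV), a
#' micro pre-trained simple model (JSON) and the 272-context grid (CSV). All
#' randomness derives from `seed`, so regeneration is reproducible.
#' @param dir output directory.
#' @param seed integer seed.
#' @export
make_fixtures <- function(dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  bank <- generate_sources("chord", T_samples = 2000)
  write.csv(data.frame(s1 = bank$samples[, 1], s2 = bank$samples[, 2]),
            file.path(dir, "chord_bank.csv"), row.names = FALSE)
  mats <- replicate(6, sample_mixing_matrix(2), simplify = FALSE)
  write.csv(do.call(rbind, lapply(seq_along(mats), function(i)
    data.frame(id = i, a11 = mats[[i]][1, 1], a12 = mats[[i]][1, 2],
               a21 = mats[[i]][2, 1], a22 = mats[[i]][2, 2]))),
    file.path(dir, "mixing_matrices.csv"), row.names = FALSE)
  grid <- context_grid(20, 0.2)
  write.csv(grid$vars, file.path(dir, "context_grid.csv"), row.names = FALSE)
  net <- modulated_network("simple", n_hidden = 16)
  fit <- train_modulator(net, training_config(n_batches = 50, n_t = 200,
                                              bank_length = 2000))
  write_network(fit$net, file.path(dir, "micro_simple_model.json"))
  invisible(dir)
}
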
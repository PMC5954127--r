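#' Log-spaced weight grid
#'
#' @param n number of grid points.
#' @param lo_exp,hi_exp base-10 exponents of the end points.  The default
#'   `(32, -2, 3)` is the full study grid of 32 log-spaced weights between
#'   10^-2 and 10^3.
#' @return numeric vector of weights.
#' @export
weight_grid <- function(n = 32, lo_exp = -2, hi_exp = 3) {
  10^seq(lo_exp, hi_exp, length.out = n)
}

# Deterministic per-cell seed derived from the master seed and cell indices.
# Distinct cells get distinct streams; the same master seed always yields
# the same table.  Kept below 2^31 - 1.
derive_seed <- function(master, ...) {
  idx <- c(...)
  h <- as.double(master) %% 2147483647
  for (v in idx) h <- (h * 69069 + as.double(v) * 2654435 + 1013904223) %% 2147483647
  as.integer(h)
}

#' Experiment configuration
#'
#' Bundles the field configuration, the model configuration, and the sweep
#' grid (weights, group sizes, noise levels, replicates) into one validated
#' object, as read from / written to YAML.
#'
#' @param field a [field_config()].
#' @param model a [model_config()].
#' @param weights weight grid (vector), or a list
#'   `list(n =, lo_exp =, hi_exp =)` passed to [weight_grid()].
#' @param sizes group sizes N.
#' @param etas noise levels.
#' @param replicates replicates per cell.
#' @param master_seed master seed from which all per-cell seeds derive.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(field = field_config(), model = model_config(),
                              weights = list(n = 32, lo_exp = -2, hi_exp = 3),
                              sizes = c(8, 16, 32, 64, 128, 256),
                              etas = c(0.10, 0.25, 0.40),
                              replicates = 20, master_seed = 1L) {
  if (is.list(weights)) {
    weights <- if (!is.null(weights$n))
      weight_grid(weights$n, weights$lo_exp, weights$hi_exp)
    else as.numeric(unlist(weights))
  }
  cfg <- list(field = field, model = model, weights = weights,
              sizes = as.integer(sizes), etas = etas,
              replicates = as.integer(replicates),
              master_seed = as.integer(master_seed))
  class(cfg) <- "experiment_config"
  validate_experiment_config(cfg)
  cfg
}

validate_experiment_config <- function(cfg) {
  validate_field_config(cfg$field)
  validate_model_config(cfg$model)
  if (length(cfg$weights) < 1 || any(cfg$weights < 0))
    stop("experiment config: weights must be non-negative")
  if (any(cfg$sizes < 1)) stop("experiment config: sizes must be >= 1")
  if (any(cfg$etas < 0 | cfg$etas > 1))
    stop("experiment config: noise levels must lie in [0, 1]")
  if (cfg$replicates < 1) stop("experiment config: replicates must be >= 1")
  invisible(cfg)
}

#' Expand a sweep into its full factorial job table
#'
#' One row per (weight, size, eta, replicate) cell, with a deterministic
#' per-cell simulation seed and a per-(eta, replicate) field seed (replicates
#' see different light fields; all cells of one replicate share its field, so
#' weights and sizes are compared on identical stimuli).
#'
#' @param config an [experiment_config()].
#' @return a `data.frame` with `w`, `N`, `eta`, `replicate`, `seed`,
#'   `field_seed`.
#' @export
expand_sweep <- function(config) {
  validate_experiment_config(config)
  grid <- expand.grid(iw = seq_along(config$weights),
                      iN = seq_along(config$sizes),
                      ieta = seq_along(config$etas),
                      replicate = seq_len(config$replicates))
  data.frame(
    w = config$weights[grid$iw],
    N = config$sizes[grid$iN],
    eta = config$etas[grid$ieta],
    replicate = grid$replicate,
    seed = mapply(function(a, b, c, d)
      derive_seed(config$master_seed, 1L, a, b, c, d),
      grid$iw, grid$iN, grid$ieta, grid$replicate),
    field_seed = mapply(function(c, d)
      derive_seed(config$master_seed, 2L, c, d),
      grid$ieta, grid$replicate))
}

#' Read / write an experiment configuration as YAML
#'
#' Unknown keys are rejected; missing keys fall back to the defaults of
#' [field_config()], [model_config()], [social_params()] and
#' [experiment_config()].  An empty file therefore yields the full default
#' configuration.
#'
#' @param path YAML file path.
#' @param config an [experiment_config()] (for writing).
#' @return `read_experiment_config` returns an `experiment_config`;
#'   `write_experiment_config` returns `path` invisibly.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  build_config_from_list(raw)
}

build_config_from_list <- function(raw) {
  take <- function(lst, fn, extra = list()) {
    if (is.null(lst)) lst <- list()
    known <- names(formals(fn))
    bad <- setdiff(names(lst), known)
    if (length(bad))
      stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
    do.call(fn, c(lst, extra))
  }
  top_known <- c("field", "model", "social", "weights", "sizes", "etas",
                 "replicates", "master_seed")
  bad <- setdiff(names(raw), top_known)
  if (length(bad))
    stop("unknown configuration section(s): ", paste(bad, collapse = ", "))
  social <- take(raw$social, social_params)
  model_args <- raw$model
  if (is.null(model_args)) model_args <- list()
  model <- take(model_args, model_config, list(social = social))
  field <- take(raw$field, field_config)
  args <- raw[intersect(names(raw), c("weights", "sizes", "etas",
                                      "replicates", "master_seed"))]
  do.call(experiment_config, c(list(field = field, model = model), args))
}

#' @rdname read_experiment_config
#' @export
write_experiment_config <- function(config, path) {
  validate_experiment_config(config)
  model <- unclass(config$model)
  social <- unclass(model$social)
  model$social <- NULL
  yaml::write_yaml(list(field = unclass(config$field), model = model,
                        social = social,
                        weights = as.numeric(config$weights),
                        sizes = as.integer(config$sizes),
                        etas = as.numeric(config$etas),
                        replicates = config$replicates,
                        master_seed = config$master_seed),
                   path, precision = 15)
  invisible(path)
}

#' Run a full sweep of school simulations
#'
#' For every replicate and noise level, generates one light-field sequence
#' (its own derived seed), then runs the school model for every (weight,
#' size) cell on that field and computes the per-run gradient-tracking
#' performance and mean nearest-neighbour distance.  Fields are generated
#' per replicate and discarded, so memory stays bounded.
#'
#' @param config an [experiment_config()].  `config$field$duration_s` must
#'   cover `config$model$steps * dt`.
#' @param progress print one line per replicate/eta block.
#' @return tidy `data.frame` with one row per run: `w`, `N`, `eta`,
#'   `replicate`, `seed`, `field_seed`, `psi`, `psi_null`, `Psi`, `d_nn`
#'   (cm), `d_nn_bl`.
#' @export
run_sweep <- function(config, progress = FALSE) {
  jobs <- expand_sweep(config)
  out <- vector("list", nrow(jobs))
  blocks <- split(seq_len(nrow(jobs)), jobs$field_seed[seq_len(nrow(jobs))])
  for (b in blocks) {
    fcfg <- config$field
    fcfg$seed <- jobs$field_seed[b[1]]
    fcfg$noise_level <- jobs$eta[b[1]]
    if (progress)
      message(sprintf("field seed %d (eta = %.2f): %d runs",
                      fcfg$seed, fcfg$noise_level, length(b)))
    fs <- field_sequence(fcfg, keep_frames = TRUE)
    for (k in b) {
      mcfg <- config$model
      mcfg$n_agents <- jobs$N[k]
      mcfg$w <- jobs$w[k]
      mcfg$seed <- jobs$seed[k]
      traj <- run_simulation(mcfg, fs)
      perf <- performance(traj, fs)
      dnn <- nearest_neighbour_distance(traj)
      out[[k]] <- data.frame(
        w = jobs$w[k], N = jobs$N[k], eta = jobs$eta[k],
        replicate = jobs$replicate[k], seed = jobs$seed[k],
        field_seed = jobs$field_seed[k],
        psi = perf$psi, psi_null = perf$psi_null, Psi = perf$Psi,
        d_nn = dnn, d_nn_bl = dnn / mcfg$body_length_cm)
    }
    rm(fs)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
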
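#' Save a Competitive Perceptron model as JSON
#'
#' The model (input coding, weights, autapses, shifts, slope, velocity,
#' inhibition gain, class map and training configuration) is written as a
#' versioned JSON document with 17 significant digits, so that
#' save -> load -> save yields byte-identical files and numeric fields
#' round-trip exactly.
#'
#' @param model A trained `cp_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_cp_model <- function(model, path) {
  stopifnot(inherits(model, "cp_model"))
  cfg <- model$config
  doc <- list(
    schema_version = model_schema_version(),
    mode = model$mode,
    n_inputs = model$n_inputs,
    coding = list(complement = model$coding$complement,
                  normalize = model$coding$normalize, eps = model$coding$eps),
    weights = unname(model$layer$weights),
    autapse = model$layer$autapse,
    shifts = model$layer$shifts,
    k = model$layer$k, nu = model$layer$nu, g = model$layer$g,
    theta_fire = model$layer$theta_fire,
    class_map = model$class_map,
    config = list(n_neurons = cfg$n_neurons, mode = cfg$mode, eta = cfg$eta,
                  nu = cfg$nu, k = cfg$k, g = cfg$g, epochs = cfg$epochs,
                  seed = cfg$seed, max_steps = cfg$max_steps,
                  theta_fire = cfg$theta_fire,
                  init_weight_max = cfg$init_weight_max,
                  init_shift = cfg$init_shift, autapse_init = cfg$autapse_init,
                  shuffle = cfg$shuffle, amp = cfg$amp, amp_eps = cfg$amp_eps,
                  amp_clip = cfg$amp_clip, predict_adapt = cfg$predict_adapt))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

model_schema_version <- function() "1"

#' Read a Competitive Perceptron model from JSON
#'
#' @param path Path to a file written by [save_cp_model()].
#' @return A `cp_model`.
#' @export
read_cp_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$schema_version) ||
      !identical(as.character(doc$schema_version), model_schema_version()))
    stop("unsupported model schema_version: ", doc$schema_version)
  coding <- input_coding(complement = doc$coding$complement,
                         normalize = doc$coding$normalize,
                         eps = doc$coding$eps)
  cfgl <- doc$config
  config <- cp_config(n_neurons = cfgl$n_neurons, mode = cfgl$mode,
                      eta = cfgl$eta, nu = cfgl$nu, k = cfgl$k, g = cfgl$g,
                      epochs = cfgl$epochs, seed = cfgl$seed,
                      max_steps = cfgl$max_steps, theta_fire = cfgl$theta_fire,
                      coding = coding, init_weight_max = cfgl$init_weight_max,
                      init_shift = cfgl$init_shift,
                      autapse_init = cfgl$autapse_init, shuffle = cfgl$shuffle,
                      amp = cfgl$amp, amp_eps = cfgl$amp_eps,
                      amp_clip = cfgl$amp_clip,
                      predict_adapt = cfgl$predict_adapt)
  w <- as.matrix(doc$weights)
  dimnames(w) <- NULL
  layer <- competitive_layer(weights = w,
                             autapse = doc$autapse, g = doc$g,
                             shifts = doc$shifts, k = doc$k, nu = doc$nu,
                             theta_fire = doc$theta_fire)
  structure(list(coding = coding, layer = layer, class_map = doc$class_map,
                 mode = doc$mode, config = config, n_inputs = doc$n_inputs),
            class = "cp_model")
}

#' Export a settling or training trace as CSV
#'
#' Settling traces export one row per (step, neuron) with the net input,
#' output and shift; training traces (data frames from [cp_train()]) are
#' written as-is. Floats use 17 significant digits.
#'
#' @param trace A `settle_trace` or a training trace `data.frame`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- if (inherits(trace, "settle_trace")) as.data.frame(trace) else
    as.data.frame(trace)
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], fmt17)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Run-configuration JSON (CLI)

run_config_keys <- c("schema_version", "mode", "neurons", "eta", "nu", "k",
                     "g", "epochs", "seed", "max_steps", "theta_fire",
                     "complement", "normalize", "eps", "init_weight_max",
                     "init_shift", "autapse_init", "shuffle", "amp",
                     "amp_eps", "amp_clip", "predict_adapt")

#' Validate a run configuration list
#'
#' Checks a configuration (e.g. parsed from the CLI's `--config` JSON)
#' against the published key set (see `inst/schema/run-config-schema.json`):
#' unknown keys are rejected and basic types/domains are enforced before
#' any run.
#'
#' @param cfg Named list of configuration values.
#' @return The validated list, invisibly; errors otherwise.
#' @export
validate_run_config <- function(cfg) {
  if (!is.list(cfg)) stop("configuration must be a JSON object")
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  num_keys <- c("eta", "nu", "k", "g", "eps", "theta_fire", "init_weight_max",
                "init_shift", "autapse_init", "amp_eps")
  for (key in intersect(names(cfg), num_keys))
    if (!is.numeric(cfg[[key]]) || length(cfg[[key]]) != 1)
      stop("configuration key '", key, "' must be a single number")
  for (key in intersect(names(cfg), c("neurons", "epochs", "seed", "max_steps")))
    if (!is.numeric(cfg[[key]]) || cfg[[key]] != round(cfg[[key]]))
      stop("configuration key '", key, "' must be an integer")
  for (key in intersect(names(cfg), c("complement", "normalize", "shuffle",
                                      "amp", "predict_adapt")))
    if (!is.logical(cfg[[key]]))
      stop("configuration key '", key, "' must be true/false")
  if (!is.null(cfg$mode) && !cfg$mode %in% c("supervised", "unsupervised"))
    stop("configuration key 'mode' must be 'supervised' or 'unsupervised'")
  invisible(cfg)
}

# build a cp_config from a validated run-config list (defaults from cp_config)
config_from_run <- function(cfg) {
  validate_run_config(cfg)
  coding <- input_coding(
    complement = if (is.null(cfg$complement)) TRUE else cfg$complement,
    normalize = if (is.null(cfg$normalize)) TRUE else cfg$normalize,
    eps = if (is.null(cfg$eps)) 1e-6 else cfg$eps)
  args <- cfg[setdiff(names(cfg), c("schema_version", "complement",
                                    "normalize", "eps", "neurons"))]
  if (!is.null(cfg$neurons)) args$n_neurons <- cfg$neurons
  args$coding <- coding
  do.call(cp_config, args)
}
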
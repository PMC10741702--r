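#' Configuration for the simplified koniocortex-like network
#'
#' The koniocortex-like network (KLN) prepends two biologically motivated
#' preprocessing stages to a competitive layer with autapses:
#' thalamocortical (TC) neurons, one per input component, whose intrinsic
#' plasticity tracks the mean of each input channel; and a shunting basket
#' stage that divisively normalizes the drive to the competitive (spiny
#' stellate) neurons by the summed TC activity. Basket-cell inhibition is
#' modelled as the competitive layer's fixed inhibition gain (inhibitory
#' synapses are non-modifiable), not as separate units.
#'
#' @param n_inputs Input dimensionality (TC neuron count). The classical
#'   sizing of the architecture (15 inputs, 10 competitive neurons) is the
#'   default preset.
#' @param n_neurons Number of competitive (S) neurons.
#' @param tc_k TC sigmoid compression factor. TC neurons are graded (default
#'   4), unlike the near-binary competitive neurons: a steep TC sigmoid
#'   would discard the amplitude information the mean-tracking shift needs.
#' @param tc_nu TC intrinsic-plasticity velocity.
#' @param tc_init_shift Initial TC shift.
#' @param sb_eps Guard added to the summed TC activity in the shunting
#'   division.
#' @param tc_identity,sb_identity Replace the TC stage / shunting stage by
#'   the identity, reducing the KLN to a Competitive Perceptron without
#'   input coding (used to verify the reduction).
#' @param ... Passed to [cp_config()] (learning rate `eta`, velocity `nu`,
#'   slope `k`, inhibition `g`, `epochs`, `seed`, ...).
#' @return An object of class `kln_config`.
#' @export
kln_config <- function(n_inputs = 15, n_neurons = 10, tc_k = 4, tc_nu = 0.1,
                       tc_init_shift = 0.5, sb_eps = 1e-6,
                       tc_identity = FALSE, sb_identity = FALSE, ...) {
  stopifnot(n_inputs >= 1, tc_k > 0, tc_nu >= 0, sb_eps > 0)
  cp <- cp_config(n_neurons = n_neurons,
                  coding = input_coding(complement = FALSE, normalize = FALSE),
                  ...)
  structure(list(n_inputs = as.integer(n_inputs), cp = cp, tc_k = tc_k,
                 tc_nu = tc_nu, tc_init_shift = tc_init_shift,
                 sb_eps = sb_eps, tc_identity = isTRUE(tc_identity),
                 sb_identity = isTRUE(sb_identity)),
            class = "kln_config")
}

#' Thalamocortical preprocessing stage
#'
#' Each TC neuron applies its shifted sigmoid to one raw input component;
#' with `adapt = TRUE` its shift moves towards the produced output, so over
#' a stationary input stream each TC shift converges to the long-run mean
#' output of its channel (mean-component extraction by intrinsic
#' plasticity).
#'
#' @param model A `kln_model`.
#' @param x Raw input vector in \[0, 1\].
#' @param adapt Logical; update the TC shifts.
#' @return List with `outputs` (TC firing probabilities) and the (possibly
#'   updated) `model`.
#' @export
tc_forward <- function(model, x, adapt = FALSE) {
  stopifnot(inherits(model, "kln_model"))
  if (length(x) != model$n_inputs) stop("input dimension mismatch")
  check_unit(x, "x")
  if (model$tc_identity) return(list(outputs = as.numeric(x), model = model))
  O <- stats::plogis(model$tc_k * (x + 0.5 - 2 * model$tc_shifts))
  if (adapt)
    model$tc_shifts <- (model$tc_nu * O + model$tc_shifts) / (1 + model$tc_nu)
  list(outputs = O, model = model)
}

#' Shunting (divisive) normalization
#'
#' Net input of one competitive neuron after the basket stage: the weighted
#' TC drive divided by the summed TC activity,
#' `sum(w * tc) / (sum(tc) + eps)`. The result is bounded in \[0, 1\] for
#' weights in \[0, 1\] and invariant (up to `eps`) under positive rescaling
#' of the TC activity.
#'
#' @param tc_out Non-negative TC output vector.
#' @param weights Weight row of the target neuron, in \[0, 1\].
#' @param eps Positive guard for the division.
#' @return Normalized net input (scalar).
#' @export
shunting_normalize <- function(tc_out, weights, eps = 1e-6) {
  if (any(tc_out < 0) || anyNA(tc_out)) stop("'tc_out' must be non-negative")
  if (length(tc_out) != length(weights)) stop("dimension mismatch")
  check_unit(weights, "weights")
  sum(weights * tc_out) / (sum(tc_out) + eps)
}

# internal: effective input to the competitive layer (so that the layer's
# weighted sum equals the shunting-normalized net for every neuron row)
kln_effective_input <- function(model, tc_out) {
  if (model$sb_identity) tc_out
  else tc_out / (sum(tc_out) + model$sb_eps)
}

#' Train a koniocortex-like network
#'
#' As [cp_train()], with the TC stage plus shunting normalization replacing
#' the input coding: per presentation the TC neurons adapt and fire, their
#' normalized activity drives the competitive layer, which settles with
#' intrinsic plasticity, and the presynaptic rule updates the excitatory
#' and autapse weights of the competitive neurons only (basket inhibition
#' is fixed).
#'
#' @param data A [cp_dataset()] or pattern matrix.
#' @param config A [kln_config()].
#' @param labels Optional labels (supervised mode).
#' @return List with `model` (class `kln_model`) and `trace` (as in
#'   [cp_train()]).
#' @export
kln_train <- function(data, config, labels = NULL) {
  stopifnot(inherits(config, "kln_config"))
  if (inherits(data, "cp_dataset")) {
    if (is.null(labels)) labels <- data$labels
    patterns <- data$patterns
  } else patterns <- as.matrix(data)
  if (nrow(patterns) < 1) stop("'data' must contain at least one pattern")
  if (ncol(patterns) != config$n_inputs) stop("data/config dimension mismatch")
  cp <- config$cp
  supervised <- cp$mode == "supervised"
  if (supervised) {
    if (is.null(labels)) stop("supervised mode requires labels")
    classes <- sort(unique(labels))
    if (length(classes) != cp$n_neurons)
      stop("supervised mode needs exactly one neuron per class")
  }

  set.seed(cp$seed)
  layer <- competitive_layer(
    weights = matrix(stats::runif(cp$n_neurons * config$n_inputs, 0,
                                  cp$init_weight_max),
                     cp$n_neurons, config$n_inputs),
    autapse = rep(cp$autapse_init, cp$n_neurons),
    g = cp$g, shifts = rep(cp$init_shift, cp$n_neurons),
    k = cp$k, nu = cp$nu, theta_fire = cp$theta_fire)
  model <- structure(list(n_inputs = config$n_inputs,
                          tc_shifts = rep(config$tc_init_shift, config$n_inputs),
                          tc_k = config$tc_k, tc_nu = config$tc_nu,
                          sb_eps = config$sb_eps,
                          tc_identity = config$tc_identity,
                          sb_identity = config$sb_identity,
                          layer = layer, class_map = seq_len(cp$n_neurons),
                          mode = cp$mode, config = config),
                     class = "kln_model")

  n_pat <- nrow(patterns)
  total <- cp$epochs * n_pat
  trace <- data.frame(epoch = integer(total), presentation = integer(total),
                      pattern = integer(total), winner = integer(total),
                      steps = integer(total), converged = character(total),
                      stringsAsFactors = FALSE)
  winners_last <- integer(n_pat)
  pres <- 0L
  for (ep in seq_len(cp$epochs)) {
    ord <- if (cp$shuffle) sample.int(n_pat) else seq_len(n_pat)
    for (p in ord) {
      pres <- pres + 1L
      tc <- tc_forward(model, patterns[p, ], adapt = TRUE)
      model <- tc$model
      xe <- kln_effective_input(model, tc$outputs)
      st <- settle(model$layer, xe, cp$max_steps, adapt = TRUE)
      model$layer <- st$layer
      out <- st$outputs[st$steps, ]
      signal <- if (supervised) as.numeric(classes == labels[p]) else out
      for (j in seq_len(cp$n_neurons)) {
        model$layer$weights[j, ] <- presynaptic_update(model$layer$weights[j, ],
                                                       xe, signal[j], cp$eta)
        model$layer$autapse[j] <- presynaptic_update(model$layer$autapse[j],
                                                     out[j], signal[j], cp$eta)
      }
      trace[pres, ] <- list(ep, pres, p, st$winner, st$steps, st$converged)
      if (ep == cp$epochs) winners_last[p] <- st$winner
    }
  }
  model$class_map <- if (supervised) classes else
    majority_class_map(winners_last, labels, cp$n_neurons)
  list(model = model, trace = trace)
}

#' Predict with a trained koniocortex-like network
#'
#' @param model A trained `kln_model`.
#' @param x Raw input vector.
#' @param adapt Evaluation mode (default frozen; the model is never
#'   modified).
#' @return List with `class`, `winner` and the settling `trace`.
#' @export
kln_predict <- function(model, x, adapt = FALSE) {
  stopifnot(inherits(model, "kln_model"))
  tc <- tc_forward(model, x, adapt = adapt)
  xe <- kln_effective_input(tc$model, tc$outputs)
  st <- settle(tc$model$layer, xe, tc$model$config$cp$max_steps, adapt = adapt)
  list(class = model$class_map[st$winner], winner = st$winner, trace = st)
}

#' @export
print.kln_model <- function(x, ...) {
  cat(sprintf("<kln_model> %d TC inputs -> %d competitive neurons (%s)\n",
              x$n_inputs, nrow(x$layer$weights), x$mode))
  invisible(x)
}
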
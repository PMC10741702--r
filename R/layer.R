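#' Competitive layer with lateral inhibition
#'
#' A layer of shifted-sigmoid rate-coding neurons in which every neuron
#' laterally inhibits all others through fixed (non-learned) inhibitory
#' connections of gain `g`, and optionally excites itself through an autapse
#' (a recurrent positive connection). Winner-take-all behaviour is not
#' computed by an external argmax during the dynamics: it emerges from the
#' interplay of lateral inhibition and intrinsic plasticity while the layer
#' settles on an input ([settle()]).
#'
#' Excitatory and autapse weights are synaptic efficacies in \[0, 1\] and are
#' the only plastic connections (trained elsewhere by the presynaptic rule);
#' the inhibition gain is fixed by construction.
#'
#' @param weights `n_neurons x n_inputs` matrix of efficacies in \[0, 1\].
#' @param autapse Per-neuron self-excitation weights in \[0, 1\]
#'   (default 0 = no autapses).
#' @param g Positive lateral inhibition gain, fixed at 1 by default.
#' @param shifts Per-neuron initial sigmoid shifts in \[0, 1\].
#' @param k Sigmoid compression factor (shared; default 500, near-binary).
#' @param nu Intrinsic-plasticity velocity (shared).
#' @param theta_fire Firing criterion in (0.5, 1): a settled state counts as
#'   a winner-take-all firing when exactly one output is `>= theta_fire` and
#'   all others are `<= 1 - theta_fire`.
#' @return An object of class `competitive_layer`.
#' @export
competitive_layer <- function(weights, autapse = rep(0, nrow(weights)),
                              g = 1, shifts = rep(0.5, nrow(weights)),
                              k = 500, nu = 0.1, theta_fire = 0.9) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  check_unit(weights, "weights")
  check_unit(autapse, "autapse")
  check_unit(shifts, "shifts")
  stopifnot(length(autapse) == n, length(shifts) == n)
  if (g <= 0) stop("'g' must be positive")
  if (k <= 0) stop("'k' must be positive")
  if (nu < 0) stop("'nu' must be non-negative")
  if (theta_fire <= 0.5 || theta_fire >= 1) stop("'theta_fire' must lie in (0.5, 1)")
  structure(list(weights = weights, autapse = as.numeric(autapse), g = g,
                 shifts = as.numeric(shifts), k = k, nu = nu,
                 theta_fire = theta_fire),
            class = "competitive_layer")
}

#' @export
print.competitive_layer <- function(x, ...) {
  cat(sprintf("<competitive_layer> %d neurons, %d inputs, g = %g, k = %g, nu = %g\n",
              nrow(x$weights), ncol(x$weights), x$g, x$k, x$nu))
  invisible(x)
}

#' Extract one neuron of a layer as a `neuron_state`
#'
#' @param layer A [competitive_layer()].
#' @param j Neuron index (1-based).
#' @param last_output Optional last output to record.
#' @return A [neuron_state()].
#' @export
layer_neuron <- function(layer, j, last_output = 0) {
  stopifnot(inherits(layer, "competitive_layer"))
  neuron_state(shift = layer$shifts[j], k = layer$k, nu = layer$nu,
               last_output = last_output)
}

#' One synchronous step of the lateral-inhibition dynamics
#'
#' For each neuron `j` the net input is the weighted feedforward drive plus
#' the autaptic self-excitation minus the pooled lateral inhibition:
#' `net_j = sum_i w_ji x_i + a_j prev_out_j - g * sum_{m != j} prev_out_m`.
#' All nets use the previous step's outputs (synchronous update), then every
#' neuron activates through its shifted sigmoid; with `adapt = TRUE` each
#' shift is moved towards the produced output (intrinsic plasticity).
#'
#' @param layer A [competitive_layer()].
#' @param x Input vector in \[0, 1\], length `ncol(layer$weights)`.
#' @param prev_out Previous outputs, length `nrow(layer$weights)`.
#' @param adapt Logical; update the shifts from the produced outputs.
#' @return List with `outputs` (new firing probabilities), `nets`, and the
#'   (possibly shift-updated) `layer`.
#' @export
layer_step <- function(layer, x, prev_out, adapt = FALSE) {
  stopifnot(inherits(layer, "competitive_layer"))
  if (length(x) != ncol(layer$weights)) stop("input dimension mismatch")
  if (length(prev_out) != nrow(layer$weights)) stop("'prev_out' dimension mismatch")
  nets <- as.numeric(layer$weights %*% x) +
    layer$autapse * prev_out - layer$g * (sum(prev_out) - prev_out)
  O <- stats::plogis(layer$k * (nets + 0.5 - 2 * layer$shifts))
  if (adapt)
    layer$shifts <- (layer$nu * O + layer$shifts) / (1 + layer$nu)
  list(outputs = O, nets = nets, layer = layer)
}

#' Settle the layer on an input until a winner emerges
#'
#' Iterates [layer_step()] from a silent state (`prev_out = 0`) until either
#' exactly one neuron fires (output `>= theta_fire` with all others
#' `<= 1 - theta_fire`), the outputs stagnate (maximal change below 1e-9),
#' or `max_steps` is reached. With `adapt = TRUE` the neurons' sigmoids
#' shift while settling: a silent layer drifts leftwards until its most
#' driven neuron fires, and a winning neuron drifts rightwards, which is
#' what rotates winners over time (homeostatic competition).
#'
#' The winner is read with [wta_winner()] from the final nets and (post-
#' update) thresholds. Non-convergence is reported in the trace, not raised.
#'
#' @param layer A [competitive_layer()].
#' @param x Input vector in \[0, 1\].
#' @param max_steps Maximum number of settling steps (>= 1).
#' @param adapt Logical; apply intrinsic plasticity during settling.
#' @return An object of class `settle_trace`: per-step matrices `outputs`,
#'   `nets`, `shifts` (one row per executed step), `winner` (1-based index),
#'   `steps`, `converged` (`"fired"`, `"stagnated"` or `"max_steps"`), and
#'   the final `layer`.
#' @export
settle <- function(layer, x, max_steps = 60, adapt = FALSE) {
  stopifnot(inherits(layer, "competitive_layer"), max_steps >= 1)
  n <- nrow(layer$weights)
  out <- rep(0, n)
  nets <- numeric(n)
  outputs_t <- matrix(NA_real_, max_steps, n)
  nets_t <- matrix(NA_real_, max_steps, n)
  shifts_t <- matrix(NA_real_, max_steps, n)
  converged <- "max_steps"
  steps <- max_steps
  for (t in seq_len(max_steps)) {
    prev_shifts <- layer$shifts
    st <- layer_step(layer, x, out, adapt = adapt)
    layer <- st$layer
    nets <- st$nets
    O <- st$outputs
    outputs_t[t, ] <- O
    nets_t[t, ] <- nets
    shifts_t[t, ] <- layer$shifts
    if (sum(O >= layer$theta_fire) == 1 &&
        sum(O <= 1 - layer$theta_fire) == n - 1) {
      out <- O; converged <- "fired"; steps <- t; break
    }
    # stagnation means the whole state is stable: outputs, and shifts too
    # when intrinsic plasticity is active (a silent layer keeps drifting)
    if (max(abs(O - out)) < 1e-9 &&
        (!adapt || max(abs(layer$shifts - prev_shifts)) < 1e-9)) {
      out <- O; converged <- "stagnated"; steps <- t; break
    }
    out <- O
  }
  thresholds <- 2 * layer$shifts - 0.5
  structure(list(outputs = outputs_t[seq_len(steps), , drop = FALSE],
                 nets = nets_t[seq_len(steps), , drop = FALSE],
                 shifts = shifts_t[seq_len(steps), , drop = FALSE],
                 winner = wta_winner(nets, thresholds),
                 steps = steps, converged = converged, layer = layer),
            class = "settle_trace")
}

#' Winner-take-all readout
#'
#' The plausible comparison between near-binary steep sigmoids is the total
#' excitation `net_j - T_j` (net input minus activation threshold) rather
#' than the outputs themselves, which saturate within machine precision of
#' one another. Returns the 1-based index of the maximal excitation; ties
#' break to the lowest index.
#'
#' @param nets Vector of net inputs.
#' @param thresholds Vector of activation thresholds, same length.
#' @return Winning neuron index (1-based).
#' @export
#' @examples
#' wta_winner(c(0.13, 0.07), c(0, 0))  # 1: the first neuron wins
wta_winner <- function(nets, thresholds) {
  if (length(nets) < 1) stop("'nets' must be non-empty")
  if (length(nets) != length(thresholds))
    stop("'nets' and 'thresholds' must have the same length")
  which.max(nets - thresholds)
}

#' @export
print.settle_trace <- function(x, ...) {
  cat(sprintf("<settle_trace> %d steps (%s), winner = %d\n",
              x$steps, x$converged, x$winner))
  invisible(x)
}

#' @export
as.data.frame.settle_trace <- function(x, ...) {
  n <- ncol(x$outputs)
  data.frame(step = rep(seq_len(x$steps), each = n),
             neuron = rep(seq_len(n), times = x$steps),
             net = as.numeric(t(x$nets)),
             output = as.numeric(t(x$outputs)),
             shift = as.numeric(t(x$shifts)))
}
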
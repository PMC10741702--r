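#' Rate-coding neuron state
#'
#' A rate-coding neuron is described by the position (`shift`) and slope (`k`)
#' of its sigmoidal activation function, the velocity `nu` of its homeostatic
#' shift adaptation (intrinsic plasticity), and its last output (a firing
#' probability). The activation threshold, the net input at which the neuron
#' fires with probability 1/2, is the derived quantity `T = 2 s - 0.5`.
#'
#' Intrinsic plasticity moves the sigmoid rightwards after high activity and
#' leftwards after low activity, so very active neurons moderate their firing
#' and silent neurons become excitable. The shift always stays in \[0, 1\]
#' because each update is a convex combination of the current shift and the
#' current output (see [update_shift()]).
#'
#' @param shift Position of the sigmoid, in \[0, 1\].
#' @param k Positive sigmoid compression factor; large `k` (e.g. the default
#'   500 used by the competitive networks) makes the activation near-binary.
#' @param nu Non-negative shift velocity; `nu = 0` freezes the shift.
#' @param last_output Last firing probability produced, in \[0, 1\].
#'
#' @return An object of class `neuron_state`.
#' @seealso [activate()], [threshold_of()], [update_shift()]
#' @export
#' @examples
#' n <- neuron_state(shift = 0.325)
#' threshold_of(n)  # 0.15
neuron_state <- function(shift = 0.5, k = 500, nu = 0.1, last_output = 0) {
  stopifnot(is.numeric(shift), length(shift) == 1, is.finite(shift))
  if (shift < 0 || shift > 1) stop("'shift' must lie in [0, 1]")
  if (!is.numeric(k) || length(k) != 1 || !is.finite(k) || k <= 0)
    stop("'k' must be a positive finite number")
  if (!is.numeric(nu) || length(nu) != 1 || !is.finite(nu) || nu < 0)
    stop("'nu' must be a non-negative finite number")
  if (!is.numeric(last_output) || last_output < 0 || last_output > 1)
    stop("'last_output' must lie in [0, 1]")
  structure(list(shift = shift, k = k, nu = nu, last_output = last_output),
            class = "neuron_state")
}

#' @export
print.neuron_state <- function(x, ...) {
  cat(sprintf("<neuron_state> s = %.4g (T = %.4g), k = %g, nu = %g, O = %.4g\n",
              x$shift, threshold_of(x), x$k, x$nu, x$last_output))
  invisible(x)
}

#' Net input of a neuron
#'
#' The net input is the sum of presynaptic firing probabilities weighted by
#' synaptic efficacies, `sum(w * x)`. Both efficacies and inputs are
#' probabilities in \[0, 1\], so the result lies in `[0, length(w)]`.
#'
#' @param weights Vector of synaptic efficacies in \[0, 1\].
#' @param inputs Vector of presynaptic firing probabilities in \[0, 1\],
#'   same length as `weights`.
#' @return The scalar net input.
#' @export
#' @examples
#' net_input(c(1, 1), c(0.5, 0.5))  # 1
net_input <- function(weights, inputs) {
  if (length(weights) != length(inputs))
    stop("'weights' and 'inputs' must have the same length")
  if (length(weights) < 1) stop("'weights' must have length >= 1")
  check_unit(weights, "weights")
  check_unit(inputs, "inputs")
  sum(weights * inputs)
}

#' Shifted-sigmoid activation
#'
#' Computes the firing probability `1 / (1 + exp(-k * (net + 0.5 - 2 s)))`.
#' The sigmoid crosses 1/2 exactly at the activation threshold
#' `T = 2 s - 0.5`, is strictly increasing in `net`, and is evaluated in a
#' numerically stable form (via [stats::plogis()]) so that steep slopes such
#' as `k = 500` never overflow.
#'
#' @param net Finite net input.
#' @param state A [neuron_state()].
#' @return Firing probability in \[0, 1\].
#' @export
#' @examples
#' activate(0.5, neuron_state(shift = 0.5))  # 0.5: net equals the threshold
activate <- function(net, state) {
  stopifnot(inherits(state, "neuron_state"))
  if (!is.numeric(net) || anyNA(net) || any(!is.finite(net)))
    stop("'net' must be finite")
  stats::plogis(state$k * (net + 0.5 - 2 * state$shift))
}

#' Activation threshold of a neuron
#'
#' The net input at which the activation equals 1/2: `T = 2 s - 0.5`,
#' always in \[-0.5, 1.5\].
#'
#' @param state A [neuron_state()].
#' @return The scalar threshold.
#' @export
threshold_of <- function(state) {
  stopifnot(inherits(state, "neuron_state"))
  2 * state$shift - 0.5
}

#' Intrinsic-plasticity shift update
#'
#' Moves the sigmoid position towards the produced output:
#' `s' = (nu * O + s) / (1 + nu)`, a convex combination of the current shift
#' and the output, so `s'` stays in \[0, 1\] and increases exactly when
#' `O > s`. Under constant output the shift converges geometrically to `O`
#' with ratio `1 / (1 + nu)`.
#'
#' @param state A [neuron_state()].
#' @param output Firing probability in \[0, 1\] just produced by the neuron.
#' @return The updated `neuron_state` (with `last_output` recorded).
#' @export
#' @examples
#' n <- neuron_state(shift = 0, nu = 1)
#' for (i in 1:3) n <- update_shift(n, 1)
#' n$shift  # 0.875 = 1 - 2^-3
update_shift <- function(state, output) {
  stopifnot(inherits(state, "neuron_state"))
  if (!is.numeric(output) || length(output) != 1 || is.na(output) ||
      output < 0 || output > 1)
    stop("'output' must lie in [0, 1]")
  state$shift <- (state$nu * output + state$shift) / (1 + state$nu)
  state$last_output <- output
  state
}

# internal: check all components lie in [0,1]
check_unit <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    stop(sprintf("all components of '%s' must lie in [0, 1]", name))
  invisible(x)
}
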
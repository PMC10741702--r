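#' Presynaptic (Grossberg-type) weight update
#'
#' Incremental probabilistic learning rule `w' = w + eta * I * (O - w)`,
#' where `I` and `O` are the presynaptic and postsynaptic firing
#' probabilities. The update only acts when the presynaptic neuron is active
#' and drives the weight towards the postsynaptic activity, so at
#' equilibrium the weight estimates the conditional probability that the
#' postsynaptic neuron fires given that the presynaptic one fired. Because
#' `w' = w * (1 - eta * I) + eta * I * O` is a convex combination, weights
#' remain in \[0, 1\], and updates shrink as `w` approaches `O` — the
#' metaplasticity property that already-adapted synapses change less.
#'
#' All arguments are vectorized (recycled to a common length).
#'
#' @param w Synaptic efficacy(ies) in \[0, 1\].
#' @param input Presynaptic firing probability(ies) in \[0, 1\].
#' @param output Postsynaptic firing probability(ies) in \[0, 1\].
#' @param eta Learning rate(s) in \[0, 1\].
#' @return Updated weight(s), guaranteed in \[0, 1\].
#' @export
#' @examples
#' presynaptic_update(0.2, input = 1, output = 1, eta = 0.5)  # 0.6
#' presynaptic_update(0.7, input = 0, output = 1, eta = 0.5)  # unchanged
presynaptic_update <- function(w, input, output, eta) {
  check_unit(w, "w")
  check_unit(input, "input")
  check_unit(output, "output")
  check_unit(eta, "eta")
  w + eta * input * (output - w)
}

#' Fit a pattern-frequency model for artificial metaplasticity
#'
#' Artificial metaplasticity (AMP) makes the learning rate depend on how
#' frequent the presented pattern is: rare patterns, which produced little
#' prior firing, induce larger weight changes. This fits an estimator of the
#' pattern probability `p(x)` over a training set, from which [amp_rate()]
#' derives an effective learning rate
#' `eta_eff = clip(eta0 * pbar / (eps + p(x)), eta0 * clip[1], eta0 * clip[2])`,
#' with `pbar` the mean estimated probability over the training patterns, so
#' that a uniform pattern distribution reduces AMP to the constant rate
#' `eta0`.
#'
#' Discrete pattern sets use an exact histogram keyed on the pattern values;
#' continuous ones use a product-Gaussian kernel density with Silverman's
#' rule-of-thumb bandwidth per dimension. `method = "auto"` picks the
#' histogram when every column takes at most 10 distinct values.
#'
#' @param patterns Numeric matrix, one pattern per row.
#' @param base_rate Base learning rate `eta0` in (0, 1\].
#' @param eps Floor added to the estimated probability (default `1e-3`).
#' @param clip Length-2 multiplier bounds on `eta0` (default `c(0.1, 10)`);
#'   use `c(1, 1)` for a constant-rate (plain backpropagation) model.
#' @param method `"auto"`, `"histogram"`, or `"kde"`.
#' @param bandwidth Optional per-dimension kernel bandwidth(s) for the KDE;
#'   default Silverman.
#' @return An object of class `amp_rate_model`.
#' @export
amp_rate_model <- function(patterns, base_rate = 0.1, eps = 1e-3,
                           clip = c(0.1, 10),
                           method = c("auto", "histogram", "kde"),
                           bandwidth = NULL) {
  patterns <- as.matrix(patterns)
  if (nrow(patterns) < 1) stop("need at least one pattern to fit")
  if (base_rate <= 0 || base_rate > 1) stop("'base_rate' must lie in (0, 1]")
  if (eps <= 0) stop("'eps' must be positive")
  if (length(clip) != 2 || clip[1] > clip[2] || clip[1] <= 0)
    stop("'clip' must be increasing positive bounds")
  method <- match.arg(method)
  if (method == "auto") {
    discrete <- all(apply(patterns, 2, function(col) length(unique(col)) <= 10))
    method <- if (discrete) "histogram" else "kde"
  }
  m <- list(base_rate = base_rate, eps = eps, clip = clip, method = method,
            patterns = patterns)
  if (method == "histogram") {
    key <- apply(patterns, 1, paste, collapse = "\r")
    tab <- table(key)
    m$freq <- as.numeric(tab) / nrow(patterns)
    names(m$freq) <- names(tab)
  } else {
    h <- bandwidth
    if (is.null(h)) {
      n <- nrow(patterns)
      h <- apply(patterns, 2, function(col)
        1.06 * max(stats::sd(col), 1e-3) * n^(-1 / 5))
    }
    m$bandwidth <- rep_len(h, ncol(patterns))
  }
  phat <- vapply(seq_len(nrow(patterns)),
                 function(i) amp_phat(m, patterns[i, ]), 0)
  m$pbar <- mean(phat)
  class(m) <- "amp_rate_model"
  m
}

# internal: estimated pattern probability (histogram mass or kernel density)
amp_phat <- function(model, pattern) {
  if (model$method == "histogram") {
    key <- paste(pattern, collapse = "\r")
    p <- model$freq[key]
    if (is.na(p)) 0 else unname(p)
  } else {
    z <- sweep(model$patterns, 2, pattern) # rows: x_i - x
    k <- exp(-0.5 * sweep(z^2, 2, model$bandwidth^2, "/"))
    k <- sweep(k, 2, model$bandwidth * sqrt(2 * pi), "/")
    mean(apply(k, 1, prod))
  }
}

#' Metaplastic learning rate for a pattern
#'
#' Effective learning rate under artificial metaplasticity: inversely
#' proportional to the estimated probability of the pattern (rarer patterns
#' learn more), normalized by the mean training-pattern probability and
#' clipped to `base_rate * clip`. Non-increasing in the estimated
#' probability.
#'
#' @param model A fitted [amp_rate_model()].
#' @param pattern Numeric input vector.
#' @return The effective learning rate (scalar).
#' @export
amp_rate <- function(model, pattern) {
  if (!inherits(model, "amp_rate_model")) stop("fit the model with amp_rate_model() first")
  phat <- amp_phat(model, as.numeric(pattern))
  eta <- model$base_rate * model$pbar / (model$eps + phat)
  min(max(eta, model$base_rate * model$clip[1]), model$base_rate * model$clip[2])
}

#' @export
print.amp_rate_model <- function(x, ...) {
  cat(sprintf("<amp_rate_model> %s estimator on %d patterns, eta0 = %g, clip = [%g, %g]\n",
              x$method, nrow(x$patterns), x$base_rate,
              x$clip[1] * x$base_rate, x$clip[2] * x$base_rate))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Minimal multilayer perceptron used to demonstrate AMP-modulated
# backpropagation. Logistic activations everywhere; error = mean squared
# error over output units.

#' Construct a small logistic multilayer perceptron
#'
#' @param sizes Integer vector of layer sizes, e.g. `c(2, 4, 1)`.
#' @param seed Seed for the uniform `U(-0.5, 0.5)` weight initialization.
#' @return An object of class `amp_mlp` with per-layer weight matrices
#'   (`n_out x n_in`) and bias vectors.
#' @export
amp_mlp <- function(sizes, seed) {
  stopifnot(length(sizes) >= 2, all(sizes >= 1))
  set.seed(seed)
  L <- length(sizes) - 1
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::runif(sizes[l + 1] * sizes[l], -0.5, 0.5),
                     sizes[l + 1], sizes[l])
    b[[l]] <- stats::runif(sizes[l + 1], -0.5, 0.5)
  }
  structure(list(sizes = sizes, W = W, b = b), class = "amp_mlp")
}

#' Forward pass of the demonstration MLP
#'
#' @param model An [amp_mlp()].
#' @param x Input vector matching the first layer size.
#' @return List with `output` (final activations, in \[0, 1\]) and
#'   `activations` (per-layer activations including the input).
#' @export
mlp_forward <- function(model, x) {
  stopifnot(inherits(model, "amp_mlp"))
  if (length(x) != model$sizes[1]) stop("input dimension mismatch")
  a <- list(as.numeric(x))
  for (l in seq_along(model$W))
    a[[l + 1]] <- stats::plogis(as.numeric(model$W[[l]] %*% a[[l]] + model$b[[l]]))
  list(output = a[[length(a)]], activations = a)
}

#' Gradient of the MLP mean-squared error
#'
#' Backpropagated gradient of `E = mean((output - target)^2)` with respect to
#' every weight and bias.
#'
#' @param model An [amp_mlp()].
#' @param x Input vector.
#' @param target Target output vector matching the last layer size.
#' @return List with per-layer gradient matrices `dW` and vectors `db`.
#' @export
mlp_gradient <- function(model, x, target) {
  stopifnot(inherits(model, "amp_mlp"))
  if (length(target) != utils::tail(model$sizes, 1)) stop("target dimension mismatch")
  fw <- mlp_forward(model, x)
  a <- fw$activations
  L <- length(model$W)
  n_out <- length(target)
  dW <- vector("list", L)
  db <- vector("list", L)
  # delta at output: dE/dz with E = mean((o - t)^2), o = plogis(z)
  delta <- (2 / n_out) * (a[[L + 1]] - as.numeric(target)) * a[[L + 1]] * (1 - a[[L + 1]])
  for (l in L:1) {
    dW[[l]] <- outer(delta, a[[l]])
    db[[l]] <- delta
    if (l > 1)
      delta <- as.numeric(crossprod(model$W[[l]], delta)) * a[[l]] * (1 - a[[l]])
  }
  list(dW = dW, db = db)
}

#' One (possibly metaplastic) backpropagation step
#'
#' Moves every weight by `-eta_eff * dE/dw`, where `eta_eff` is evaluated
#' once per pattern presentation from the AMP rate model. With a
#' constant-rate model (`clip = c(1, 1)` or `rates = NULL` and a plain
#' `eta`), the step is identical to standard backpropagation at the base
#' rate.
#'
#' @param model An [amp_mlp()].
#' @param x Input pattern.
#' @param target Target output vector.
#' @param rates A fitted [amp_rate_model()], or `NULL` for a fixed rate.
#' @param eta Fixed learning rate used when `rates` is `NULL`.
#' @return The updated `amp_mlp`.
#' @export
amp_backprop_step <- function(model, x, target, rates = NULL, eta = 0.1) {
  eta_eff <- if (is.null(rates)) eta else amp_rate(rates, x)
  g <- mlp_gradient(model, x, target)
  for (l in seq_along(model$W)) {
    model$W[[l]] <- model$W[[l]] - eta_eff * g$dW[[l]]
    model$b[[l]] <- model$b[[l]] - eta_eff * g$db[[l]]
  }
  model
}

#' @export
print.amp_mlp <- function(x, ...) {
  cat("<amp_mlp> layers:", paste(x$sizes, collapse = "-"), "\n")
  invisible(x)
}
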
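# Shared helpers for the test suite. All fixtures are generated in code.

# fraction of patterns won by their cluster's modal winner
cluster_consistency <- function(model, dataset, predict_fn = cp_predict) {
  win <- vapply(seq_len(nrow(dataset$patterns)), function(i)
    predict_fn(model, dataset$patterns[i, ])$winner, 0L)
  consistent <- 0L
  for (cl in unique(dataset$labels)) {
    w <- win[dataset$labels == cl]
    consistent <- consistent + max(table(w))
  }
  as.numeric(consistent) / length(win)
}

# winners of a model over all rows of a dataset
predict_winners <- function(model, dataset, adapt = FALSE) {
  vapply(seq_len(nrow(dataset$patterns)), function(i)
    cp_predict(model, dataset$patterns[i, ], adapt = adapt)$winner, 0L)
}

# the ablated linear control for the XOR demonstration: no complement coding,
# single settling step, frozen shifts (autapses never enter a one-step settle)
xor_ablated_config <- function(seed) {
  cp_config(n_neurons = 2, mode = "supervised", eta = 0.6, nu = 0,
            k = 500, g = 1, epochs = 30, seed = seed, max_steps = 1,
            autapse_init = 0, shuffle = FALSE, predict_adapt = FALSE,
            coding = input_coding(complement = FALSE, normalize = TRUE))
}

# a reference multilayer perceptron step written independently of the package
# (plain loops, explicit chain rule) used as a gradient oracle
reference_mlp_grad <- function(model, x, target) {
  eps <- 1e-6
  loss <- function(m) {
    a <- as.numeric(x)
    for (l in seq_along(m$W)) a <- stats::plogis(as.numeric(m$W[[l]] %*% a + m$b[[l]]))
    mean((a - as.numeric(target))^2)
  }
  g <- list(dW = model$W, db = model$b)
  for (l in seq_along(model$W)) {
    for (i in seq_len(nrow(model$W[[l]]))) {
      for (j in seq_len(ncol(model$W[[l]]))) {
        up <- model; up$W[[l]][i, j] <- up$W[[l]][i, j] + eps
        dn <- model; dn$W[[l]][i, j] <- dn$W[[l]][i, j] - eps
        g$dW[[l]][i, j] <- (loss(up) - loss(dn)) / (2 * eps)
      }
      up <- model; up$b[[l]][i] <- up$b[[l]][i] + eps
      dn <- model; dn$b[[l]][i] <- dn$b[[l]][i] - eps
      g$db[[l]][i] <- (loss(up) - loss(dn)) / (2 * eps)
    }
  }
  g
}
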
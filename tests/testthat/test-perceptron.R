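test_that("complement coding plus divisive normalization behaves as designed", {
  cod <- input_coding()
  expect_equal(encode(cod, c(0, 0)), c(0, 0, 0.5, 0.5), tolerance = 1e-5)
  expect_equal(encode(cod, c(1, 1)), c(0.5, 0.5, 0, 0), tolerance = 1e-5)
  set.seed(2)
  for (rep in 1:10) {
    y <- encode(cod, runif(4))
    expect_true(all(y >= 0))
    expect_lt(abs(sum(y) - 1), 10 * cod$eps)
  }
  expect_error(encode(cod, c(0.5, 1.3)), "\\[0, 1\\]")
  # flags off reproduce the raw vector
  expect_equal(encode(input_coding(FALSE, FALSE), c(0.2, 0.7)), c(0.2, 0.7))
})

test_that("a single neuron on a single pattern reaches the rule's fixed point", {
  ds <- cp_dataset(matrix(c(0.8, 0.3), 1, 2))
  cfg <- cp_config(n_neurons = 1, mode = "unsupervised", eta = 0.3, nu = 0.1,
                   epochs = 150, seed = 4)
  fit <- cp_train(ds, cfg)
  w_end <- fit$model$layer$weights
  # one more epoch changes the weights by almost nothing (Delta w -> 0)
  fit2 <- cp_train(ds, cp_config(n_neurons = 1, mode = "unsupervised",
                                 eta = 0.3, nu = 0.1, epochs = 1, seed = 4),
                   model = fit$model)
  expect_lt(max(abs(fit2$model$layer$weights - w_end)), 1e-2)
  # once the neuron fires on every presentation its weights approach 1 on the
  # encoded support (the postsynaptic signal, not the input, is the target);
  # convergence is fastest where the encoded input is largest
  enc <- encode(cfg$coding, c(0.8, 0.3))
  expect_true(all(w_end[enc > 0.05] > 0.9))
  expect_gt(w_end[which.max(enc)], w_end[which.min(enc)])
})

test_that("a zero learning rate leaves the weights untouched", {
  ds <- xor_dataset()
  cfg <- cp_config(n_neurons = 2, mode = "supervised", eta = 0, nu = 0.1,
                   epochs = 5, seed = 3, shuffle = FALSE)
  fit <- cp_train(ds, cfg)
  set.seed(3)
  W0 <- matrix(runif(2 * 4, 0, 0.1), 2, 4)
  expect_identical(fit$model$layer$weights, W0)
})

test_that("frozen prediction is deterministic and side-effect free", {
  ds <- xor_dataset()
  fit <- cp_train(ds, xor_config(seed = 2))
  p1 <- cp_predict(fit$model, c(0, 1), adapt = FALSE)
  p2 <- cp_predict(fit$model, c(0, 1), adapt = FALSE)
  expect_identical(p1$winner, p2$winner)
  expect_identical(p1$trace$nets, p2$trace$nets)
  # adaptive evaluation acts on a copy, so it is also repeatable
  a1 <- cp_predict(fit$model, c(0, 1), adapt = TRUE)
  a2 <- cp_predict(fit$model, c(0, 1), adapt = TRUE)
  expect_identical(a1$winner, a2$winner)
  # duplicate neurons tie-break to the first
  lay <- competitive_layer(rbind(c(0.3, 0.3, 0.3, 0.3), c(0.3, 0.3, 0.3, 0.3)),
                           autapse = c(0.2, 0.2), shifts = c(0.4, 0.4))
  m <- fit$model
  m$layer <- lay
  expect_identical(cp_predict(m, c(1, 0), adapt = FALSE)$winner, 1L)
})

test_that("identical seeds and configs give identical training runs", {
  ds <- gaussian_clusters(2, 10, dim = 2, spread = 0.05, seed = 50)
  cfg <- cp_config(n_neurons = 2, mode = "unsupervised", eta = 0.2, nu = 0.1,
                   epochs = 5, seed = 11)
  f1 <- cp_train(ds, cfg)
  f2 <- cp_train(ds, cfg)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$model$layer, f2$model$layer)
})

test_that("untrained perceptrons classify XOR at chance", {
  acc <- vapply(1:100, function(sd)
    evaluate_xor(cp_config(n_neurons = 2, mode = "supervised", eta = 0,
                           nu = 0, epochs = 1, seed = sd, shuffle = FALSE,
                           predict_adapt = FALSE)), 0)
  expect_gt(mean(acc), 0.4)
  expect_lt(mean(acc), 0.6)
  expect_true(all(acc < 1))
})

test_that("the shipped configuration solves XOR across seeds", {
  acc <- vapply(1:10, function(sd) evaluate_xor(xor_config(seed = sd)), 0)
  expect_true(all(acc == 1))
})

test_that("the ablated linear control never solves XOR", {
  acc <- vapply(1:10, function(sd) evaluate_xor(xor_ablated_config(sd)), 0)
  expect_true(all(acc < 1))
})

test_that("supervised training needs consistent labels and neurons", {
  ds <- xor_dataset()
  expect_error(cp_train(ds$patterns, cp_config(n_neurons = 2,
                                               mode = "supervised", seed = 1)),
               "labels")
  expect_error(cp_train(ds, cp_config(n_neurons = 3, mode = "supervised",
                                      seed = 1)),
               "one neuron per class")
  expect_error(cp_train(ds$patterns[0, , drop = FALSE],
                        cp_config(n_neurons = 2, seed = 1)),
               "at least one pattern")
})

test_that("competitive training assigns clusters consistently", {
  acc <- vapply(1:5, function(sd) {
    ds <- gaussian_clusters(3, 30, dim = 2, spread = 0.05, seed = 1000 + sd)
    cfg <- cp_config(n_neurons = 3, mode = "unsupervised", eta = 0.2,
                     nu = 0.02, epochs = 20, seed = sd)
    cluster_consistency(cp_train(ds, cfg)$model, ds)
  }, 0)
  expect_gte(mean(acc >= 0.9), 0.8)
})

test_that("adding neurons does not degrade quantization", {
  qe <- vapply(1:5, function(sd) {
    ds <- gaussian_clusters(3, 30, dim = 2, spread = 0.05, seed = 2000 + sd)
    vapply(c(3L, 6L), function(nn) {
      cfg <- cp_config(n_neurons = nn, mode = "unsupervised", eta = 0.2,
                       nu = 0.02, epochs = 20, seed = sd)
      cp_quantization_error(cp_train(ds, cfg)$model, ds)
    }, 0)
  }, numeric(2))
  expect_lte(mean(qe[2, ]), mean(qe[1, ]) * 1.05)
})

test_that("a new cluster is absorbed without collapsing old assignments", {
  res <- vapply(1:5, function(sd) {
    ds3 <- gaussian_clusters(3, 30, dim = 2, spread = 0.05, seed = 3000 + sd)
    ab <- ds3$labels < 2
    dsAB <- cp_dataset(ds3$patterns[ab, ], labels = ds3$labels[ab])
    cfg <- cp_config(n_neurons = 4, mode = "unsupervised", eta = 0.2,
                     nu = 0.02, epochs = 20, seed = sd)
    fit1 <- cp_train(dsAB, cfg)
    before <- cluster_consistency(fit1$model, dsAB)
    cfg2 <- cp_config(n_neurons = 4, mode = "unsupervised", eta = 0.2,
                      nu = 0.02, epochs = 10, seed = sd + 7)
    fit2 <- cp_train(ds3, cfg2, model = fit1$model)
    after_ab <- cluster_consistency(fit2$model, dsAB)
    keep <- ds3$labels == 2
    dsC <- cp_dataset(ds3$patterns[keep, ], labels = ds3$labels[keep])
    c_rate <- cluster_consistency(fit2$model, dsC)
    c(drop = before - after_ab, c_rate = c_rate)
  }, numeric(2))
  expect_true(all(res["drop", ] < 0.2))
  expect_true(all(res["c_rate", ] >= 0.9))
})

test_that("unsupervised class maps come from majority votes over winners", {
  ds <- gaussian_clusters(2, 20, dim = 2, spread = 0.05, seed = 60)
  cfg <- cp_config(n_neurons = 2, mode = "unsupervised", eta = 0.1, nu = 0.1,
                   epochs = 15, seed = 2)
  fit <- cp_train(ds, cfg)
  expect_length(fit$model$class_map, 2)
  # labels predicted for training data are actual labels, not neuron indices
  cls <- vapply(seq_len(40), function(i)
    cp_predict(fit$model, ds$patterns[i, ])$class, 0)
  expect_true(all(cls %in% c(0, 1)))
})
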
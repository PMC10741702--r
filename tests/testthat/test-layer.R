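make_layer <- function(n = 3, d = 4, seed = 1, ...) {
  set.seed(seed)
  competitive_layer(matrix(runif(n * d), n, d),
                    autapse = runif(n), shifts = runif(n), ...)
}

test_that("a synchronous step matches an explicit per-neuron loop", {
  lay <- make_layer(3, 4, seed = 8, g = 0.7, k = 12, nu = 0.2)
  set.seed(9)
  x <- runif(4); prev <- runif(3)
  st <- layer_step(lay, x, prev)
  for (j in 1:3) {
    net_j <- 0
    for (i in 1:4) net_j <- net_j + lay$weights[j, i] * x[i]
    net_j <- net_j + lay$autapse[j] * prev[j]
    for (m in 1:3) if (m != j) net_j <- net_j - lay$g * prev[m]
    expect_equal(st$nets[j], net_j, tolerance = 1e-15)
    expect_equal(st$outputs[j],
                 activate(net_j, neuron_state(lay$shifts[j], lay$k, lay$nu)),
                 tolerance = 1e-15)
  }
})

test_that("lateral inhibition subtracts exactly g per active neighbour", {
  W <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  lay <- competitive_layer(W, g = 0.8, shifts = c(0.5, 0.5))
  quiet <- layer_step(lay, c(0.5, 0.5), c(0, 0))
  active <- layer_step(lay, c(0.5, 0.5), c(1, 0))
  expect_equal(active$nets[2], quiet$nets[2] - 0.8)
  expect_equal(active$nets[1], quiet$nets[1] + lay$autapse[1])
})

test_that("a silent layer with small weights drifts leftwards under adaptation", {
  lay <- competitive_layer(matrix(0, 2, 2), shifts = c(0.5, 0.5), nu = 0.1)
  st <- layer_step(lay, c(0.5, 0.5), c(0, 0), adapt = TRUE)
  expect_true(all(st$outputs < 1e-9))       # nets 0, T = 0.5, k = 500
  expect_true(all(st$layer$shifts < 0.5))   # every shift strictly decreases
})

test_that("a driven neuron eventually fires through threshold decay", {
  lay <- competitive_layer(matrix(0.4, 1, 1), shifts = 0.5, nu = 0.1)
  st <- settle(lay, x = 0.5, max_steps = 60, adapt = TRUE)
  expect_identical(st$converged, "fired")
  expect_gte(st$outputs[st$steps, 1], lay$theta_fire)
  # firing time agrees with the closed-form shift decay s_t = s0 (1+nu)^-t:
  # the neuron fires once 2 s_t - 0.5 < net = 0.2
  t_pred <- ceiling(log(0.5 / ((0.2 + 0.5) / 2)) / log(1.1))
  expect_lte(abs(st$steps - t_pred), 1)
})

test_that("with frozen equal shifts the larger-net neuron wins", {
  W <- rbind(c(0.9, 0.1), c(0.4, 0.1))
  lay <- competitive_layer(W, shifts = c(0.5, 0.5))
  st <- settle(lay, c(1, 1), max_steps = 40, adapt = FALSE)
  expect_identical(st$winner, 1L)
  lay2 <- competitive_layer(W[2:1, ], shifts = c(0.5, 0.5))
  expect_identical(settle(lay2, c(1, 1), max_steps = 40)$winner, 2L)
})

test_that("repeated wins on the same input shift the winner rightwards", {
  lay <- competitive_layer(rbind(c(0.9, 0.8), c(0.1, 0.1)),
                           shifts = c(0.3, 0.3), nu = 0.1)
  s0 <- lay$shifts[1]
  for (rep in 1:5) {
    st <- settle(lay, c(1, 1), max_steps = 40, adapt = TRUE)
    expect_identical(st$winner, 1L)
    lay <- st$layer
  }
  expect_gt(lay$shifts[1], s0)
})

test_that("firing convergence implies a unique firing neuron", {
  set.seed(33)
  for (rep in 1:20) {
    lay <- make_layer(4, 5, seed = rep, nu = 0.1)
    st <- settle(lay, runif(5), max_steps = 60, adapt = TRUE)
    if (st$converged == "fired") {
      final <- st$outputs[st$steps, ]
      expect_identical(sum(final >= lay$theta_fire), 1L)
      expect_identical(sum(final <= 1 - lay$theta_fire), 3L)
    }
  }
})

test_that("the dynamics are equivariant under neuron permutation", {
  set.seed(44)
  for (rep in 1:5) {
    lay <- make_layer(4, 3, seed = 100 + rep, nu = 0.15)
    x <- runif(3)
    perm <- sample(4)
    lay_p <- competitive_layer(lay$weights[perm, ], autapse = lay$autapse[perm],
                               g = lay$g, shifts = lay$shifts[perm],
                               k = lay$k, nu = lay$nu,
                               theta_fire = lay$theta_fire)
    st <- settle(lay, x, max_steps = 50, adapt = TRUE)
    st_p <- settle(lay_p, x, max_steps = 50, adapt = TRUE)
    expect_equal(st_p$outputs, st$outputs[, perm, drop = FALSE])
    expect_equal(st_p$nets, st$nets[, perm, drop = FALSE])
    expect_identical(st_p$winner, match(st$winner, perm))
  }
})

test_that("outputs fall with inhibition gain and rise with autapse weight", {
  set.seed(55)
  for (rep in 1:5) {
    n <- 3; d <- 4
    W <- matrix(runif(n * d), n, d)
    x <- runif(d); prev <- runif(n)
    sh <- runif(n)
    base <- layer_step(competitive_layer(W, autapse = rep(0.4, n), g = 1,
                                         shifts = sh, k = 10), x, prev)
    hi_g <- layer_step(competitive_layer(W, autapse = rep(0.4, n), g = 1.5,
                                         shifts = sh, k = 10), x, prev)
    hi_a <- layer_step(competitive_layer(W, autapse = rep(0.9, n), g = 1,
                                         shifts = sh, k = 10), x, prev)
    expect_true(all(hi_g$outputs <= base$outputs + 1e-12))
    expect_true(all(hi_a$outputs >= base$outputs - 1e-12))
  }
})

test_that("adaptation equalizes win rates over a random stream", {
  spread <- vapply(1:10, function(sd) {
    set.seed(sd)
    n <- 4; d <- 6
    W <- matrix(runif(n * d), n, d)
    lay0 <- competitive_layer(W, autapse = rep(0.3, n), shifts = rep(0.5, n),
                              nu = 0.1)
    pats <- matrix(runif(150 * d), 150, d)
    pats <- pats / rowSums(pats)  # unit total activity, like coded inputs
    wins_on <- integer(n); wins_off <- integer(n)
    lay_on <- lay0
    for (i in 1:150) {
      st <- settle(lay_on, pats[i, ], 60, adapt = TRUE)
      lay_on <- st$layer
      wins_on[st$winner] <- wins_on[st$winner] + 1L
      w_off <- settle(lay0, pats[i, ], 60)$winner
      wins_off[w_off] <- wins_off[w_off] + 1L
    }
    c(sd(wins_on), sd(wins_off))
  }, numeric(2))
  expect_lt(mean(spread[1, ]), mean(spread[2, ]))
})

test_that("the winner-take-all readout compares excitations", {
  expect_identical(wta_winner(c(0.13, 0.07), c(0, 0)), 1L)
  expect_identical(wta_winner(c(0.2, 0.2), c(0, 0)), 1L)  # tie to lowest index
  set.seed(66)
  for (rep in 1:6) {
    nets <- runif(6); thr <- runif(6, -0.5, 1.5)
    exc <- nets - thr
    best <- 1
    for (j in 2:6) if (exc[j] > exc[best]) best <- j  # exhaustive scan
    expect_identical(wta_winner(nets, thr), as.integer(best))
  }
  expect_error(wta_winner(numeric(0), numeric(0)), "non-empty")
  expect_error(wta_winner(c(1, 2), 1), "length")
})

test_that("settle traces export one row per step and neuron", {
  lay <- make_layer(2, 3, seed = 3)
  st <- settle(lay, c(0.2, 0.4, 0.1), max_steps = 10)
  df <- as.data.frame(st)
  expect_equal(nrow(df), st$steps * 2)
  expect_named(df, c("step", "neuron", "net", "output", "shift"))
  expect_equal(df$net[df$step == st$steps], st$nets[st$steps, ])
})
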
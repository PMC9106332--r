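test_that("evaluation streams have the right shape and metrics", {
  set.seed(50)
  net <- tiny_net("simple", seed = 50)
  ev <- evaluate_model(net, n_contexts = 3, n_t = 120)
  expect_equal(nrow(ev$traces$y), 3 * 120)
  expect_equal(nrow(ev$metrics), 3)
  expect_true(all(c("clarity_y", "clarity_x", "deviation") %in% names(ev$metrics)))
  expect_equal(length(ev$stream$context_index), 3 * 120)
  # default evaluation uses 20 contexts
  expect_equal(formals(evaluate_model)$n_contexts, 20)
})

test_that("protocols are bitwise reproducible under a seed", {
  net <- tiny_net("population", seed = 51, tau = 10)
  set.seed(52); e1 <- evaluate_model(net, 2, 80)
  set.seed(52); e2 <- evaluate_model(net, 2, 80)
  expect_identical(e1$traces$y, e2$traces$y)
  expect_identical(e1$metrics, e2$metrics)
})

test_that("an identity-forcing modulation yields near-zero deviation", {
  net <- tiny_net("simple", seed = 53)
  # constant modulation M = I / W0 makes the effective weights the identity
  net <- constant_modulator(net, as.numeric(diag(2) / net$params$W0))
  bank <- generate_sources("chord", T_samples = 200)
  ident <- structure(list(contexts = list(diag(2)), n_t = 200L,
                          n_contexts = 1L, n_s = 2L),
                     class = "context_schedule")
  stream <- mix_stream(bank, ident, sigma_n = 0)
  sim <- simulate_network(net, stream$x)
  expect_lt(max(abs(sim$y - stream$s)), 1e-10)
})

test_that("noise sweep reports per-level clarity and SNR", {
  set.seed(54)
  net <- tiny_net("simple", seed = 54)
  tab <- sweep_noise(net, c(0.001, 0.1), n_contexts = 2, n_t = 100)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$snr_db[tab$sigma_n == 0.001] >
                    tab$snr_db[tab$sigma_n == 0.1]))
})

test_that("slower modulation damps within-context fluctuations", {
  # dynamical property: the low-pass filter shrinks the drive fluctuations,
  # so M varies less within a context for larger tau
  stream <- random_stream(2, 400, seed = 55)
  v <- vapply(c(2, 100), function(tau) {
    net <- tiny_net("simple", seed = 56, tau = tau)
    sim <- simulate_network(net, stream$x)
    late <- 201:400   # second half of the first context
    mean(apply(sim$mod[late, , drop = FALSE], 2, var))
  }, numeric(1))
  expect_lt(v[2], v[1])
  # relative timescale 0.001 of an n_t = 1000 context is 1 sample
  expect_equal(0.001 * 1000, 1)
})

test_that("freeze protocol clamps the modulation exactly and keeps stage bookkeeping", {
  net <- tiny_net("population", seed = 57, tau = 8)
  set.seed(58)
  fz <- freeze_feedback(net, n_t = 200, freeze_duration = 100)
  expect_equal(fz$stages$start, c(1, 201, 301))
  expect_equal(fz$stages$end, c(200, 300, 400))
  expect_equal(sum(fz$stages$end - fz$stages$start + 1), 400)
  frozen <- fz$traces$mod[201:300, ]
  expect_equal(max(apply(frozen, 2, function(z) diff(range(z)))), 0)
  # modulation moves again after release
  released <- fz$traces$mod[301:400, ]
  expect_gt(max(apply(released, 2, function(z) diff(range(z)))), 0)
  expect_error(freeze_feedback(net, n_t = 100, freeze_duration = 200), "n_t")
})

test_that("freezing is inert when the modulation is already at its fixed point", {
  # constant-feedback modulator without filtering: clamping M changes nothing
  net <- constant_modulator(tiny_net("simple", seed = 59), value = c(1, 0.2, 0.1, 1))
  stream <- random_stream(2, 100, seed = 60)
  a <- simulate_network(net, stream$x)
  b <- simulate_network(net, stream$x, freeze_window = c(101, 150))
  expect_identical(a$y[2:200, ], b$y[2:200, ])
})

test_that("modulation-unit manipulation shifts gains without touching weights", {
  net <- tiny_net("dalean", seed = 61, tau = 5)
  set.seed(62)
  res <- manipulate_modulation_units(net, delta = 3, n_contexts = 1, n_t = 150)
  # delta = 0 leaves the trajectory unchanged
  set.seed(62)
  res0 <- manipulate_modulation_units(net, delta = 0, n_contexts = 1, n_t = 150)
  expect_identical(res0$baseline$y, res0$perturbed$y)
  # positive drive to the modulation units lowers the gain (inhibitory sigmoid)
  expect_lt(mean(res$perturbed$p), mean(res$baseline$p))
  # the perturbation never enters the feedforward weights
  expect_identical(net$params$WHL, net$params$WHL)
  expect_error(manipulate_modulation_units(tiny_net("simple"), 3), "dalean")
})

test_that("a fixed linear readout fails to generalise across contexts", {
  set.seed(63)
  bl <- baseline_linear(n_ctx = 6, n_train = 256, n_test = 256, sigma_n = 0)
  expect_equal(unname(diag(bl$r2)), rep(1, 6), tolerance = 1e-8)
  off <- bl$r2[row(bl$r2) != col(bl$r2)]
  expect_lt(mean(off), mean(diag(bl$r2)))
})

test_that("cross-context linear prediction matches the closed form for swapped mixing", {
  # contexts I and the swap matrix: the readout trained on I is the identity,
  # so testing on the swapped context predicts the swapped sources
  t <- 0:499
  s <- cbind(sin(2 * pi * 100 * t / 8000), sin(2 * pi * 150 * t / 8000))
  swap <- matrix(c(0, 1, 1, 0), 2, 2)
  W <- qr.solve(cbind(1, s), s)            # identity up to numerical error
  pred <- cbind(1, s %*% swap) %*% W
  r2_hand <- mean(sapply(1:2, function(j)
    1 - sum((s[, j] - s[, 3 - j])^2) / sum((s[, j] - mean(s[, j]))^2)))
  r2_got <- mean(sapply(1:2, function(j)
    1 - sum((s[, j] - pred[, j])^2) / sum((s[, j] - mean(s[, j]))^2)))
  expect_equal(r2_got, r2_hand, tolerance = 1e-8)
  expect_lt(r2_got, 0.5)
})

test_that("the multilayer control has the stated architecture and learns", {
  set.seed(64)
  mlp <- baseline_mlp(seq_len = 1, n_batches = 150, contexts_per_batch = 16,
                      n_t = 400)
  expect_equal(vapply(mlp$params$W, ncol, 1L), c(32L, 16L, 8L, 2L))
  expect_equal(nrow(mlp$params$W[[1]]), 2)  # single time point in
  expect_lt(mean(tail(mlp$loss, 30)), mean(head(mlp$loss, 30)))
  pred <- mlp$predict(matrix(c(0.1, 0.2), 1))
  expect_equal(dim(pred), c(1L, 2L))
  # sequence variant flattens the window
  mlp5 <- baseline_mlp(seq_len = 5, n_batches = 5, contexts_per_batch = 4, n_t = 100)
  expect_equal(nrow(mlp5$params$W[[1]]), 10)
})
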
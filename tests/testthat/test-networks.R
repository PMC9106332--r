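test_that("modulator step follows zero-input LSTM algebra and is deterministic", {
  net <- tiny_net("simple")
  # zero state, zero input, zero biases: h = sigmoid(0)*tanh(sigmoid(0)*tanh(0)) = 0,
  # so the feedback equals the readout bias
  net0 <- net
  net0$params$b[] <- 0
  net0$params$bl <- c(0.3, -0.1, 0.2, 0.05)
  step <- modulator_step(net0, c(0, 0), c(0, 0))
  expect_equal(step$feedback, net0$params$bl)

  # stepping twice from the same saved state and input is bitwise identical
  s1 <- modulator_step(net, c(0.4, -0.2), c(0.1, 0.3))
  s2 <- modulator_step(net, c(0.4, -0.2), c(0.1, 0.3))
  expect_identical(s1, s2)
  s3 <- modulator_step(net, c(0.5, 0.1), c(0, 0), state = s1$state)
  s4 <- modulator_step(net, c(0.5, 0.1), c(0, 0), state = s1$state)
  expect_identical(s3$feedback, s4$feedback)

  expect_error(modulator_step(net, c(1, 2, 3)), "n_s")
  expect_equal(modulated_network("simple")$dims$n_hidden, 100)
})

test_that("the R modulator step reproduces the compiled closed loop", {
  net <- tiny_net("simple", seed = 21)
  stream <- random_stream(1, 40, seed = 22)
  sim <- simulate_network(net, stream$x)
  # replay the closed loop with the reference R implementation
  state <- NULL; yprev <- c(0, 0)
  for (t in 1:40) {
    st <- modulator_step(net, stream$x[t, ], yprev, state)
    state <- st$state
    M <- matrix(st$feedback, 2, 2)
    yprev <- forward_simple(net, stream$x[t, ], M)
    expect_equal(yprev, sim$y[t, ], tolerance = 1e-12)
    expect_equal(st$feedback, sim$feedback[t, ], tolerance = 1e-12)
  }
})

test_that("forward_simple is elementwise modulation of the baseline weights", {
  net <- tiny_net("simple")
  net$params$W0 <- diag(2)
  x <- c(0.7, -1.2)
  expect_equal(forward_simple(net, x, matrix(1, 2, 2)), x)
  # modulation equal to A^-1 / W0 inverts the mixture exactly
  set.seed(30)
  net$params$W0 <- matrix(rnorm(4, 1, 0.03), 2, 2)
  A <- sample_mixing_matrix(2)
  s <- c(0.3, -0.8)
  M <- solve(A) / net$params$W0
  expect_equal(forward_simple(net, drop(A %*% s), M), s, tolerance = 1e-12)
  # independent elementwise oracle
  W0 <- matrix(rnorm(4), 2); Mr <- matrix(rnorm(4), 2); xr <- rnorm(2)
  net$params$W0 <- W0
  oracle <- c(sum(Mr[1, ] * W0[1, ] * xr), sum(Mr[2, ] * W0[2, ] * xr))
  expect_equal(forward_simple(net, xr, Mr), oracle)
})

test_that("filtered modulation converges geometrically to its drive", {
  expect_equal(step_filtered_modulation(matrix(0, 2, 2), matrix(3, 2, 2), tau = 1),
               matrix(3, 2, 2))
  tau <- 12; M0 <- 2; drive <- -1
  M <- M0
  for (k in 1:40) M <- step_filtered_modulation(M, drive, tau)
  expect_equal(M - drive, (1 - 1 / tau)^40 * (M0 - drive), tolerance = 1e-12)
  expect_error(step_filtered_modulation(1, 1, tau = 0), "positive")
})

test_that("von Mises kernel has ring geometry", {
  K <- von_mises_kernel(4, 4, sigma_m_sq = 0.2, normalize = FALSE)
  # coincident unit and preferred location: cos(0)/sigma^2
  expect_equal(K[1, 1], exp(1 / 0.2))
  # direct evaluation of the formula at all 16 angle pairs
  zi <- 2 * pi * (1:4) / 4; lj <- 2 * pi * (1:4) / 4
  expect_equal(K, exp(outer(zi, lj, function(z, l) cos(z - l)) / 0.2))
  # circulant: equal row sums, rows are rotations
  expect_equal(rowSums(K), rep(rowSums(K)[1], 4))
  expect_equal(K[2, 2:4], K[1, 1:3])
  # infinite width = uniform modulation across the population
  Ku <- von_mises_kernel(10, 4, sigma_m_sq = Inf, normalize = FALSE)
  expect_true(all(Ku == Ku[1, 1]))
  # normalisation: rows sum to one
  expect_equal(rowSums(von_mises_kernel(16, 3, 0.2)), rep(1, 16))
  # invariance under joint rotation of units and preferred locations
  K8 <- von_mises_kernel(8, 4, 0.5, normalize = FALSE)
  expect_equal(K8[c(3:8, 1:2), c(2:4, 1)], K8, tolerance = 1e-12)
})

test_that("population modulation dynamics have the analytic fixed point", {
  K <- von_mises_kernel(6, 3, 0.2)
  expect_equal(step_population_modulation(rep(0, 6), rep(0, 3), K, tau = 5),
               rep(0, 6))
  # constant feedback: fixed point m* = K l
  l <- c(0.5, -0.2, 1)
  mstar <- drop(K %*% l)
  expect_equal(step_population_modulation(mstar, l, K, tau = 7), mstar)
  m <- rep(0, 6)
  for (k in 1:60) m <- step_population_modulation(m, l, K, tau = 4)
  expect_equal(m - mstar, (1 - 1 / 4)^60 * (0 - mstar), tolerance = 1e-6)
  # hand Euler step: tau = 2, m = 1, Kl = 3 -> 1 + (3 - 1)/2 = 2
  expect_equal(step_population_modulation(1, 3, matrix(1), tau = 2), 2)
})

test_that("population forward pass separates modulation and readout", {
  net <- tiny_net("population", seed = 31)
  x <- c(0.2, -0.5)
  m1 <- rep(1, net$dims$N_z)
  fw <- forward_population(net, x, m1)
  expect_equal(fw$z, drop(net$params$Wx %*% x))
  # two-line oracle for random modulation
  set.seed(32)
  m <- rnorm(net$dims$N_z)
  fw <- forward_population(net, x, m)
  expect_equal(fw$z, m * drop(net$params$Wx %*% x))
  expect_equal(fw$y, drop(net$params$Wro %*% (m * drop(net$params$Wx %*% x))))
  # defaults
  full <- modulated_network("population")
  expect_equal(full$dims$N_z, 100)
  expect_equal(full$N_FB, 4)
  expect_equal(full$sigma_m_sq, 0.2)
  expect_equal(full$tau, 100)
})

test_that("gain is an inhibitory sigmoid of modulation", {
  expect_equal(gain_from_modulation(0), 0.5)
  expect_equal(gain_from_modulation(log(3)), 0.25)
  m <- seq(-20, 20, length.out = 201)
  p <- gain_from_modulation(m)
  expect_true(all(diff(p) < 0))
  expect_true(all(p > 0 & p < 1))
})

test_that("Dalean forward pass is rectified, gain-scaled and Dalean", {
  net <- tiny_net("dalean", seed = 33)
  p <- rep(0.5, net$dims$N_H)
  # input driving every lower-level unit below threshold silences the network
  net0 <- net
  net0$params$WLx <- matrix(1, net$dims$N_L, 2)
  fw <- forward_dalean(net0, c(-1, -1), p)
  expect_equal(fw$zL, rep(0, net$dims$N_L))
  expect_equal(fw$zH, rep(0, net$dims$N_H))
  expect_equal(fw$y, c(0, 0))
  # zero gains silence the higher-level population
  fw <- forward_dalean(net, c(0.4, 0.1), rep(0, net$dims$N_H))
  expect_equal(fw$zH, rep(0, net$dims$N_H))
  # defaults
  full <- modulated_network("dalean")
  expect_equal(full$dims[c("N_L", "N_H", "N_I")], list(N_L = 40, N_H = 100, N_I = 20))
})

test_that("effective weights equal the true input-output Jacobian", {
  net <- tiny_net("simple")
  net$params$W0 <- diag(2)
  expect_equal(effective_weights(net, list(M = matrix(1, 2, 2))), diag(2))

  # population: closed form Wro diag(m) Wx, checked by finite differences
  pop <- tiny_net("population", seed = 34)
  set.seed(35)
  m <- rnorm(pop$dims$N_z)
  Weff <- effective_weights(pop, list(m = m))
  expect_equal(Weff, pop$params$Wro %*% (m * pop$params$Wx))
  x0 <- c(0.3, -0.2); eps <- 1e-6
  J <- sapply(1:2, function(j) {
    dx <- c(0, 0); dx[j] <- eps
    (forward_population(pop, x0 + dx, m)$y -
       forward_population(pop, x0 - dx, m)$y) / (2 * eps)
  })
  expect_equal(unname(Weff), unname(J), tolerance = 1e-6)

  # dalean: linearised through the rectifications at the operating point
  dal <- tiny_net("dalean", seed = 36)
  p <- gain_from_modulation(rnorm(dal$dims$N_H))
  x0 <- c(0.5, 0.2)
  Weff <- effective_weights(dal, list(p = p, x_t = x0))
  J <- sapply(1:2, function(j) {
    dx <- c(0, 0); dx[j] <- 1e-7
    (forward_dalean(dal, x0 + dx, p)$y - forward_dalean(dal, x0 - dx, p)$y) / 2e-7
  })
  expect_equal(unname(Weff), unname(J), tolerance = 1e-5)
})

test_that("input ablations zero-mask the modulator input without changing shapes", {
  xo <- tiny_net("simple", seed = 37, input_mode = "x_only")
  yo <- tiny_net("simple", seed = 37, input_mode = "y_only")
  both <- tiny_net("simple", seed = 37)
  expect_equal(dim(xo$params$Wi), dim(both$params$Wi))
  # x_only: feedback is invariant to the output fed back
  a <- modulator_step(xo, c(0.3, 0.1), c(5, -5))
  b <- modulator_step(xo, c(0.3, 0.1), c(0, 0))
  expect_identical(a$feedback, b$feedback)
  # y_only: feedback is invariant to the stimulus
  a <- modulator_step(yo, c(9, 9), c(0.2, 0.4))
  b <- modulator_step(yo, c(0, 0), c(0.2, 0.4))
  expect_identical(a$feedback, b$feedback)
})
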
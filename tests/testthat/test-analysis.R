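test_that("pearson_r behaves like the textbook coefficient", {
  u <- rnorm(50)
  expect_equal(pearson_r(u, u), 1)
  expect_equal(pearson_r(u, -u), -1)
  # orthogonal sines decorrelate over whole periods
  t <- 0:7999
  expect_equal(pearson_r(sin(2 * pi * 100 * t / 8000),
                         sin(2 * pi * 150 * t / 8000)), 0, tolerance = 1e-10)
  expect_error(pearson_r(rep(1, 10), rnorm(10)), "zero-variance")
  expect_error(pearson_r(1:3, 1:4), "length")
})

test_that("signal clarity separates clean outputs from even mixes", {
  bank <- generate_sources("chord", T_samples = 4000)
  s <- bank$samples
  # outputs identical to the sources: clarity ~ 1 on both channels
  expect_equal(signal_clarity(s, s), c(1, 1), tolerance = 1e-6)
  # a 0.8/0.2 mixture of orthogonal unit-variance sources: |2*0.8 - 1| = 0.6
  t <- 0:7999
  su <- cbind(sqrt(2) * sin(2 * pi * 100 * t / 8000),
              sqrt(2) * sin(2 * pi * 150 * t / 8000))
  mixed <- su %*% t(matrix(c(0.8, 0.2, 0.2, 0.8), 2, 2, byrow = TRUE))
  expect_equal(signal_clarity(mixed, su), c(0.6, 0.6), tolerance = 1e-6)
  # raw (unnormalised) variant: |r1| - |r2| without the denominator
  r <- abs(cor(mixed, su))
  expect_equal(signal_clarity(mixed, su, normalized = FALSE),
               unname(abs(r[, 1] - r[, 2])), tolerance = 1e-12)
})

test_that("normalised clarity is invariant to rescaling and label swaps", {
  set.seed(70)
  stream <- random_stream(1, 1000, seed = 70)
  cl <- signal_clarity(stream$x, stream$s)
  expect_equal(signal_clarity(stream$x %*% diag(c(3, 0.1)), stream$s), cl)
  expect_equal(sort(signal_clarity(stream$x[, 2:1], stream$s)), sort(cl))
  expect_error(signal_clarity(matrix(1, 10, 2), matrix(rnorm(20), 10)), "zero-variance")
})

test_that("per-neuron clarity flags silent neurons and recovers pure carriers", {
  bank <- generate_sources("chord", T_samples = 2000)
  s <- bank$samples
  ctx <- rep(1:2, each = 1000)
  act <- cbind(s[, 1],                 # carries source 1 exactly
               0.5 * s[, 1] + 0.5 * s[, 2],  # even mix
               rep(0, 2000))           # silent
  pc <- per_neuron_clarity(act, s, ctx)
  expect_equal(dim(pc), c(3, 2))
  # finite-window correlation leakage keeps this a little below 1
  expect_equal(pc[1, ], c(ctx1 = 1, ctx2 = 1), tolerance = 0.05)
  expect_lt(max(pc[2, ]), 0.05)
  expect_true(all(is.na(pc[3, ])))
})

test_that("clarity-readout correlation detects dependence and independence", {
  set.seed(71)
  w <- matrix(rnorm(2 * 40), 2, 40)
  mags <- sqrt(colSums(w^2))
  r <- clarity_readout_correlation(mags, w)
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_lt(r$p, 1e-10)
  # permutation oracle: independent clarities give small |r|, large p on average
  rs <- replicate(200, {
    cl <- sample(mags)
    clarity_readout_correlation(cl, w)$r
  })
  expect_lt(abs(mean(rs)), 0.05)
  expect_lt(mean(abs(rs)), 0.25)
})

test_that("source decoding generalises from identity activity but not raw stimuli", {
  set.seed(72)
  n_ctx <- 20; n_t <- 200
  bank <- generate_sources("chord", T_samples = n_ctx * n_t)
  stream <- mix_stream(bank, build_schedule(n_ctx, n_t), sigma_n = 0.001)
  # activity equal to the sources: perfect generalisation
  rep1 <- decode_sources(stream$s, stream$s, stream$context_index)
  expect_equal(mean(rep1$r2_test), 1, tolerance = 1e-6)
  # activity equal to the context-mixed stimuli: poor generalisation
  rep2 <- decode_sources(stream$x, stream$s, stream$context_index)
  expect_lt(mean(rep2$r2_test), rep2$r2_train)
  expect_error(decode_sources(stream$x, stream$s, stream$context_index,
                              train_ctx = 1:10, test_ctx = 10:19), "distinct")
})

test_that("decoder training set size follows the stated defaults", {
  set.seed(73)
  n_ctx <- 20; n_t <- 1000
  ctx <- rep(seq_len(n_ctx), each = n_t)
  act <- matrix(rnorm(n_ctx * n_t * 3), ncol = 3)
  src <- act[, 1:2] + rnorm(n_ctx * n_t, 0, 0.1)
  rep <- decode_sources(act, src, ctx)
  expect_equal(rep$n_train_samples, 10000)
  expect_equal(length(rep$r2_test), 10)
})

test_that("context decoding recovers linear and inverse-matrix structure", {
  set.seed(74)
  grid <- context_grid(20, 0.2)
  expect_equal(nrow(grid$vars), 272)
  vars <- as.matrix(grid$vars)
  # activity = the context variables themselves: linear R2 = 1
  r_lin <- decode_context(vars, grid$contexts, mode = "linear")
  expect_equal(r_lin$r2, 1, tolerance = 1e-8)
  # activity = entries of A^-1: inverse mode perfect, linear mode not
  inv_act <- t(vapply(grid$contexts, function(A) as.vector(solve(A)), numeric(4)))
  r_inv <- decode_context(inv_act, grid$contexts, mode = "inverse")
  expect_equal(r_inv$r2, 1, tolerance = 1e-8)
  r_lin2 <- decode_context(inv_act, grid$contexts, mode = "linear")
  expect_lt(r_lin2$r2, 1 - 1e-4)
  # quadratic expansion can only help a linear target
  r_quad <- decode_context(inv_act, grid$contexts, mode = "quadratic")
  expect_gte(r_quad$r2 + 1e-8, r_lin2$r2)
  # folds partition the contexts
  expect_equal(sort(unique(r_lin$folds)), 1:5)
  expect_equal(length(r_lin$folds), 272)
  expect_error(decode_context(vars[1:3, ], grid$contexts[1:3], n_folds = 5),
               "folds")
})

test_that("subspace coordinates recover analytic principal directions", {
  set.seed(75)
  N <- 20
  ro <- matrix(0, 2, N); ro[1, 1] <- 1; ro[2, 2] <- 1
  # construct activity with a known dominant direction orthogonal to readout
  dir3 <- c(rep(0, 2), 1, rep(0, N - 3))
  T_n <- 500
  act <- cbind(rnorm(T_n), rnorm(T_n)) %*% ro + 3 * rnorm(T_n) %*% t(dir3) +
    0.01 * matrix(rnorm(T_n * N), T_n, N)
  co <- subspace_coordinates(act, ro)
  ax <- attr(co, "axes")
  expect_equal(abs(sum(ax[, 3] * dir3)), 1, tolerance = 1e-3)
  expect_equal(ax[, 1], c(1, rep(0, N - 1)))
  # activity confined to the readout plane: third coordinate vanishes
  flat <- cbind(rnorm(T_n), rnorm(T_n)) %*% ro
  co2 <- subspace_coordinates(flat, ro, reference_trace = act)
  expect_lt(max(abs(co2[, 3])), 1e-10)
  # degenerate reference (rank < 3) is flagged
  expect_error(subspace_coordinates(flat, ro, reference_trace = flat),
               "degenerate")
})

test_that("plane fitting and folded angles have the stated geometry", {
  set.seed(76)
  pts_xy <- cbind(rnorm(50), rnorm(50), 0)
  n1 <- fit_plane(pts_xy)
  expect_equal(abs(n1), c(0, 0, 1), tolerance = 1e-12)
  u <- rnorm(50); w <- rnorm(50)
  n2 <- fit_plane(cbind(u, u, w))   # the plane x = y
  expect_equal(abs(sum(n2 * c(1, -1, 0) / sqrt(2))), 1, tolerance = 1e-8)
  # noisy plane recovery within 1 degree
  normal <- c(1, 2, -1) / sqrt(6)
  basis <- svd(diag(3) - normal %*% t(normal))$u[, 1:2]
  noisy <- cbind(rnorm(400), rnorm(400)) %*% t(basis) +
    0.01 * matrix(rnorm(1200), 400, 3)
  expect_lt(plane_angle(fit_plane(noisy), normal), 1)
  expect_error(fit_plane(cbind(1:10, 1:10, 1:10)), "collinear")

  expect_equal(plane_angle(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(plane_angle(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(plane_angle(c(1, 0, 0), c(-1, 0, 0)), 0)
  # symmetry and bounds over random pairs
  for (i in 1:50) {
    a <- rnorm(3); b <- rnorm(3)
    ang <- plane_angle(a, b)
    expect_equal(ang, plane_angle(b, a))
    expect_true(ang >= 0 && ang <= 90)
  }
  expect_error(plane_angle(c(0, 0, 0), c(1, 0, 0)), "zero")
})

test_that("context-pair bookkeeping labels sides of the diagonal", {
  net <- tiny_net("population", seed = 77, tau = 8)
  set.seed(78)
  rep <- angle_vs_context_distance(net, n_pairs = 4, n_t = 200)
  expect_equal(nrow(rep$pairs), 4)
  expect_true(all(rep$pairs$angle >= 0 & rep$pairs$angle <= 90))
  expect_true(all(rep$pairs$side %in% c("same-side", "different-side")))
  # label oracle: (0.2,0.8) vs (0.3,0.9) same side; vs (0.8,0.2) different
  sgn <- function(v) sign(v[1] - v[2])
  expect_true(sgn(c(0.2, 0.8)) == sgn(c(0.3, 0.9)))
  expect_false(sgn(c(0.2, 0.8)) == sgn(c(0.8, 0.2)))
})
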
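#' Pearson correlation over time
#'
#' Standard Pearson coefficient between two traces, erroring on degenerate
#' input instead of returning `NA`.
#' @param u,v numeric vectors of equal length (>= 2).
#' @export
pearson_r <- function(u, v) {
  if (length(u) != length(v) || length(u) < 2)
    stop("u and v must have equal length >= 2", call. = FALSE)
  if (sd(u) == 0 || sd(v) == 0)
    stop("correlation undefined for zero-variance input", call. = FALSE)
  cor(u, v)
}

#' Signal clarity of outputs with respect to two sources
#'
#' For each output channel `j`, the absolute difference between its absolute
#' correlations with the two sources,
#' \deqn{c_j = | |r_{1j}| - |r_{2j}| |,}
#' normalised by default by the correlation sum `|r_{1j}| + |r_{2j}|` so that
#' 1 means the channel carries a single source and 0 an even mix. The mean
#' normalised clarity of the raw mixed stimuli over random contexts is the
#' chance reference (about 0.5, slightly below because row-normalised uniform
#' mixtures concentrate near the even mix). For more than two sources a
#' generalisation is used: the gap between the largest and second-largest
#' absolute correlation (normalised by their sum).
#'
#' @param outputs matrix `T` x `n_out` (an output, stimulus or single-neuron
#'   trace per column).
#' @param sources matrix `T` x `n_s` of aligned sources.
#' @param normalized divide by the correlation sum (default TRUE).
#' @return numeric vector of per-channel clarities; average it for the
#'   channel-mean clarity of the stage.
#' @export
signal_clarity <- function(outputs, sources, normalized = TRUE) {
  outputs <- as.matrix(outputs); sources <- as.matrix(sources)
  r <- abs(suppressWarnings(cor(outputs, sources)))
  if (anyNA(r)) stop("clarity undefined: zero-variance trace", call. = FALSE)
  if (ncol(sources) == 2) {
    top <- r[, 1]; second <- r[, 2]
  } else {
    ord <- t(apply(r, 1, sort, decreasing = TRUE))
    top <- ord[, 1]; second <- ord[, 2]
  }
  num <- abs(top - second)
  if (normalized) {
    den <- top + second
    if (any(den == 0)) stop("clarity undefined: both correlations zero", call. = FALSE)
    num <- num / den
  }
  unname(num)
}

#' Per-neuron, per-context signal clarity
#'
#' [signal_clarity()] applied to every neuron's trace within every context.
#' Neurons that are silent (zero variance) within a context get `NA` and are
#' excluded from averages.
#' @param activity matrix `T` x `N` of population activity.
#' @param sources matrix `T` x `n_s` of aligned sources.
#' @param context_index per-sample context id (length `T`).
#' @param normalized passed to [signal_clarity()].
#' @return matrix `N` x `n_contexts`.
#' @export
per_neuron_clarity <- function(activity, sources, context_index,
                               normalized = TRUE) {
  ctxs <- sort(unique(context_index))
  out <- sapply(ctxs, function(k) {
    idx <- which(context_index == k)
    act <- activity[idx, , drop = FALSE]
    src <- sources[idx, , drop = FALSE]
    vapply(seq_len(ncol(act)), function(j) {
      tr <- act[, j]
      if (sd(tr) == 0) return(NA_real_)
      cl <- tryCatch(signal_clarity(matrix(tr), src, normalized),
                     error = function(e) NA_real_)
      cl[1]
    }, numeric(1))
  })
  colnames(out) <- paste0("ctx", ctxs)
  out
}

#' Correlation between per-neuron clarity and readout weight
#'
#' Pearson correlation (with two-sided p-value) between each neuron's mean
#' signal clarity over contexts and the magnitude of its readout weight
#' (Euclidean norm across the output channels). For trained models no
#' significant relation is expected: invariance lives in the population, not
#' in a subset of clear neurons that the readout could single out.
#' @param mean_clarity per-neuron clarity averaged over contexts (length `N`).
#' @param readout_weights readout matrix `n_s` x `N`.
#' @return list with `r` and `p`.
#' @export
clarity_readout_correlation <- function(mean_clarity, readout_weights) {
  w <- sqrt(colSums(as.matrix(readout_weights)^2))
  ok <- is.finite(mean_clarity)
  ct <- cor.test(mean_clarity[ok], w[ok])
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Cross-context linear decoding of the sources
#'
#' Fits one ordinary-least-squares decoder of the sources from population
#' activity on the concatenated training contexts (10 contexts x 1000 samples
#' = 10,000 samples at the defaults) and reports R^2 on each held-out test
#' context. An invariant subspace exists exactly when one fixed decoder
#' generalises across contexts.
#'
#' @param activity matrix `T` x `N` of activity at some processing stage.
#' @param sources matrix `T` x `n_s` of aligned sources.
#' @param context_index per-sample context id.
#' @param train_ctx,test_ctx context ids for fitting and testing; by default
#'   the first 10 and the next 10 distinct contexts.
#' @return class `decoding_report`: list with `r2_test` (per test context),
#'   `r2_train`, `n_train_samples`, `coefficients`.
#' @export
decode_sources <- function(activity, sources, context_index,
                           train_ctx = NULL, test_ctx = NULL) {
  ctxs <- sort(unique(context_index))
  if (is.null(train_ctx)) train_ctx <- head(ctxs, 10)
  if (is.null(test_ctx)) test_ctx <- head(setdiff(ctxs, train_ctx), 10)
  if (length(intersect(train_ctx, test_ctx)) > 0)
    stop("train and test contexts must be distinct", call. = FALSE)
  tr <- which(context_index %in% train_ctx)
  X <- cbind(1, activity[tr, , drop = FALSE])
  B <- tryCatch(qr.solve(X, sources[tr, , drop = FALSE]),
                error = function(e) {
                  # rank-deficient design: least-norm solution via pseudoinverse
                  sv <- svd(X)
                  pos <- sv$d > max(sv$d) * 1e-10
                  sv$v[, pos] %*% ((t(sv$u[, pos]) %*% sources[tr, , drop = FALSE]) / sv$d[pos])
                })
  r2_test <- vapply(test_ctx, function(k) {
    idx <- which(context_index == k)
    r_squared(sources[idx, , drop = FALSE],
              cbind(1, activity[idx, , drop = FALSE]) %*% B)
  }, numeric(1))
  structure(list(r2_test = r2_test,
                 r2_train = r_squared(sources[tr, , drop = FALSE], X %*% B),
                 n_train_samples = length(tr),
                 train_ctx = train_ctx, test_ctx = test_ctx,
                 coefficients = B),
            class = "decoding_report")
}

#' @export
print.decoding_report <- function(x, ...) {
  cat(sprintf("<decoding_report> train R2 = %.3f (n = %d), mean test R2 = %.3f\n",
              x$r2_train, x$n_train_samples, mean(x$r2_test)))
  invisible(x)
}

#' Decode the context from time-averaged activity
#'
#' Linear regression of the two context variables `(a, b)` (or, in
#' `"inverse"` mode, the four entries of the inverse mixing matrix) on the
#' per-context temporal mean of the activity, scored by fivefold
#' cross-validated R^2. `"quadratic"` mode augments the features with all
#' squares and pairwise products before the linear fit.
#'
#' @param mean_activity matrix `n_contexts` x `N` of per-context average
#'   activity (exclude onset transients by averaging the second half of each
#'   context).
#' @param contexts list of mixing matrices or a matrix/data.frame of context
#'   variables `(a, b)` with one row per context.
#' @param mode `"linear"`, `"quadratic"` or `"inverse"`.
#' @param n_folds cross-validation folds (default 5).
#' @return class `decoding_report`: list with `r2` (mean over folds),
#'   `r2_folds`, `mode`, `folds` assignment.
#' @export
decode_context <- function(mean_activity, contexts,
                           mode = c("linear", "quadratic", "inverse"),
                           n_folds = 5) {
  mode <- match.arg(mode)
  X <- as.matrix(mean_activity)
  n <- nrow(X)
  if (n < n_folds) stop("fewer contexts than folds", call. = FALSE)
  if (is.list(contexts) && !is.data.frame(contexts)) {
    vars <- t(vapply(contexts, context_vars, numeric(2)))
    mats <- contexts
  } else {
    vars <- as.matrix(contexts)
    mats <- lapply(seq_len(n), function(i)
      matrix(c(vars[i, 1], vars[i, 2], 1 - vars[i, 1], 1 - vars[i, 2]), 2, 2))
  }
  Y <- if (mode == "inverse") {
    t(vapply(mats, function(A) as.vector(solve(A)), numeric(4)))
  } else vars
  if (mode == "quadratic") {
    p <- ncol(X)
    quad <- do.call(cbind, lapply(seq_len(p), function(i)
      X[, i:p, drop = FALSE] * X[, i]))
    X <- cbind(X, quad)
  }
  folds <- sample(rep(seq_len(n_folds), length.out = n))
  r2_folds <- vapply(seq_len(n_folds), function(f) {
    tr <- folds != f
    Xd <- cbind(1, X)
    sv <- svd(Xd[tr, , drop = FALSE])
    pos <- sv$d > max(sv$d) * 1e-10
    B <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% Y[tr, , drop = FALSE]) / sv$d[pos])
    r_squared(Y[!tr, , drop = FALSE], Xd[!tr, , drop = FALSE] %*% B)
  }, numeric(1))
  structure(list(r2 = mean(r2_folds), r2_folds = r2_folds, mode = mode,
                 folds = folds, r2_train = NA, n_train_samples = sum(folds != 1),
                 r2_test = r2_folds),
            class = "decoding_report")
}

#' Project population activity onto the readout plane and PC1
#'
#' Display coordinates for the subspace analysis: the two (orthonormalised)
#' readout axes, plus the first principal component of a reference-condition
#' trace after removing its components along the readout axes, so the three
#' axes are non-redundant.
#'
#' @param population_trace matrix `T` x `N`.
#' @param readout readout matrix `n_s` x `N` with two output channels.
#' @param reference_trace trace defining PC1 (defaults to
#'   `population_trace`).
#' @return matrix `T` x 3 of coordinates; the axes are attached as attribute
#'   `"axes"` (`N` x 3).
#' @export
subspace_coordinates <- function(population_trace, readout,
                                 reference_trace = population_trace) {
  readout <- as.matrix(readout)
  if (nrow(readout) != 2) stop("readout must have 2 output channels", call. = FALSE)
  q1 <- readout[1, ]; q1 <- q1 / sqrt(sum(q1^2))
  q2 <- readout[2, ] - sum(readout[2, ] * q1) * q1
  q2 <- q2 / sqrt(sum(q2^2))
  ref <- scale(reference_trace, center = TRUE, scale = FALSE)
  resid <- ref - (ref %*% q1) %*% t(q1) - (ref %*% q2) %*% t(q2)
  sv <- svd(resid, nu = 0, nv = 1)
  if (sv$d[1] < max(1e-12, 1e-10 * norm(ref, "F")))
    stop("activity confined to the readout plane: PC1 degenerate", call. = FALSE)
  pc1 <- sv$v[, 1]
  axes <- cbind(readout1 = q1, readout2 = q2, pc1 = pc1)
  coords <- population_trace %*% axes
  attr(coords, "axes") <- axes
  coords
}

#' Total-least-squares plane fit
#'
#' Fits a plane through the centroid of 3-D points; the unit normal is the
#' direction of least variance.
#' @param points_3d matrix `n` x 3 with `n >= 3`.
#' @return unit normal (length-3 vector).
#' @export
fit_plane <- function(points_3d) {
  points_3d <- as.matrix(points_3d)
  if (nrow(points_3d) < 3) stop("need at least 3 points", call. = FALSE)
  cen <- scale(points_3d, center = TRUE, scale = FALSE)
  sv <- svd(cen, nu = 0)
  if (sv$d[2] < max(sv$d) * 1e-10)
    stop("degenerate fit: points are collinear", call. = FALSE)
  sv$v[, 3]
}

#' Folded angle between two planes
#'
#' `acos(|cos(theta)|)` between the plane normals, in degrees: antiparallel
#' normals describe the same plane, so a rotation of 180 degrees corresponds
#' to 0 and all angles lie in \[0, 90\].
#' @param normal_a,normal_b plane normals (nonzero length-3 vectors).
#' @export
plane_angle <- function(normal_a, normal_b) {
  na <- sqrt(sum(normal_a^2)); nb <- sqrt(sum(normal_b^2))
  if (na == 0 || nb == 0) stop("zero-length normal", call. = FALSE)
  acos(min(1, abs(sum(normal_a * normal_b)) / (na * nb))) * 180 / pi
}

#' Subspace angle versus context distance
#'
#' For pairs of random contexts, simulates the model with intact feedback in
#' both contexts, fits a plane to the population activity (readout plane +
#' PC1 coordinates) in each, and relates the folded angle between the planes
#' to the Euclidean distance of the contexts in `(a, b)` space. Pairs are
#' labelled `same-side` or `different-side` of the diagonal `a = b` by the
#' sign of `a - b`.
#'
#' @param net a trained population or dalean [modulated_network()].
#' @param n_pairs number of context pairs.
#' @param n_t samples per context (the second half, past the onset transient,
#'   enters the plane fits).
#' @param freqs sine frequencies for the protocol sources.
#' @param sigma_n stimulus noise.
#' @return class `subspace_report`: data.frame `pairs` (distance, angle,
#'   side label) plus the Pearson correlation `r` and `p` over pairs.
#' @export
angle_vs_context_distance <- function(net, n_pairs = 20, n_t = 1000,
                                      freqs = c(100, 150), sigma_n = 0.001) {
  readout <- net$params$Wro
  rows <- lapply(seq_len(n_pairs), function(i) {
    A1 <- sample_mixing_matrix(net$dims$n_s)
    A2 <- sample_mixing_matrix(net$dims$n_s)
    bank <- generate_sources("sine", freqs = freqs, T_samples = 2 * n_t)
    schedule <- structure(list(contexts = list(A1, A2), n_t = n_t,
                               n_contexts = 2L, n_s = net$dims$n_s),
                          class = "context_schedule")
    stream <- mix_stream(bank, schedule, sigma_n)
    sim <- simulate_network(net, stream$x)
    act <- population_activity(sim, net)
    late1 <- (n_t / 2 + 1):n_t
    late2 <- (n_t + n_t / 2 + 1):(2 * n_t)
    co <- subspace_coordinates(act, readout,
                               reference_trace = act[late1, , drop = FALSE])
    ang <- plane_angle(fit_plane(co[late1, ]), fit_plane(co[late2, ]))
    v1 <- context_vars(A1); v2 <- context_vars(A2)
    data.frame(pair = i, distance = sqrt(sum((v1 - v2)^2)), angle = ang,
               side = if (sign(v1["a"] - v1["b"]) == sign(v2["a"] - v2["b"]))
                 "same-side" else "different-side")
  })
  pairs <- do.call(rbind, rows)
  ct <- cor.test(pairs$distance, pairs$angle)
  structure(list(pairs = pairs, r = unname(ct$estimate), p = ct$p.value),
            class = "subspace_report")
}

#' @export
print.subspace_report <- function(x, ...) {
  cat(sprintf("<subspace_report> %d pairs, Pearson r = %.3f (p = %.3g)\n",
              nrow(x$pairs), x$r, x$p))
  invisible(x)
}
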
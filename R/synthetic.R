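# Seeded synthetic multimodal generator. It reproduces the statistical
# structure the hierarchical framework assumes: motion-sensor segments are
# drawn from per-MOTION-STATE signal models (a gravity orientation per
# posture plus Gaussian noise, with a gait-like sinusoid for ambulatory
# states), so activities sharing a state are indistinguishable from the
# sensor alone; image payloads are drawn from per-ACTIVITY Gaussian feature
# clusters whose separation delta controls the image layer's difficulty.
# Low-frame-rate payloads are single feature vectors; high-frame-rate
# payloads are K-frame AR(1) sequences.

resample1 <- function(x) x[sample.int(length(x), 1L)]

#' Default per-motion-state signal models
#'
#' Each state gets a distinct gravity orientation (spread over a quarter
#' circle in the x/z accelerometer plane, magnitude 9.81 m/s^2) and
#' channel noise sd 0.3. States whose label suggests periodic movement
#' (walking, running, cycling, push-ups, sit-ups) additionally carry a
#' sinusoidal oscillation with a state-specific frequency near the 2 Hz
#' human gait band.
#'
#' @param states a [motion_state_set()].
#' @return named list of per-state models (`gravity`, `noise_sd`,
#'   `osc_amp`, `osc_freq`, `gyro_amp`).
#' @export
default_state_models <- function(states) {
  m <- states$m
  osc <- grepl("WK|RN|CY|DPU|DSU", states$labels)
  freq <- cumsum(osc)  # 1, 2, ... over the oscillatory states
  models <- lapply(seq_len(m), function(i) {
    theta <- if (m == 1L) 0 else (i - 1) / (m - 1) * (pi / 2)
    list(gravity = 9.81 * c(sin(theta), 0, cos(theta)),
         noise_sd = 0.3,
         osc_amp = if (osc[i]) 3 else 0,
         osc_freq = if (osc[i]) 1.5 + 0.5 * freq[i] else 0,
         gyro_amp = if (osc[i]) 1.5 else 0)
  })
  names(models) <- states$labels
  models
}

#' Specify a synthetic multimodal dataset
#'
#' @param C a [correspondence()] defining activities, states and groups.
#' @param regime `"low"` (one frame per window, disjoint windows) or
#'   `"high"` (K-frame correlated sequence per window).
#' @param fs sensor sampling rate, Hz.
#' @param t_w window width, seconds.
#' @param feature_dim dimension d of the image feature space.
#' @param delta separation scale of the per-activity feature clusters
#'   (cluster means are `delta` times unit vectors; within-cluster sd
#'   `feature_sd`).
#' @param feature_sd within-cluster standard deviation.
#' @param K frames per high-rate sequence (about `t_w` x 30 fps).
#' @param rho AR(1) correlation of consecutive frame features, `0 <= rho < 1`.
#' @param proportions activity sampling proportions (default uniform).
#' @param state_models per-state signal models; default
#'   [default_state_models()].
#' @param layout_seed seed fixing the cluster-mean layout (kept separate
#'   from the dataset seed so different draws share one geometry).
#' @return an object of class `generator_spec`.
#' @export
generator_spec <- function(C, regime = c("low", "high"), fs = 90, t_w = 3,
                           feature_dim = 16L, delta = 2.5, feature_sd = 1,
                           K = 90L, rho = 0.9, proportions = NULL,
                           state_models = NULL, layout_seed = 101L) {
  regime <- match.arg(regime)
  stopifnot(inherits(C, "correspondence"))
  if (delta < 0 || feature_sd <= 0) stop_hf("delta >= 0 and feature_sd > 0 required",
                                            class = "hf_invalid")
  if (rho < 0 || rho >= 1) stop_hf("need 0 <= rho < 1", class = "hf_invalid")
  if (is.null(proportions)) proportions <- rep(1 / C$activities$n, C$activities$n)
  if (length(proportions) != C$activities$n || any(proportions < 0))
    stop_hf("bad proportions", class = "hf_invalid")
  proportions <- proportions / sum(proportions)
  sm <- state_models %||% default_state_models(C$states)
  if (!setequal(names(sm), C$states$labels))
    stop_hf("state_models must cover exactly the state set", class = "hf_invalid")
  structure(list(C = C, regime = regime, fs = fs, t_w = t_w,
                 feature_dim = as.integer(feature_dim), delta = delta,
                 feature_sd = feature_sd, K = as.integer(K), rho = rho,
                 proportions = proportions, state_models = sm,
                 layout_seed = as.integer(layout_seed)),
            class = "generator_spec")
}

#' Cluster means of the feature model
#'
#' Deterministic given the spec: `delta` times unit direction vectors drawn
#' under `layout_seed`. Directions are the signed axes of one random
#' rotation, so any two cluster means are at distance `delta * sqrt(2)` (or
#' `2 * delta` for a sign pair) — `delta` is a genuine separation scale,
#' not just a norm. If the activity count exceeds `2 d`, the surplus
#' directions are random unit vectors. Row order is the canonical activity
#' order.
#'
#' @param spec a [generator_spec()].
#' @return `n x d` matrix of cluster means.
#' @export
cluster_means <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  n <- spec$C$activities$n; d <- spec$feature_dim
  with_seed(spec$layout_seed, {
    R <- qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
    U <- rbind(t(R), -t(R))
    if (n > 2L * d) {
      Z <- matrix(stats::rnorm((n - 2L * d) * d), ncol = d)
      U <- rbind(U, Z / sqrt(rowSums(Z^2)))
    }
    M <- spec$delta * U[seq_len(n), , drop = FALSE]
    rownames(M) <- spec$C$activities$labels
    M
  })
}

make_segment <- function(spec, state, t_c) {
  sm <- spec$state_models[[state]]
  L <- as.integer(round(spec$fs * spec$t_w))
  tt <- (seq_len(L) - 1) / spec$fs
  phase <- stats::runif(1, 0, 2 * pi)
  osc <- sm$osc_amp * sin(2 * pi * sm$osc_freq * tt + phase)
  gyr <- sm$gyro_amp * sin(2 * pi * sm$osc_freq * tt + phase)
  acc <- matrix(rep(sm$gravity, each = L), L, 3)
  acc[, 1] <- acc[, 1] + osc
  acc[, 3] <- acc[, 3] + osc / 2
  gy <- matrix(0, L, 3)
  gy[, 2] <- gyr
  samples <- cbind(acc, gy) + matrix(stats::rnorm(L * 6, sd = sm$noise_sd), L, 6)
  colnames(samples) <- SENSOR_CHANNELS
  structure(list(samples = samples, window = window_for_frame(t_c, spec$t_w),
                 pad_flags = rep(FALSE, L), fs = spec$fs),
            class = "sensor_segment")
}

make_payload <- function(spec, mu) {
  d <- spec$feature_dim
  if (spec$regime == "low")
    return(mu + spec$feature_sd * stats::rnorm(d))
  X <- matrix(0, spec$K, d)
  X[1, ] <- mu + spec$feature_sd * stats::rnorm(d)
  sdi <- spec$feature_sd * sqrt(1 - spec$rho^2)
  for (k in seq_len(spec$K)[-1])
    X[k, ] <- mu + spec$rho * (X[k - 1, ] - mu) + sdi * stats::rnorm(d)
  X
}

#' Generate an aligned multimodal dataset
#'
#' Each sample draws an activity from the spec's proportions, a motion
#' state uniformly from the activity's states, a sensor segment from that
#' state's signal model, and an image payload from the activity's feature
#' cluster. Fully reproducible from the seed.
#'
#' @param spec a [generator_spec()].
#' @param n number of samples.
#' @param seed integer seed.
#' @return list with `samples` (each a list `segment`, `payload`,
#'   `activity`, `state`), `spec`, `seed`.
#' @export
generate_dataset <- function(spec, n, seed = 1L) {
  stopifnot(inherits(spec, "generator_spec"), n >= 1)
  M <- cluster_means(spec)
  labs <- spec$C$activities$labels
  spacing <- if (spec$regime == "low") 4 else 1   # frame spacing, seconds
  with_seed(seed, {
    a_idx <- sample.int(length(labs), n, replace = TRUE, prob = spec$proportions)
    samples <- lapply(seq_len(n), function(i) {
      a <- labs[a_idx[i]]
      s <- resample1(states_of(spec$C, a))
      list(segment = make_segment(spec, s, t_c = i * spacing),
           payload = make_payload(spec, M[a, ]),
           activity = a, state = s)
    })
    list(samples = samples, spec = spec, seed = as.integer(seed))
  })
}

#' Generate whole labeled sequences (streams) and their segments
#'
#' Emulates a sequence dataset: each sequence is one activity performed for
#' `duration` seconds; its continuous 6-channel stream is cut by
#' [segment_stream()] into overlapping windows at `dc` spacing, and each
#' window receives a high-rate K-frame payload from the activity's feature
#' cluster.
#'
#' @param spec a high-rate [generator_spec()].
#' @param n_sequences number of sequences (activities cycle through the
#'   activity set so counts are balanced).
#' @param duration sequence length, seconds.
#' @param dc window-center spacing, seconds.
#' @param seed integer seed.
#' @return list with `sequences`; each has `id`, `activity`, `state`,
#'   `samples` (list of aligned samples as in [generate_dataset()]).
#' @export
generate_sequence_dataset <- function(spec, n_sequences, duration = 15,
                                      dc = 1, seed = 1L) {
  stopifnot(inherits(spec, "generator_spec"))
  M <- cluster_means(spec)
  labs <- spec$C$activities$labels
  with_seed(seed, {
    acts <- labs[rep_len(seq_along(labs), n_sequences)]
    seqs <- lapply(seq_len(n_sequences), function(i) {
      a <- acts[i]
      s <- resample1(states_of(spec$C, a))
      sm <- spec$state_models[[s]]
      L <- as.integer(round(spec$fs * duration))
      tt <- (seq_len(L) - 1) / spec$fs
      phase <- stats::runif(1, 0, 2 * pi)
      osc <- sm$osc_amp * sin(2 * pi * sm$osc_freq * tt + phase)
      acc <- matrix(rep(sm$gravity, each = L), L, 3)
      acc[, 1] <- acc[, 1] + osc
      acc[, 3] <- acc[, 3] + osc / 2
      gy <- matrix(0, L, 3)
      gy[, 2] <- sm$gyro_amp * sin(2 * pi * sm$osc_freq * tt + phase)
      ch <- cbind(acc, gy) + matrix(stats::rnorm(L * 6, sd = sm$noise_sd), L, 6)
      stream <- sensor_stream(tt, ch, fs = spec$fs)
      segs <- segment_stream(stream, t_w = spec$t_w, dc = dc)
      samples <- lapply(segs, function(sg)
        list(segment = sg, payload = make_payload(spec, M[a, ]),
             activity = a, state = s))
      list(id = sprintf("seq%04d", i), activity = a, state = s, samples = samples)
    })
    list(sequences = seqs, spec = spec, seed = as.integer(seed))
  })
}

#' Exact activity posterior under the generative model
#'
#' The acceptance oracle: given a sample's payload and/or segment, returns
#' the posterior over activities computed from the known generator
#' parameters. Feature likelihoods are exact (iid Gaussian or AR(1)
#' Gaussian); the oscillation phase of ambulatory sensor models is
#' marginalized numerically over a uniform grid.
#'
#' @param spec a [generator_spec()].
#' @param payload image payload (vector or K x d matrix) or `NULL`.
#' @param segment sensor segment or `NULL`.
#' @param n_phase phase-grid size for the sensor likelihood.
#' @return named posterior probability vector over the activities.
#' @export
bayes_oracle <- function(spec, payload = NULL, segment = NULL, n_phase = 64L) {
  stopifnot(inherits(spec, "generator_spec"))
  labs <- spec$C$activities$labels
  logpost <- log(spec$proportions)
  names(logpost) <- labs
  if (!is.null(payload)) {
    M <- cluster_means(spec)
    ll <- vapply(labs, function(a) feature_loglik(spec, payload, M[a, ]), numeric(1))
    logpost <- logpost + ll
  }
  if (!is.null(segment)) {
    seg_ll <- vapply(spec$C$states$labels, function(s)
      segment_loglik(spec, segment, s, n_phase), numeric(1))
    names(seg_ll) <- spec$C$states$labels
    mix <- vapply(labs, function(a) {
      ss <- states_of(spec$C, a)
      m0 <- max(seg_ll[ss])
      m0 + log(mean(exp(seg_ll[ss] - m0)))
    }, numeric(1))
    logpost <- logpost + mix
  }
  p <- exp(logpost - max(logpost))
  p / sum(p)
}

feature_loglik <- function(spec, payload, mu) {
  if (is.null(dim(payload)))
    return(sum(stats::dnorm(payload, mu, spec$feature_sd, log = TRUE)))
  X <- as.matrix(payload)
  ll <- sum(stats::dnorm(X[1, ], mu, spec$feature_sd, log = TRUE))
  if (nrow(X) > 1) {
    sdi <- spec$feature_sd * sqrt(1 - spec$rho^2)
    for (k in 2:nrow(X))
      ll <- ll + sum(stats::dnorm(X[k, ], mu + spec$rho * (X[k - 1, ] - mu),
                                  sdi, log = TRUE))
  }
  ll
}

segment_loglik <- function(spec, segment, state, n_phase = 64L) {
  sm <- spec$state_models[[state]]
  S <- segment_matrix(segment)
  L <- nrow(S)
  tt <- (seq_len(L) - 1) / spec$fs
  base <- cbind(matrix(rep(sm$gravity, each = L), L, 3), matrix(0, L, 3))
  if (sm$osc_amp == 0) {
    return(sum(stats::dnorm(S - base, 0, sm$noise_sd, log = TRUE)))
  }
  phases <- 2 * pi * (seq_len(n_phase) - 1) / n_phase
  lls <- vapply(phases, function(ph) {
    osc <- sin(2 * pi * sm$osc_freq * tt + ph)
    mean_mat <- base
    mean_mat[, 1] <- mean_mat[, 1] + sm$osc_amp * osc
    mean_mat[, 3] <- mean_mat[, 3] + sm$osc_amp * osc / 2
    mean_mat[, 5] <- mean_mat[, 5] + sm$gyro_amp * osc
    sum(stats::dnorm(S - mean_mat, 0, sm$noise_sd, log = TRUE))
  }, numeric(1))
  m0 <- max(lls)
  m0 + log(mean(exp(lls - m0)))
}

#' Packaged generator presets
#'
#' `"ebutton-like"`: 15 ADLs over 4 posture states (the packaged eButton
#' grouping), low-frame-rate regime, 90 Hz / 3 s windows, frames >= 4 s
#' apart. `"multimodal-like"`: 20 activities under the M6 grouping,
#' high-frame-rate regime (K = 90 correlated frames per 3 s window,
#' 15 s sequences cut at 1 s spacing).
#'
#' @param name `"ebutton-like"` or `"multimodal-like"`.
#' @param ... overrides passed to [generator_spec()].
#' @return a [generator_spec()].
#' @export
preset <- function(name = c("ebutton-like", "multimodal-like"), ...) {
  name <- match.arg(name)
  args <- if (name == "ebutton-like")
    list(C = load_fixture("eButton"), regime = "low")
  else
    list(C = load_fixture("M6"), regime = "high", K = 90L, rho = 0.9)
  do.call(generator_spec, utils::modifyList(args, list(...)))
}
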
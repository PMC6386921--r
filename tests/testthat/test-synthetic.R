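test_that("generation is bitwise reproducible from the seed", {
  spec <- preset("ebutton-like", fs = 30)
  d1 <- generate_dataset(spec, 25, seed = 9)
  d2 <- generate_dataset(spec, 25, seed = 9)
  expect_identical(d1$samples, d2$samples)
  d3 <- generate_dataset(spec, 25, seed = 10)
  expect_false(identical(d1$samples, d3$samples))
  # generation does not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(generate_dataset(spec, 5, seed = 1)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("activity draws follow the requested proportions", {
  # cheap segments (low rate, short window) -- the property is multinomial
  spec <- preset("ebutton-like", fs = 10, t_w = 1)
  ds <- generate_dataset(spec, 10000, seed = 5)
  counts <- table(factor(vapply(ds$samples, `[[`, character(1), "activity"),
                         levels = spec$C$activities$labels))
  # exact multinomial 99% band per cell (Bonferroni across 15 cells)
  alpha <- 0.01 / 15
  band <- qbinom(c(alpha / 2, 1 - alpha / 2), 10000, 1 / 15)
  expect_true(all(counts >= band[1] & counts <= band[2]))
})

test_that("states are drawn only from each activity's own state set", {
  spec <- preset("ebutton-like", fs = 10, t_w = 1)
  ds <- generate_dataset(spec, 400, seed = 6)
  for (s in ds$samples)
    expect_true(s$state %in% states_of(spec$C, s$activity))
})

test_that("within one group, different activities share the sensor distribution", {
  spec <- preset("ebutton-like")
  ds <- generate_dataset(spec, 600, seed = 21)
  acts <- vapply(ds$samples, `[[`, character(1), "activity")
  states <- vapply(ds$samples, `[[`, character(1), "state")
  # two sedentary-group activities, conditioned on the SD state
  mean_az <- function(a) vapply(ds$samples[acts == a & states == "SD"],
                                function(s) mean(s$segment$samples[, 3]), numeric(1))
  x <- mean_az("CU"); y <- mean_az("TV")
  expect_gt(length(x), 10); expect_gt(length(y), 10)
  expect_gt(suppressWarnings(stats::ks.test(x, y)$p.value), 0.01)
})

test_that("ambulatory segments carry their gait line in the spectrum", {
  spec <- preset("ebutton-like")
  ds <- generate_dataset(spec, 120, seed = 22)
  wk <- Filter(function(s) s$state == "WK", ds$samples)
  f_cfg <- spec$state_models$WK$osc_freq
  for (s in wk[1:5]) {
    x <- s$segment$samples[, 1] - mean(s$segment$samples[, 1])
    sp <- stats::spec.pgram(stats::ts(x, frequency = spec$fs), plot = FALSE,
                            taper = 0, detrend = FALSE)
    expect_equal(sp$freq[which.max(sp$spec)], f_cfg, tolerance = 0.15)
  }
})

test_that("the exact posterior matches symmetry and the 1-d closed form", {
  A <- activity_set(c("a", "b")); M <- motion_state_set(c("s1", "s2"))
  Cid <- correspondence(A, M, cbind(c("a", "b"), c("s1", "s2")))
  spec <- generator_spec(Cid, regime = "low", feature_dim = 1, delta = 1.5)
  mu <- cluster_means(spec)
  # equidistant payload: posterior is (1/2, 1/2)
  mid <- (mu[1, ] + mu[2, ]) / 2
  expect_equal(unname(bayes_oracle(spec, payload = mid)), c(0.5, 0.5),
               tolerance = 1e-12)
  # payload at a cluster mean with large separation: posterior ~ 1
  spec_big <- generator_spec(Cid, regime = "low", feature_dim = 4, delta = 12)
  mu_big <- cluster_means(spec_big)
  expect_gt(bayes_oracle(spec_big, payload = mu_big["a", ])["a"], 0.999)
  # Monte-Carlo Bayes accuracy matches Phi(d12 / (2 sd))
  ds <- generate_dataset(spec, 3000, seed = 5)
  pred <- vapply(ds$samples,
                 function(s) names(which.max(bayes_oracle(spec, payload = s$payload))),
                 character(1))
  acc <- mean(pred == vapply(ds$samples, `[[`, character(1), "activity"))
  d12 <- sqrt(sum((mu[1, ] - mu[2, ])^2))
  expect_equal(acc, pnorm(d12 / 2), tolerance = 0.025)
})

test_that("vanishing separation drives the oracle to chance", {
  A <- activity_set(c("a", "b")); M <- motion_state_set("s")
  C1 <- correspondence(A, M, cbind(c("a", "b"), "s"))
  spec0 <- generator_spec(C1, regime = "low", feature_dim = 3, delta = 0)
  ds <- generate_dataset(spec0, 50, seed = 3)
  for (s in ds$samples[1:10])
    expect_equal(unname(bayes_oracle(spec0, payload = s$payload)), c(0.5, 0.5),
                 tolerance = 1e-9)
})

test_that("oracle accuracy grows monotonically with separation", {
  A <- activity_set(c("a", "b")); M <- motion_state_set("s")
  C1 <- correspondence(A, M, cbind(c("a", "b"), "s"))
  accs <- vapply(c(0.5, 1.5, 3), function(dl) {
    spec <- generator_spec(C1, regime = "low", feature_dim = 2, delta = dl,
                           layout_seed = 7)
    ds <- generate_dataset(spec, 1200, seed = 8)
    pred <- vapply(ds$samples,
                   function(s) names(which.max(bayes_oracle(spec, payload = s$payload))),
                   character(1))
    mean(pred == vapply(ds$samples, `[[`, character(1), "activity"))
  }, numeric(1))
  expect_true(all(diff(accs) > 0))
})

test_that("the sensor likelihood identifies the generating state", {
  spec <- preset("ebutton-like")
  ds <- generate_dataset(spec, 40, seed = 31)
  hits <- vapply(ds$samples, function(s) {
    ll <- vapply(spec$C$states$labels,
                 function(st) hierfusar:::segment_loglik(spec, s$segment, st),
                 numeric(1))
    spec$C$states$labels[which.max(ll)] == s$state
  }, logical(1))
  expect_gt(mean(hits), 0.95)
})

test_that("presets encode the two study regimes", {
  eb <- preset("ebutton-like")
  expect_identical(hierarchy_fingerprint(eb$C),
                   hierarchy_fingerprint(load_fixture("eButton")))
  expect_equal(eb$regime, "low")
  expect_equal(eb$fs, 90)
  expect_equal(eb$t_w, 3)
  mm <- preset("multimodal-like")
  expect_identical(hierarchy_fingerprint(mm$C),
                   hierarchy_fingerprint(load_fixture("M6")))
  expect_equal(mm$regime, "high")
  expect_equal(mm$K, 90L)
  # a generated high-rate payload is a K x d frame-feature matrix
  ds <- generate_dataset(generator_spec(mm$C, regime = "high", K = 7,
                                        feature_dim = 5), 3, seed = 1)
  expect_equal(dim(ds$samples[[1]]$payload), c(7L, 5L))
})

test_that("sequence datasets cut each stream into duration/dc windows", {
  mm <- preset("multimodal-like", fs = 30, K = 4L, feature_dim = 3)
  sq <- generate_sequence_dataset(mm, n_sequences = 6, duration = 15, dc = 1,
                                  seed = 2)
  expect_length(sq$sequences, 6L)
  for (s in sq$sequences) {
    expect_length(s$samples, 15L)
    expect_true(all(vapply(s$samples, function(x) nrow(x$segment$samples),
                           integer(1)) == 90L))
    expect_true(s$state %in% states_of(mm$C, s$activity))
  }
})

test_that("generator specs validate their parameters", {
  C <- identity_corr(2)
  expect_error(generator_spec(C, rho = 1), class = "hf_invalid")
  expect_error(generator_spec(C, feature_sd = 0), class = "hf_invalid")
  expect_error(generator_spec(C, proportions = c(1, -1)), class = "hf_invalid")
  expect_error(generator_spec(C, state_models = list(M1 = list())),
               class = "hf_invalid")
})
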
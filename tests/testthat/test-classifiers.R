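test_that("global average pooling equals the per-map mean", {
  expect_equal(gap(list(matrix(c(1, 5, 3, 7), 2), matrix(c(0, 4, 2, 6), 2))),
               c(4, 3))
  expect_equal(gap(array(2.5, c(4, 4, 3))), rep(2.5, 3))
  # 1x1 maps: identity on the channel vector
  expect_equal(gap(array(1:5, c(1, 1, 5))), as.numeric(1:5))
  expect_equal(gap(c(1.5, -2, 7)), c(1.5, -2, 7))
  # brute-force oracle on random tensors
  set.seed(1)
  for (rep in 1:10) {
    H <- sample(1:5, 1); W <- sample(1:5, 1); Cc <- sample(1:4, 1)
    x <- array(rnorm(H * W * Cc), c(H, W, Cc))
    oracle <- vapply(seq_len(Cc), function(c_) sum(x[, , c_]) / (H * W), numeric(1))
    expect_equal(gap(x), oracle, tolerance = 1e-12)
  }
  expect_error(gap(list()), class = "hf_invalid")
  expect_error(gap(list(matrix(0, 2, 2), matrix(0, 3, 3))), class = "hf_invalid")
})

test_that("LSTM backward pass agrees with numerical gradients", {
  set.seed(3)
  T_ <- 3L; B <- 2L; d <- 2L; H <- 3L; K <- 2L
  X <- array(rnorm(T_ * B * d), c(T_, B, d))
  y <- c(1L, 2L)
  par <- hierfusar:::nn_lstm_init(d, H, K, fc_hidden = 4L)
  Y <- hierfusar:::one_hot(y, K)
  loss_fn <- function(p) {
    fwd <- hierfusar:::nn_lstm_forward(p, X, train = TRUE)
    -sum(log(fwd$probs[cbind(1:B, y)])) / B
  }
  fwd <- hierfusar:::nn_lstm_forward(par, X, train = TRUE)
  g <- hierfusar:::nn_lstm_backward(par, X, fwd, Y)
  eps <- 1e-6
  for (nm in names(g)) {
    idx <- seq_len(min(5L, length(par[[nm]])))
    for (i in idx) {
      pp <- par; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- par; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("motion classifier separates motion states on generated data", {
  spec <- preset("ebutton-like")
  tr <- generate_dataset(spec, 800, seed = 7)
  te <- generate_dataset(spec, 300, seed = 8)
  segs <- lapply(tr$samples, `[[`, "segment")
  states <- vapply(tr$samples, `[[`, character(1), "state")
  m <- fit_motion_classifier(segs, states, spec$C$states,
                             config = train_config("ci"), seed = 7)
  P <- predict(m, lapply(te$samples, `[[`, "segment"))
  # rows are probability simplices
  expect_true(all(abs(rowSums(P) - 1) < 1e-6))
  expect_true(all(P >= 0))
  acc <- mean(colnames(P)[apply(P, 1, which.max)] ==
                vapply(te$samples, `[[`, character(1), "state"))
  expect_gt(acc, 0.95)
  # a walking-like segment is confidently routed to WK
  wk_idx <- which(vapply(te$samples, `[[`, character(1), "state") == "WK")[1]
  p1 <- predict_state(m, te$samples[[wk_idx]]$segment)
  expect_equal(names(which.max(p1)), "WK")
  expect_gt(max(p1), 0.9)
})

test_that("training is deterministic given the seed and validates inputs", {
  spec <- preset("ebutton-like")
  tr <- generate_dataset(spec, 60, seed = 2)
  segs <- lapply(tr$samples, `[[`, "segment")
  states <- vapply(tr$samples, `[[`, character(1), "state")
  cfg <- quick_cfg()
  m1 <- fit_motion_classifier(segs, states, spec$C$states, cfg, seed = 5)
  m2 <- fit_motion_classifier(segs, states, spec$C$states, cfg, seed = 5)
  expect_identical(m1$par, m2$par)
  expect_identical(m1$loss, m2$loss)
  # loss history is recorded per epoch
  expect_length(m1$loss, cfg$epochs_motion)
  # single-class data rejected
  one <- which(states == states[1])
  expect_error(fit_motion_classifier(segs[one], states[one], spec$C$states, cfg),
               class = "hf_single_class")
  # label outside the state set rejected
  expect_error(fit_motion_classifier(segs, rep(c("XX", states[1]),
                                               length.out = length(segs)),
                                     spec$C$states, cfg),
               class = "hf_lookup")
  # segment shorter than the pooled training length cannot be coerced
  expect_error(predict(m1, list(matrix(0, 5, 6))), class = "hf_shape")
})

test_that("shuffled labels collapse accuracy to chance", {
  spec <- preset("ebutton-like")
  tr <- generate_dataset(spec, 240, seed = 3)
  te <- generate_dataset(spec, 240, seed = 4)
  segs <- lapply(tr$samples, `[[`, "segment")
  set.seed(99)
  shuffled <- sample(vapply(tr$samples, `[[`, character(1), "state"))
  m <- fit_motion_classifier(segs, shuffled, spec$C$states, quick_cfg(), seed = 5)
  P <- predict(m, lapply(te$samples, `[[`, "segment"))
  acc <- mean(colnames(P)[apply(P, 1, which.max)] ==
                vapply(te$samples, `[[`, character(1), "state"))
  # chance is 1/4; accept the exact binomial 99.9% band
  band <- qbinom(c(5e-4, 1 - 5e-4), 240, 0.25) / 240
  expect_gte(acc, band[1])
  expect_lte(acc, band[2])
})

test_that("group frame head reaches the Bayes bound on an 11-activity group", {
  spec <- preset("ebutton-like", delta = 3)
  C <- spec$C
  sd_group <- group_activities(C, "SD")
  ds <- generate_dataset(spec, 1700, seed = 3)
  acts <- vapply(ds$samples, `[[`, character(1), "activity")
  keep <- which(acts %in% sd_group)
  pays <- lapply(ds$samples[keep], `[[`, "payload")
  labs <- acts[keep]
  n_tr <- floor(length(keep) * 2 / 3)
  fit <- fit_group_frame_classifier(sd_group, pays[1:n_tr], labs[1:n_tr],
                                    config = train_config("ci"), seed = 3)
  hold <- (n_tr + 1):length(keep)
  P <- predict(fit, pays[hold])
  expect_true(all(abs(rowSums(P) - 1) < 1e-6))
  acc <- mean(colnames(P)[apply(P, 1, which.max)] == labs[hold])
  # the exact-posterior oracle on the same held-out payloads bounds what any
  # classifier can do; the trained head must essentially attain it
  oracle_pred <- vapply(pays[hold], function(x) {
    post <- bayes_oracle(spec, payload = x)[sd_group]
    sd_group[which.max(post)]
  }, character(1))
  oracle_acc <- mean(oracle_pred == labs[hold])
  expect_gt(oracle_acc, 0.85)          # delta = 3 regime is strongly separable
  expect_gt(acc, oracle_acc - 0.03)    # head is within a small gap of Bayes
  expect_gt(acc, 0.85)
})

test_that("frame-head training matches an independent multinomial fit", {
  skip_if_not_installed("nnet")
  spec <- preset("ebutton-like", delta = 3)
  wk <- group_activities(spec$C, "WK")
  ds <- generate_dataset(spec, 600, seed = 6)
  acts <- vapply(ds$samples, `[[`, character(1), "activity")
  keep <- which(acts %in% wk)
  F_ <- t(vapply(ds$samples[keep], function(s) s$payload,
                 numeric(spec$feature_dim)))
  labs <- acts[keep]
  fit <- fit_group_frame_classifier(wk, lapply(ds$samples[keep], `[[`, "payload"),
                                    labs, config = train_config("ci"), seed = 6)
  ref <- nnet::multinom(y ~ ., data = data.frame(y = factor(labs, levels = wk), F_),
                        trace = FALSE)
  ours <- colnames(predict(fit, lapply(ds$samples[keep], `[[`, "payload")))[
    apply(predict(fit, lapply(ds$samples[keep], `[[`, "payload")), 1, which.max)]
  theirs <- as.character(predict(ref, newdata = data.frame(F_)))
  expect_gt(mean(ours == theirs), 0.95)
})

test_that("group heads reject singletons and out-of-group labels; extractors stay frozen", {
  cfg <- quick_cfg()
  pays <- lapply(1:20, function(i) rnorm(4))
  expect_error(fit_group_frame_classifier("only", pays, rep("only", 20),
                                          config = cfg),
               class = "hf_singleton_group")
  expect_error(fit_group_sequence_classifier("only", pays, rep("only", 20),
                                             config = cfg),
               class = "hf_singleton_group")
  expect_error(fit_group_frame_classifier(c("a", "b"), pays,
                                          rep(c("a", "z"), 10), config = cfg),
               class = "hf_lookup")
  ex <- passthrough_extractor()
  fp <- extractor_fingerprint(ex)
  fit <- fit_group_frame_classifier(c("a", "b"), pays, rep(c("a", "b"), 10),
                                    extractor = ex, config = cfg, seed = 1)
  expect_identical(extractor_fingerprint(ex), fp)
  expect_identical(fit$extractor_fp, fp)
  # a sequence payload is a type error for the single-frame head
  expect_error(predict_frame(fit, matrix(0, 3, 4)), class = "hf_type")
})

test_that("sequence head uses temporal correlation and is K-flexible", {
  A <- activity_set(c("a", "b", "c"))
  M <- motion_state_set("g")
  Cg <- correspondence(A, M, cbind(c("a", "b", "c"), "g"))
  spec <- generator_spec(Cg, regime = "high", feature_dim = 4, delta = 1,
                         K = 20, rho = 0.8)
  tr <- generate_dataset(spec, 300, seed = 11)
  te <- generate_dataset(spec, 200, seed = 12)
  pays <- lapply(tr$samples, `[[`, "payload")
  labs <- vapply(tr$samples, `[[`, character(1), "activity")
  cfg <- train_config("ci")
  sq <- fit_group_sequence_classifier(c("a", "b", "c"), pays, labs,
                                      config = cfg, seed = 11)
  tep <- lapply(te$samples, `[[`, "payload")
  tel <- vapply(te$samples, `[[`, character(1), "activity")
  Pq <- predict(sq, tep)
  expect_true(all(abs(rowSums(Pq) - 1) < 1e-6))
  acc_seq <- mean(colnames(Pq)[apply(Pq, 1, which.max)] == tel)
  # single-frame classifier on the first frame of each sequence
  fr <- fit_group_frame_classifier(c("a", "b", "c"),
                                   lapply(pays, function(m) m[1, ]), labs,
                                   config = cfg, seed = 11)
  Pf <- predict(fr, lapply(tep, function(m) m[1, ]))
  acc_frame <- mean(colnames(Pf)[apply(Pf, 1, which.max)] == tel)
  expect_gt(acc_seq, acc_frame)
  # constant-repeated frames: order permutation cannot change the output
  fr1 <- tep[[1]][1, ]
  constseq <- matrix(rep(fr1, each = 12), 12)
  p_const <- predict_sequence(sq, constseq)
  p_perm <- predict_sequence(sq, constseq[sample(12), , drop = FALSE])
  expect_equal(p_const, p_perm, tolerance = 1e-12)
  expect_equal(sum(p_const), 1, tolerance = 1e-6)
  # K different from training K is accepted (K >= 1)
  expect_length(predict_sequence(sq, tep[[1]][1:5, ]), 3L)
  expect_length(predict_sequence(sq, matrix(fr1, 1)), 3L)
  expect_error(predict_sequence(sq, list()), class = "hf_invalid")
})

test_that("conv extractor is deterministic and feeds the frame head", {
  ex <- conv_extractor(n_filters = 4, n_layers = 2, seed = 9)
  img <- matrix(seq(0, 1, length.out = 28 * 28), 28)
  f1 <- gap(extract_features(ex, img))
  f2 <- gap(extract_features(conv_extractor(n_filters = 4, n_layers = 2, seed = 9), img))
  expect_identical(f1, f2)
  expect_length(f1, 4L)
  # two image classes rendered as bright top / bright bottom halves
  set.seed(4)
  mk <- function(cls) {
    base <- matrix(0.1, 16, 16)
    if (cls == "top") base[1:8, ] <- 1 else base[9:16, ] <- 1
    base + matrix(rnorm(256, sd = 0.05), 16)
  }
  labs <- rep(c("top", "bottom"), each = 30)
  imgs <- lapply(labs, mk)
  fit <- fit_group_frame_classifier(c("top", "bottom"), imgs[c(TRUE, FALSE)],
                                    labs[c(TRUE, FALSE)], extractor = ex,
                                    config = quick_cfg(epochs_image = 40L), seed = 2)
  hold <- imgs[c(FALSE, TRUE)]
  P <- predict(fit, hold)
  expect_gt(mean(colnames(P)[apply(P, 1, which.max)] == labs[c(FALSE, TRUE)]), 0.9)
})

test_that("train_config exposes the published defaults and rejects junk", {
  cfg <- train_config()
  expect_equal(cfg$learning_rate, 0.001)
  expect_equal(cfg$beta1, 0.9)
  expect_equal(cfg$beta2, 0.99)
  expect_equal(cfg$epochs_motion, 150L)
  expect_equal(cfg$batch_motion, 30L)
  expect_equal(cfg$hidden_motion, 128L)
  expect_equal(cfg$epochs_image, 50L)
  expect_equal(cfg$batch_image, 8L)
  expect_equal(cfg$hidden_seq, 512L)
  expect_equal(cfg$fc_seq, 512L)
  expect_equal(cfg$dropout_seq, 0.7)
  expect_error(train_config(bogus = 1), class = "hf_invalid")
  expect_error(train_config(epochs_motion = 0), class = "hf_invalid")
})
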
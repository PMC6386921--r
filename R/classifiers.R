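# The three classifier contracts of the cascade: the recurrent motion-state
# classifier over 6-channel sensor segments, the per-group single-frame
# classifier (feature extractor + global average pooling + one softmax FC
# layer), and the per-group frame-sequence classifier (per-frame GAP
# features fed through an LSTM and an FC head). All fits are seeded and
# reproducible; predictions are probability simplices over the model's
# class set.

#' Training configuration
#'
#' Defaults are the published recipe: Adam with learning rate 0.001, first
#' and second moment decay 0.9 / 0.99; 150 epochs at batch size 30 for the
#' motion classifier and 50 epochs at batch size 8 for the image heads; 128
#' LSTM hidden units for the motion layer, 512 hidden units plus a 512-unit
#' FC layer with dropout 0.7 for the sequence heads. The `"ci"` profile
#' shrinks epochs and widths and temporally pools sensor segments to 30
#' steps so that the full pipeline trains in seconds on one CPU.
#'
#' @param profile `"full"` (the published recipe, default) or `"ci"`.
#' @param ... named overrides of any field.
#' @return an object of class `train_config`.
#' @export
#' @examples
#' train_config("ci", epochs_motion = 10)
train_config <- function(profile = c("full", "ci"), ...) {
  profile <- match.arg(profile)
  cfg <- list(
    learning_rate = 0.001, beta1 = 0.9, beta2 = 0.99,
    epochs_motion = 150L, batch_motion = 30L, hidden_motion = 128L,
    epochs_image = 50L, batch_image = 8L,
    hidden_seq = 512L, fc_seq = 512L, dropout_seq = 0.7,
    n_steps = NULL,   # temporal pooling of sensor segments (NULL = none)
    profile = profile)
  if (profile == "ci")
    cfg[c("epochs_motion", "hidden_motion", "epochs_image",
          "hidden_seq", "fc_seq", "n_steps")] <-
      list(30L, 32L, 40L, 32L, 32L, 30L)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop_hf("unknown train_config field(s): %s",
                           paste(bad, collapse = ", "), class = "hf_invalid")
  cfg[names(dots)] <- dots
  if (any(unlist(cfg[c("learning_rate", "epochs_motion", "batch_motion",
                       "epochs_image", "batch_image")]) <= 0))
    stop_hf("train_config numeric fields must be positive", class = "hf_invalid")
  structure(cfg, class = "train_config")
}

#' Global average pooling
#'
#' Collapses a stack of spatial feature maps to one value per channel: the
#' spatial mean of each map. Replaces wide fully connected layers after the
#' convolutional stack, so the softmax head has one weight per channel.
#'
#' @param feature_maps either a 3-d array `H x W x C`, a list of equal-size
#'   numeric matrices (one per channel), or a plain numeric vector (treated
#'   as C maps of size 1 x 1, i.e. returned as is).
#' @return numeric vector of length C.
#' @export
#' @examples
#' gap(list(matrix(c(1, 5, 3, 7), 2), matrix(c(0, 4, 2, 6), 2)))
gap <- function(feature_maps) {
  if (is.numeric(feature_maps) && is.null(dim(feature_maps)))
    return(as.numeric(feature_maps))
  if (is.list(feature_maps)) {
    if (length(feature_maps) == 0L) stop_hf("empty feature map set", class = "hf_invalid")
    dims <- vapply(feature_maps, function(m) dim(as.matrix(m)), integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop_hf("feature maps must share the same spatial size", class = "hf_invalid")
    return(vapply(feature_maps, function(m) mean(as.matrix(m)), numeric(1)))
  }
  if (is.array(feature_maps) && length(dim(feature_maps)) == 3L)
    return(apply(feature_maps, 3L, mean))
  stop_hf("unsupported feature map container", class = "hf_invalid")
}

# --- feature extractors ----------------------------------------------------

#' Pass-through feature extractor
#'
#' For payloads that are already feature vectors (the synthetic generator's
#' default, or externally precomputed backbone features): returns the
#' vector unchanged, interpreted as C channels of 1 x 1 maps.
#'
#' @return an object of class `c("passthrough_extractor", "feature_extractor")`.
#' @export
passthrough_extractor <- function() {
  structure(list(kind = "passthrough"),
            class = c("passthrough_extractor", "feature_extractor"))
}

#' Small convolutional feature extractor
#'
#' A seeded stack of 3x3 valid convolutions with ReLU and 2x2 average
#' pooling, producing `n_filters` spatial maps from a grayscale image
#' matrix. The parameters are data members: they are fixed (frozen) during
#' head training, exactly as a pretrained backbone would be, and can be
#' replaced wholesale to plug in externally computed filters.
#'
#' @param n_filters channels per layer (default 8).
#' @param n_layers number of conv+pool layers (default 2).
#' @param seed seed for filter initialization.
#' @return an object of class `c("conv_extractor", "feature_extractor")`.
#' @export
conv_extractor <- function(n_filters = 8L, n_layers = 2L, seed = 1L) {
  filters <- with_seed(seed, lapply(seq_len(n_layers), function(l) {
    cin <- if (l == 1L) 1L else n_filters
    array(stats::rnorm(3 * 3 * cin * n_filters, sd = sqrt(2 / (9 * cin))),
          dim = c(3, 3, cin, n_filters))
  }))
  structure(list(kind = "conv", filters = filters, n_filters = n_filters,
                 n_layers = n_layers, seed = seed),
            class = c("conv_extractor", "feature_extractor"))
}

#' Extract spatial feature maps from a frame payload
#'
#' @param extractor a feature extractor.
#' @param payload a single frame: numeric vector (pass-through) or numeric
#'   matrix / `H x W x 1` array (convolutional).
#' @return feature maps in a form accepted by [gap()].
#' @export
extract_features <- function(extractor, payload) UseMethod("extract_features")

#' @export
extract_features.passthrough_extractor <- function(extractor, payload) {
  if (!is.numeric(payload)) stop_hf("pass-through extractor expects numeric payload",
                                    class = "hf_invalid")
  as.numeric(payload)
}

conv2d_valid <- function(img, kern) {
  # img: H x W x Cin, kern: 3 x 3 x Cin x Cout
  H <- dim(img)[1L]; W <- dim(img)[2L]; cin <- dim(img)[3L]; cout <- dim(kern)[4L]
  Ho <- H - 2L; Wo <- W - 2L
  if (Ho < 1L || Wo < 1L) stop_hf("image too small for 3x3 convolution", class = "hf_invalid")
  # im2col: rows = output pixels, cols = 9 * cin
  cols <- matrix(0, Ho * Wo, 9L * cin)
  k <- 1L
  for (c_ in seq_len(cin)) for (dx in 0:2) for (dy in 0:2) {
    cols[, k] <- as.vector(img[dy + seq_len(Ho), dx + seq_len(Wo), c_])
    k <- k + 1L
  }
  km <- matrix(0, 9L * cin, cout)
  k <- 1L
  for (c_ in seq_len(cin)) for (dx in 0:2) for (dy in 0:2) {
    km[k, ] <- kern[dy + 1L, dx + 1L, c_, ]
    k <- k + 1L
  }
  array(cols %*% km, dim = c(Ho, Wo, cout))
}

avgpool2 <- function(x) {
  H <- dim(x)[1L] %/% 2L; W <- dim(x)[2L] %/% 2L
  if (H < 1L || W < 1L) return(x)
  out <- array(0, dim = c(H, W, dim(x)[3L]))
  for (c_ in seq_len(dim(x)[3L]))
    out[, , c_] <- 0.25 * (x[2 * seq_len(H) - 1, 2 * seq_len(W) - 1, c_] +
                           x[2 * seq_len(H),     2 * seq_len(W) - 1, c_] +
                           x[2 * seq_len(H) - 1, 2 * seq_len(W),     c_] +
                           x[2 * seq_len(H),     2 * seq_len(W),     c_])
  out
}

#' @export
extract_features.conv_extractor <- function(extractor, payload) {
  x <- payload
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!(is.array(x) && length(dim(x)) == 3L))
    stop_hf("conv extractor expects a matrix or H x W x C array", class = "hf_invalid")
  for (l in seq_len(extractor$n_layers)) {
    x <- conv2d_valid(x, extractor$filters[[l]])
    x[] <- pmax(x, 0)  # ReLU
    x <- avgpool2(x)
  }
  x
}

#' Fingerprint of an extractor's parameters
#'
#' Used to assert that head training leaves the (frozen) extractor
#' untouched.
#'
#' @param extractor a feature extractor.
#' @return hex string hash of the serialized parameters.
#' @export
extractor_fingerprint <- function(extractor) {
  fnv1a(paste(utils::capture.output(utils::str(extractor, digits.d = 15)),
              collapse = "\n"))
}

# --- segment tensor plumbing ----------------------------------------------

segment_matrix <- function(seg) {
  if (inherits(seg, "sensor_segment")) seg$samples else as.matrix(seg)
}

# Block-average an L x 6 segment down to n_steps rows (temporal pooling).
pool_segment <- function(mat, n_steps) {
  L <- nrow(mat)
  if (is.null(n_steps) || n_steps >= L) return(mat)
  edges <- floor(seq(0L, L, length.out = n_steps + 1L))
  out <- matrix(0, n_steps, ncol(mat))
  for (i in seq_len(n_steps))
    out[i, ] <- colMeans(mat[(edges[i] + 1L):edges[i + 1L], , drop = FALSE])
  out
}

segments_to_tensor <- function(segments, n_steps) {
  mats <- lapply(segments, function(s) pool_segment(segment_matrix(s), n_steps))
  Ls <- vapply(mats, nrow, integer(1))
  if (length(unique(Ls)) != 1L)
    stop_hf("segments have differing lengths (%s)",
            paste(unique(Ls), collapse = ", "), class = "hf_shape")
  T_ <- Ls[1L]; N <- length(mats); d <- ncol(mats[[1L]])
  X <- array(0, dim = c(T_, N, d))
  for (i in seq_len(N)) X[, i, ] <- mats[[i]]
  X
}

standardize_tensor <- function(X, norm = NULL) {
  d <- dim(X)[3L]
  if (is.null(norm)) {
    mu <- vapply(seq_len(d), function(j) mean(X[, , j]), numeric(1))
    sd_ <- vapply(seq_len(d), function(j) stats::sd(as.vector(X[, , j])), numeric(1))
    sd_[sd_ < 1e-12] <- 1
    norm <- list(mu = mu, sd = sd_)
  }
  for (j in seq_len(d)) X[, , j] <- (X[, , j] - norm$mu[j]) / norm$sd[j]
  list(X = X, norm = norm)
}

# --- motion-state classifier ----------------------------------------------

#' Fit the recurrent motion-state classifier
#'
#' An LSTM over the 6-channel sensor segment followed by a fully connected
#' softmax layer over the motion states. Channels are standardized with
#' training-set statistics; segments may be temporally pooled to
#' `config$n_steps` block means before entering the recurrence.
#'
#' @param segments list of [extract_segment()] results (or plain L x 6
#'   matrices), all the same length.
#' @param labels character vector of motion-state labels, one per segment.
#' @param states a [motion_state_set()] giving the output class order.
#' @param config a [train_config()].
#' @param seed integer seed; recorded in the fit.
#' @return an object of class `motion_classifier` with a
#'   [predict.motion_classifier()] method.
#' @export
fit_motion_classifier <- function(segments, labels, states,
                                  config = train_config(), seed = 1L) {
  stopifnot(inherits(states, "motion_state_set"), inherits(config, "train_config"))
  labels <- as.character(labels)
  if (length(labels) != length(segments))
    stop_hf("labels/segments length mismatch", class = "hf_shape")
  bad <- setdiff(labels, states$labels)
  if (length(bad)) stop_hf("label(s) outside the state set: %s",
                           paste(unique(bad), collapse = ", "), class = "hf_lookup")
  # a one-state set is a legal degenerate hierarchy (the head is constant);
  # otherwise at least two classes must be present
  if (states$m > 1L && length(unique(labels)) < 2L)
    stop_hf("need at least two classes present to train", class = "hf_single_class")
  X <- segments_to_tensor(segments, config$n_steps)
  stz <- standardize_tensor(X)
  y <- match(labels, states$labels)
  icfg <- list(epochs = config$epochs_motion, batch_size = config$batch_motion,
               learning_rate = config$learning_rate,
               beta1 = config$beta1, beta2 = config$beta2)
  fit <- with_seed(seed, nn_train_lstm(stz$X, y, states$m, config$hidden_motion, icfg))
  structure(list(par = fit$par, loss = fit$loss, states = states,
                 norm = stz$norm, n_steps = config$n_steps,
                 seg_len = dim(X)[1L], config = config, seed = seed),
            class = "motion_classifier")
}

#' @export
print.motion_classifier <- function(x, ...) {
  cat(sprintf("Motion-state classifier: LSTM(%d) over %d-step segments -> %d states (%s)\n",
              attr(x$par, "dims")$H, x$seg_len, x$states$m,
              paste(x$states$labels, collapse = ", ")))
  cat(sprintf("  trained %d epochs, final loss %.4f, seed %d\n",
              length(x$loss), x$loss[length(x$loss)], x$seed))
  invisible(x)
}

#' Predict motion-state posteriors
#'
#' @param object a [fit_motion_classifier()] result.
#' @param newdata list of segments (or a single segment).
#' @param ... unused.
#' @return numeric matrix, one row per segment, columns = states; each row
#'   a probability vector.
#' @export
predict.motion_classifier <- function(object, newdata, ...) {
  if (inherits(newdata, "sensor_segment") || is.matrix(newdata))
    newdata <- list(newdata)
  X <- segments_to_tensor(newdata, object$n_steps)
  if (dim(X)[1L] != object$seg_len)
    stop_hf("segment length %d differs from training length %d",
            dim(X)[1L], object$seg_len, class = "hf_shape")
  X <- standardize_tensor(X, object$norm)$X
  P <- nn_predict_lstm(object$par, X)
  colnames(P) <- object$states$labels
  P
}

#' Posterior over motion states for a single segment
#'
#' Convenience wrapper around [predict.motion_classifier()]; the argmax is
#' the grouping index used by the hierarchical recognizer.
#'
#' @param model a `motion_classifier`.
#' @param segment one sensor segment.
#' @return named probability vector over the states.
#' @export
predict_state <- function(model, segment) {
  drop(predict(model, list(segment)))
}

# --- group frame classifier ------------------------------------------------

payload_features <- function(extractor, payloads) {
  t(vapply(payloads, function(p) gap(extract_features(extractor, p)),
           numeric(length(gap(extract_features(extractor, payloads[[1L]]))))))
}

#' Fit a group single-frame activity classifier
#'
#' For a multi-activity motion-state group: frozen feature extractor, GAP,
#' then one fully connected softmax layer over the group's activities (in
#' canonical order). The extractor is not modified by training.
#'
#' @param group character vector of the group's activities (canonical
#'   order), length >= 2; singleton groups are recognized directly at the
#'   motion-state layer and are rejected here.
#' @param payloads list of single-frame payloads.
#' @param labels activity label per payload; must lie inside `group`.
#' @param extractor a feature extractor (frozen).
#' @param config a [train_config()].
#' @param seed integer seed.
#' @return an object of class `group_frame_classifier`.
#' @export
fit_group_frame_classifier <- function(group, payloads, labels,
                                       extractor = passthrough_extractor(),
                                       config = train_config(), seed = 1L) {
  group <- as.character(group)
  if (length(group) < 2L)
    stop_hf("singleton group: the motion layer recognizes it directly; no image head is trained",
            class = "hf_singleton_group")
  labels <- as.character(labels)
  bad <- setdiff(labels, group)
  if (length(bad)) stop_hf("sample labeled outside the group: %s",
                           paste(unique(bad), collapse = ", "), class = "hf_lookup")
  fp_before <- extractor_fingerprint(extractor)
  F_ <- payload_features(extractor, payloads)
  mu <- colMeans(F_); sd_ <- apply(F_, 2, stats::sd); sd_[sd_ < 1e-12] <- 1
  Fz <- sweep(sweep(F_, 2, mu), 2, sd_, "/")
  y <- match(labels, group)
  icfg <- list(epochs = config$epochs_image, batch_size = config$batch_image,
               learning_rate = config$learning_rate,
               beta1 = config$beta1, beta2 = config$beta2)
  fit <- with_seed(seed, nn_train_softmax(Fz, y, length(group), icfg))
  stopifnot(identical(extractor_fingerprint(extractor), fp_before))
  structure(list(par = fit$par, loss = fit$loss, group = group,
                 extractor = extractor, extractor_fp = fp_before,
                 norm = list(mu = mu, sd = sd_), config = config, seed = seed),
            class = "group_frame_classifier")
}

#' Predict group activity posteriors from a single frame
#'
#' @param model a [fit_group_frame_classifier()] result.
#' @param frame one single-frame payload (not a frame sequence).
#' @return named probability vector over the group's activities.
#' @export
predict_frame <- function(model, frame) {
  stopifnot(inherits(model, "group_frame_classifier"))
  if (is.matrix(frame) && inherits(model$extractor, "passthrough_extractor"))
    stop_hf("sequence payload passed to a single-frame classifier", class = "hf_type")
  f <- gap(extract_features(model$extractor, frame))
  fz <- (f - model$norm$mu) / model$norm$sd
  p <- drop(nn_predict_softmax(model$par, matrix(fz, 1)))
  names(p) <- model$group
  p
}

#' @export
predict.group_frame_classifier <- function(object, newdata, ...) {
  if (!is.list(newdata)) newdata <- list(newdata)
  P <- t(vapply(newdata, function(fr) predict_frame(object, fr),
                numeric(length(object$group))))
  colnames(P) <- object$group
  P
}

# --- group sequence classifier --------------------------------------------

sequences_to_tensor <- function(extractor, sequences) {
  feats <- lapply(sequences, function(sq) {
    if (is.matrix(sq)) sq <- lapply(seq_len(nrow(sq)), function(i) sq[i, ])
    if (!is.list(sq) || length(sq) < 1L)
      stop_hf("empty frame sequence", class = "hf_invalid")
    t(vapply(sq, function(fr) gap(extract_features(extractor, fr)),
             numeric(length(gap(extract_features(extractor, sq[[1L]]))))))
  })
  Ks <- vapply(feats, nrow, integer(1))
  if (length(unique(Ks)) != 1L)
    stop_hf("sequences have differing lengths within one batch", class = "hf_shape")
  K <- Ks[1L]; N <- length(feats); d <- ncol(feats[[1L]])
  X <- array(0, dim = c(K, N, d))
  for (i in seq_len(N)) X[, i, ] <- feats[[i]]
  X
}

#' Fit a group frame-sequence activity classifier
#'
#' For high-frame-rate photo streams: per-frame features (extractor + GAP)
#' are fed through an LSTM; the final state passes through a fully
#' connected layer with dropout and a softmax over the group's activities.
#'
#' @param group character vector of the group's activities, length >= 2.
#' @param sequences list of frame sequences; each either a `K x d` feature
#'   matrix (rows = frames) or a list of frame payloads. K >= 1 and may
#'   differ between fit and predict calls.
#' @param labels activity label per sequence, inside `group`.
#' @param extractor a feature extractor (frozen).
#' @param config a [train_config()].
#' @param seed integer seed.
#' @return an object of class `group_sequence_classifier`.
#' @export
fit_group_sequence_classifier <- function(group, sequences, labels,
                                          extractor = passthrough_extractor(),
                                          config = train_config(), seed = 1L) {
  group <- as.character(group)
  if (length(group) < 2L)
    stop_hf("singleton group: no sequence head is trained", class = "hf_singleton_group")
  labels <- as.character(labels)
  bad <- setdiff(labels, group)
  if (length(bad)) stop_hf("sample labeled outside the group: %s",
                           paste(unique(bad), collapse = ", "), class = "hf_lookup")
  fp_before <- extractor_fingerprint(extractor)
  X <- sequences_to_tensor(extractor, sequences)
  stz <- standardize_tensor(X)
  y <- match(labels, group)
  icfg <- list(epochs = config$epochs_image, batch_size = config$batch_image,
               learning_rate = config$learning_rate,
               beta1 = config$beta1, beta2 = config$beta2)
  fit <- with_seed(seed, nn_train_lstm(stz$X, y, length(group), config$hidden_seq,
                                       icfg, fc_hidden = config$fc_seq,
                                       dropout = config$dropout_seq))
  stopifnot(identical(extractor_fingerprint(extractor), fp_before))
  structure(list(par = fit$par, loss = fit$loss, group = group,
                 extractor = extractor, extractor_fp = fp_before,
                 norm = stz$norm, config = config, seed = seed),
            class = "group_sequence_classifier")
}

#' Predict group activity posteriors from a frame sequence
#'
#' @param model a [fit_group_sequence_classifier()] result.
#' @param frames one sequence: `K x d` feature matrix or list of frames.
#' @return named probability vector over the group's activities.
#' @export
predict_sequence <- function(model, frames) {
  stopifnot(inherits(model, "group_sequence_classifier"))
  X <- sequences_to_tensor(model$extractor, list(frames))
  X <- standardize_tensor(X, model$norm)$X
  p <- drop(nn_predict_lstm(model$par, X))
  names(p) <- model$group
  p
}

#' @export
predict.group_sequence_classifier <- function(object, newdata, ...) {
  if (!is.list(newdata)) newdata <- list(newdata)
  X <- sequences_to_tensor(object$extractor, newdata)
  X <- standardize_tensor(X, object$norm)$X
  P <- nn_predict_lstm(object$par, X)
  colnames(P) <- object$group
  P
}
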
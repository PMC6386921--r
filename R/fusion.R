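# Hierarchical recognition: the motion-state classifier routes each sensor
# window to its most probable group; singleton groups are emitted directly,
# multi-activity groups are resolved by that group's image classifier
# (single frame for low-frame-rate streams, frame sequence for
# high-frame-rate streams). The direct-fusion baseline instead pools flat
# per-modality softmax outputs over the full activity set.

#' Bundle the trained models of the hierarchical recognizer
#'
#' @param C a [correspondence()].
#' @param motion_model a [fit_motion_classifier()] result over `C`'s states.
#' @param group_models named list of group classifiers, one per
#'   multi-activity state (`group_frame_classifier` for `ips = "L"`,
#'   `group_sequence_classifier` for `ips = "H"`). Singleton states need no
#'   model.
#' @param ips frame-rate indicator: `"L"` (low; single frame per window) or
#'   `"H"` (high; frame sequence per window).
#' @return an object of class `hier_recognizer`.
#' @export
hier_recognizer <- function(C, motion_model, group_models, ips = c("L", "H")) {
  ips <- match.arg(ips)
  stopifnot(inherits(C, "correspondence"), inherits(motion_model, "motion_classifier"))
  if (!identical(motion_model$states$labels, C$states$labels))
    stop_hf("motion model states disagree with the correspondence", class = "hf_invalid")
  multi <- setdiff(C$states$labels, singleton_groups(C))
  missing <- setdiff(multi, names(group_models))
  if (length(missing))
    stop_hf("missing group model for multi-activity group(s): %s",
            paste(missing, collapse = ", "), class = "hf_config")
  want <- if (ips == "L") "group_frame_classifier" else "group_sequence_classifier"
  for (s in multi) {
    gm <- group_models[[s]]
    if (!inherits(gm, want))
      stop_hf("group model for '%s' must be a %s under ips = %s", s, want, ips,
              class = "hf_config")
    if (!identical(gm$group, group_activities(C, s)))
      stop_hf("group model for '%s' covers a different activity list", s,
              class = "hf_config")
  }
  structure(list(C = C, motion_model = motion_model,
                 group_models = group_models[multi], ips = ips,
                 fingerprint = hierarchy_fingerprint(C)),
            class = "hier_recognizer")
}

#' @export
print.hier_recognizer <- function(x, ...) {
  cat(sprintf("Hierarchical recognizer (ips = %s): %d activities, %d groups (%d with image heads)\n",
              x$ips, x$C$activities$n, x$C$states$m, length(x$group_models)))
  cat(sprintf("  hierarchy fingerprint %s\n", x$fingerprint))
  invisible(x)
}

#' Hierarchically recognize one aligned sample
#'
#' Step 1: the motion posterior over the states is computed from the sensor
#' segment and its argmax selects the group `j` (ties break to the lowest
#' canonical index). Step 2: if group `j` is a singleton its only activity
#' is emitted with no image model consulted; otherwise the group's image
#' classifier scores the payload and its argmax, mapped through the
#' canonical activity order, gives the global activity index.
#'
#' @param bundle a [hier_recognizer()].
#' @param sample list with `segment` (sensor segment) and `payload` (single
#'   frame for `ips = "L"`, frame sequence for `ips = "H"`; may be `NULL`
#'   for singleton routes).
#' @return an object of class `activity_prediction`: list with `activity`,
#'   `k` (global index), `group`, `motion_posterior`, `group_posterior`
#'   (`NULL` on singleton routes).
#' @export
hierarchical_recognize <- function(bundle, sample) {
  stopifnot(inherits(bundle, "hier_recognizer"))
  mp <- predict_state(bundle$motion_model, sample$segment)
  j <- which.max(mp)                       # ties: lowest canonical index
  state <- bundle$C$states$labels[j]
  acts <- group_activities(bundle$C, state)
  if (length(acts) == 1L) {
    activity <- acts
    gp <- NULL
  } else {
    gm <- bundle$group_models[[state]]
    gp <- if (bundle$ips == "L") predict_frame(gm, sample$payload)
          else predict_sequence(gm, sample$payload)
    activity <- acts[which.max(gp)]
  }
  structure(list(activity = activity,
                 k = match(activity, bundle$C$activities$labels),
                 group = state, motion_posterior = mp, group_posterior = gp),
            class = "activity_prediction")
}

#' @export
print.activity_prediction <- function(x, ...) {
  cat(sprintf("activity %s (index %d) via group %s%s\n", x$activity, x$k, x$group,
              if (is.null(x$group_posterior)) " [singleton: IMU only]" else ""))
  invisible(x)
}

#' Predict activities for a list of aligned samples
#'
#' Batched equivalent of calling [hierarchical_recognize()] on every
#' sample: motion posteriors are computed in one pass, samples are routed
#' to their argmax groups, and each group's image classifier scores its
#' routed samples together.
#'
#' @param object a [hier_recognizer()].
#' @param newdata list of aligned samples (each with `segment`, `payload`).
#' @param ... unused.
#' @return data.frame with columns `activity`, `k`, `group`.
#' @export
predict.hier_recognizer <- function(object, newdata, ...) {
  MP <- predict(object$motion_model, lapply(newdata, `[[`, "segment"))
  j <- apply(MP, 1L, which.max)
  state <- object$C$states$labels[j]
  activity <- character(length(newdata))
  for (s in unique(state)) {
    rows <- which(state == s)
    acts <- group_activities(object$C, s)
    if (length(acts) == 1L) {
      activity[rows] <- acts
    } else {
      gm <- object$group_models[[s]]
      GP <- predict(gm, lapply(newdata[rows], `[[`, "payload"))
      activity[rows] <- acts[apply(GP, 1L, which.max)]
    }
  }
  data.frame(activity = activity,
             k = match(activity, object$C$activities$labels),
             group = state, stringsAsFactors = FALSE)
}

#' Direct softmax fusion of per-modality posteriors
#'
#' The baseline fusion: all modalities classify the full activity set and
#' their softmax outputs are pooled elementwise. Average pooling keeps a
#' probability simplex; maximum pooling is renormalized to sum to one
#' (which leaves the argmax unchanged).
#'
#' @param posteriors list of probability vectors of equal length over the
#'   same activity order.
#' @param mode `"avg"` or `"max"`.
#' @return fused probability vector.
#' @export
#' @examples
#' direct_fuse(list(c(0.6, 0.4), c(0.2, 0.8)), "avg")
direct_fuse <- function(posteriors, mode = c("avg", "max")) {
  mode <- match.arg(mode)
  stopifnot(is.list(posteriors), length(posteriors) >= 1L)
  n <- length(posteriors[[1L]])
  if (any(vapply(posteriors, length, integer(1)) != n))
    stop_hf("posterior length mismatch", class = "hf_shape")
  P <- do.call(rbind, posteriors)
  fused <- if (mode == "avg") colMeans(P) else {
    mx <- apply(P, 2L, max)
    mx / sum(mx)
  }
  if (!is.null(names(posteriors[[1L]]))) names(fused) <- names(posteriors[[1L]])
  fused
}

#' Flat (single-modality) recognition over the full activity set
#'
#' Comparison arm: one classifier scores all `n` activities directly. The
#' sensor arm reuses the recurrent segment classifier with the activity set
#' standing in for the state set; the image arm is the degenerate
#' one-group case of the group classifiers.
#'
#' @param model a `motion_classifier` (fit on activity labels), a
#'   `group_frame_classifier` or `group_sequence_classifier` whose group is
#'   the full activity set.
#' @param sample aligned sample (list with `segment` and/or `payload`).
#' @return an `activity_prediction` with `group = NA` and the flat
#'   posterior in `motion_posterior` or `group_posterior` by modality.
#' @export
flat_recognize <- function(model, sample) {
  if (inherits(model, "motion_classifier")) {
    p <- predict_state(model, sample$segment)
    labs <- model$states$labels
    structure(list(activity = labs[which.max(p)], k = which.max(p),
                   group = NA_character_, motion_posterior = p,
                   group_posterior = NULL),
              class = "activity_prediction")
  } else if (inherits(model, "group_frame_classifier")) {
    p <- predict_frame(model, sample$payload)
    structure(list(activity = model$group[which.max(p)], k = which.max(p),
                   group = NA_character_, motion_posterior = NULL,
                   group_posterior = p),
              class = "activity_prediction")
  } else if (inherits(model, "group_sequence_classifier")) {
    p <- predict_sequence(model, sample$payload)
    structure(list(activity = model$group[which.max(p)], k = which.max(p),
                   group = NA_character_, motion_posterior = NULL,
                   group_posterior = p),
              class = "activity_prediction")
  } else stop_hf("unsupported flat model class", class = "hf_invalid")
}
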
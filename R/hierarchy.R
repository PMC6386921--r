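# Activity / motion-state hierarchy: the many-to-many correspondence between
# the activity set A = {A1..An} and the motion-state set M = {M1..Mm}, whose
# inverse images C^-1(Mj) are the activity groups of the coarse-to-fine
# cascade. The canonical order of A is fixed at construction and defines the
# global activity indexing used by every classifier head.

#' Construct an activity set
#'
#' @param labels character vector of unique activity identifiers. The order
#'   is canonical: it fixes the global activity index used throughout the
#'   package (group-local classifier outputs are mapped back through it).
#' @return an object of class `activity_set`.
#' @export
#' @examples
#' activity_set(c("CU", "ET", "NP"))
activity_set <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 1L) stop_hf("activity set must be non-empty", class = "hf_invalid")
  if (anyDuplicated(labels))
    stop_hf("duplicate activity labels: %s",
            paste(unique(labels[duplicated(labels)]), collapse = ", "),
            class = "hf_invalid")
  structure(list(labels = labels, n = length(labels)), class = "activity_set")
}

#' Construct a motion-state set
#'
#' @param labels character vector of unique motion-state identifiers, in
#'   canonical order.
#' @return an object of class `motion_state_set`.
#' @export
motion_state_set <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 1L) stop_hf("motion-state set must be non-empty", class = "hf_invalid")
  if (anyDuplicated(labels))
    stop_hf("duplicate motion-state labels: %s",
            paste(unique(labels[duplicated(labels)]), collapse = ", "),
            class = "hf_invalid")
  structure(list(labels = labels, m = length(labels)), class = "motion_state_set")
}

#' Build a validated activity/motion-state correspondence
#'
#' Links every activity to the motion states in which it can occur. A
#' single-state-per-activity correspondence is an ordinary mapping whose
#' inverse images partition the activity set; allowing several states per
#' activity generalizes it to a many-to-many correspondence whose groups
#' overlap and whose group sizes sum to more than `n`.
#'
#' @param activities an [activity_set()].
#' @param states a [motion_state_set()].
#' @param pairs two-column character matrix or data.frame
#'   `(activity, state)`, one row per link.
#' @return an object of class `correspondence`.
#' @details Validation is strict: an activity linked to no state is an error
#'   (the hierarchical recognizer could never emit it), as is any label
#'   absent from its set. States with no activities are also rejected.
#' @export
#' @examples
#' A <- activity_set(c("a", "b"))
#' M <- motion_state_set(c("s1", "s2"))
#' C <- correspondence(A, M, cbind(c("a", "b", "b"), c("s1", "s1", "s2")))
#' group_activities(C, "s1")
correspondence <- function(activities, states, pairs) {
  stopifnot(inherits(activities, "activity_set"), inherits(states, "motion_state_set"))
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop_hf("pairs must have two columns", class = "hf_invalid")
  pairs <- matrix(as.character(pairs), ncol = 2L,
                  dimnames = list(NULL, c("activity", "state")))
  bad_a <- setdiff(pairs[, 1L], activities$labels)
  if (length(bad_a))
    stop_hf("unknown activity label(s) in pairs: %s",
            paste(bad_a, collapse = ", "), class = "hf_lookup")
  bad_s <- setdiff(pairs[, 2L], states$labels)
  if (length(bad_s))
    stop_hf("unknown motion-state label(s) in pairs: %s",
            paste(bad_s, collapse = ", "), class = "hf_lookup")
  pairs <- unique(pairs)
  uncovered <- setdiff(activities$labels, pairs[, 1L])
  if (length(uncovered))
    stop_hf("activity not covered by any motion state: %s",
            paste(uncovered, collapse = ", "), class = "hf_coverage")
  empty <- setdiff(states$labels, pairs[, 2L])
  if (length(empty))
    stop_hf("motion state with empty group: %s",
            paste(empty, collapse = ", "), class = "hf_coverage")
  obj <- structure(list(activities = activities, states = states, pairs = pairs),
                   class = "correspondence")
  if (is_function_correspondence(obj) && states$m > activities$n)
    stop_hf("more states than activities in a single-state correspondence",
            class = "hf_invalid")
  obj
}

#' @export
print.correspondence <- function(x, ...) {
  cat(sprintf("Activity/motion-state correspondence: %d activities, %d states\n",
              x$activities$n, x$states$m))
  ns <- group_sizes(x)
  for (s in x$states$labels)
    cat(sprintf("  %-10s (%2d): %s\n", s, ns$sizes[[s]],
                paste(group_activities(x, s), collapse = ", ")))
  cat(sprintf("  total group size %d (n = %d)%s\n", ns$total, x$activities$n,
              if (ns$total == x$activities$n) " [single-state mapping]" else ""))
  invisible(x)
}

#' Activities of a motion-state group
#'
#' The inverse image `C^-1(state)`: all activities that can occur in the
#' given motion state, in the canonical activity order.
#'
#' @param C a [correspondence()].
#' @param state a motion-state label.
#' @return character vector of activity labels.
#' @export
group_activities <- function(C, state) {
  stopifnot(inherits(C, "correspondence"))
  if (!state %in% C$states$labels)
    stop_hf("unknown motion state: %s", state, class = "hf_lookup")
  acts <- C$pairs[C$pairs[, "state"] == state, "activity"]
  C$activities$labels[C$activities$labels %in% acts]
}

#' Motion states of an activity
#'
#' @param C a [correspondence()].
#' @param activity an activity label.
#' @return character vector of state labels (canonical state order).
#' @export
states_of <- function(C, activity) {
  stopifnot(inherits(C, "correspondence"))
  if (!activity %in% C$activities$labels)
    stop_hf("unknown activity: %s", activity, class = "hf_lookup")
  sts <- C$pairs[C$pairs[, "activity"] == activity, "state"]
  C$states$labels[C$states$labels %in% sts]
}

#' Group sizes of a correspondence
#'
#' Per-state group sizes `n_i` (in canonical state order) and their total.
#' The total equals `n` exactly when every activity has a single motion
#' state, and exceeds `n` as soon as any activity is multi-state.
#'
#' @param C a [correspondence()].
#' @return list with `sizes` (named integer vector) and `total`.
#' @export
group_sizes <- function(C) {
  stopifnot(inherits(C, "correspondence"))
  sizes <- vapply(C$states$labels,
                  function(s) length(group_activities(C, s)), integer(1))
  list(sizes = sizes, total = sum(sizes))
}

#' States whose group holds exactly one activity
#'
#' Singleton groups are recognized directly at the motion-state layer: the
#' IMU alone identifies the activity and no image classifier is consulted.
#'
#' @param C a [correspondence()].
#' @return character vector of state labels.
#' @export
singleton_groups <- function(C) {
  gs <- group_sizes(C)$sizes
  names(gs)[gs == 1L]
}

#' Is the correspondence an ordinary (single-state) mapping?
#'
#' @param C a [correspondence()].
#' @return `TRUE` iff every activity is linked to exactly one state, in
#'   which case the groups partition the activity set.
#' @export
is_function_correspondence <- function(C) {
  stopifnot(inherits(C, "correspondence"))
  all(table(C$pairs[, "activity"]) == 1L)
}

#' Fingerprint of a hierarchy
#'
#' Stable short hash of the canonical serialization (labels in order plus
#' sorted pairs); every artifact written by an experiment carries it so that
#' mixed-hierarchy model banks are detected.
#'
#' @param C a [correspondence()].
#' @return 8-character hex string.
#' @export
hierarchy_fingerprint <- function(C) {
  stopifnot(inherits(C, "correspondence"))
  p <- C$pairs[order(C$pairs[, 1L], C$pairs[, 2L]), , drop = FALSE]
  fnv1a(paste(c(C$activities$labels, "|", C$states$labels, "|",
                t(p)), collapse = "\x1f"))
}

#' Read a hierarchy configuration file
#'
#' The file is YAML with three keys: `activities` (ordered list),
#' `motion_states` (ordered list) and `correspondence` (map from state to
#' list of activities). Packaged grouping fixtures use this format.
#'
#' @param path path to a YAML hierarchy file.
#' @return a [correspondence()].
#' @export
read_hierarchy <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (k in c("activities", "motion_states", "correspondence"))
    if (is.null(cfg[[k]]))
      stop_hf("hierarchy file missing '%s' section: %s", k, path, class = "hf_invalid")
  A <- activity_set(unlist(cfg$activities))
  M <- motion_state_set(names(cfg$correspondence))
  if (!identical(sort(M$labels), sort(as.character(unlist(cfg$motion_states)))))
    stop_hf("correspondence states disagree with motion_states list in %s",
            path, class = "hf_invalid")
  M <- motion_state_set(as.character(unlist(cfg$motion_states)))
  pairs <- do.call(rbind, lapply(names(cfg$correspondence), function(s)
    cbind(as.character(unlist(cfg$correspondence[[s]])), s)))
  correspondence(A, M, pairs)
}

#' Write a hierarchy configuration file
#'
#' @param C a [correspondence()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(C, path) {
  stopifnot(inherits(C, "correspondence"))
  corr <- lapply(C$states$labels, function(s) group_activities(C, s))
  names(corr) <- C$states$labels
  yaml::write_yaml(list(activities = C$activities$labels,
                        motion_states = C$states$labels,
                        correspondence = corr), path)
  invisible(path)
}

#' Load a packaged grouping fixture
#'
#' Ships the published groupings: `"eButton"` (15 ADLs over the four
#' posture states lying/sedentary/standing/walking) and the Google-Glass
#' lifelogging groupings `"M5"`--`"M8"` (20 activities over 5--8 merged
#' motion states; `"M6"` is the grouping adopted for that dataset's final
#' evaluation).
#'
#' @param name one of `"eButton"`, `"M5"`, `"M6"`, `"M7"`, `"M8"`.
#' @return a [correspondence()].
#' @export
#' @examples
#' C <- load_fixture("eButton")
#' group_activities(C, "LY")
load_fixture <- function(name) {
  known <- c("eButton", "M5", "M6", "M7", "M8")
  if (!name %in% known)
    stop_hf("unknown fixture '%s' (known: %s)", name,
            paste(known, collapse = ", "), class = "hf_lookup")
  path <- system.file("extdata", "hierarchies", paste0(tolower(name), ".yaml"),
                      package = "hierfusar", mustWork = TRUE)
  read_hierarchy(path)
}
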
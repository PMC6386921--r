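# Evaluation: confusion matrices, one-vs-rest precision / recall / F1 per
# class with unweighted macro averages, and the leave-one-sequence-out
# split protocol used for sequence datasets without a designated test set.

#' Confusion matrix
#'
#' @param true,pred equal-length label vectors.
#' @param classes class labels fixing row/column order.
#' @return integer matrix of class `confusion_matrix`; rows = true class,
#'   columns = predicted class.
#' @export
confusion_matrix <- function(true, pred, classes) {
  true <- as.character(true); pred <- as.character(pred)
  if (length(true) != length(pred))
    stop_hf("true/pred length mismatch", class = "hf_shape")
  bad <- setdiff(c(true, pred), classes)
  if (length(bad)) stop_hf("label(s) outside the class set: %s",
                           paste(unique(bad), collapse = ", "), class = "hf_lookup")
  cm <- table(factor(true, levels = classes), factor(pred, levels = classes))
  m <- matrix(as.integer(cm), length(classes), length(classes),
              dimnames = list(true = classes, pred = classes))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Per-class precision, recall and F1 from a confusion matrix
#'
#' One-vs-rest: for class i, `TP = cm[i,i]`, `FP = colSums - TP`,
#' `FN = rowSums - TP`; `F1 = 2PR/(P+R)`. Any `0/0` is reported as 0
#' (absent or never-predicted classes). Macro values are unweighted means.
#'
#' @param cm a [confusion_matrix()].
#' @return object of class `class_report`: list with `per_class`
#'   (data.frame: class, precision, recall, f1) and `macro` (named vector).
#' @export
f1_report <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  P <- safe_div(tp, tp + fp)
  R <- safe_div(tp, tp + fn)
  F1 <- safe_div(2 * P * R, P + R)
  per <- data.frame(class = rownames(cm), precision = unname(P),
                    recall = unname(R), f1 = unname(F1),
                    stringsAsFactors = FALSE)
  structure(list(per_class = per,
                 macro = c(precision = mean(P), recall = mean(R), f1 = mean(F1)),
                 accuracy = sum(tp) / max(sum(cm), 1L)),
            class = "class_report")
}

#' @export
print.class_report <- function(x, ...) {
  print(x$per_class, row.names = FALSE, digits = 4)
  cat(sprintf("macro P %.4f  R %.4f  F1 %.4f   accuracy %.4f\n",
              x$macro["precision"], x$macro["recall"], x$macro["f1"], x$accuracy))
  invisible(x)
}

#' Leave-one-sequence-out split protocol
#'
#' Partitions sequences into `k` splits such that every test split holds
#' exactly one sequence per activity (the protocol for a dataset of `k`
#' sequences per activity: e.g. 20 activities x 10 sequences -> 10 test
#' splits of 20). Assignment within each activity is a seeded shuffle.
#' Activities with more than `k` sequences keep the surplus in every
#' training split.
#'
#' @param sequence_activity named character vector: names = sequence ids,
#'   values = activity labels.
#' @param k number of splits.
#' @param seed seed for the shuffle.
#' @return list of `k` lists with `train` and `test` sequence-id vectors.
#' @export
loocv_splits <- function(sequence_activity, k, seed = 1L) {
  acts <- split(names(sequence_activity), as.character(sequence_activity))
  short <- names(acts)[vapply(acts, length, integer(1)) < k]
  if (length(short))
    stop_hf("activity with fewer than k sequences: %s",
            paste(short, collapse = ", "), class = "hf_invalid")
  assign_tab <- with_seed(seed, lapply(acts, function(ids) sample(ids)[seq_len(k)]))
  all_ids <- names(sequence_activity)
  lapply(seq_len(k), function(i) {
    test <- unname(vapply(assign_tab, `[`, character(1), i))
    list(train = setdiff(all_ids, test), test = test)
  })
}

#' Average class reports over splits
#'
#' Elementwise mean of per-class precision/recall/F1 and macro values.
#'
#' @param reports list of [f1_report()] results over the same class set.
#' @return a `class_report`.
#' @export
average_reports <- function(reports) {
  stopifnot(length(reports) >= 1L)
  cls <- reports[[1L]]$per_class$class
  for (r in reports)
    if (!identical(r$per_class$class, cls))
      stop_hf("reports cover different class sets", class = "hf_invalid")
  per <- reports[[1L]]$per_class
  for (col in c("precision", "recall", "f1"))
    per[[col]] <- rowMeans(vapply(reports, function(r) r$per_class[[col]],
                                  numeric(length(cls))))
  macro <- rowMeans(vapply(reports, `[[`, numeric(3), "macro"))
  names(macro) <- c("precision", "recall", "f1")
  structure(list(per_class = per, macro = macro,
                 accuracy = mean(vapply(reports, `[[`, numeric(1), "accuracy"))),
            class = "class_report")
}

#' Write a confusion matrix as labeled CSV
#' @param cm a [confusion_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_confusion_csv <- function(cm, path) {
  utils::write.csv(as.data.frame(unclass(cm)), path, row.names = TRUE)
  invisible(path)
}
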
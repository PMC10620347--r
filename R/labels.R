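#' The five strategy classes
#'
#' Labels for caregiver-strategy records. `ENV` (environment/context) is the
#' extrinsic class; `SELF` (sense of self), `PREF` (preferences) and `COMP`
#' (activity competence) are the intrinsic classes; `NONSTRAT` marks records
#' that do not describe a strategy at all.
#'
#' @return Character vector of the five class labels, in canonical order.
#' @export
#' @examples
#' strategy_classes()
strategy_classes <- function() {
  c("ENV", "SELF", "PREF", "COMP", "NONSTRAT")
}

#' @rdname strategy_classes
#' @return `intrinsic_classes()`: the three intrinsic class labels.
#' @export
intrinsic_classes <- function() {
  c("SELF", "PREF", "COMP")
}

#' Map five-class gold labels onto one of the four task label schemes
#'
#' The pipeline is run as four tasks: (1) strategy vs non-strategy over all
#' records; (2) extrinsic vs intrinsic over strategy records only; (3) the
#' three intrinsic constructs over intrinsic records only; (4) flat
#' five-class. Records outside a task's domain map to `"EXCLUDED"`.
#'
#' @param labels Character vector of five-class labels
#'   (see [strategy_classes()]).
#' @param task Integer task id in 1:4.
#' @return Character vector of task labels; `"EXCLUDED"` for records the
#'   task does not cover.
#' @export
#' @examples
#' task_labels(c("ENV", "SELF", "NONSTRAT"), task = 2)
task_labels <- function(labels, task) {
  stopifnot(length(task) == 1L, task %in% 1:4)
  known <- strategy_classes()
  bad <- setdiff(unique(labels), known)
  if (length(bad) > 0L) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "))
  }
  switch(as.character(task),
    "1" = ifelse(labels == "NONSTRAT", "NONSTRAT", "STRATEGY"),
    "2" = ifelse(labels == "NONSTRAT", "EXCLUDED",
                 ifelse(labels == "ENV", "EXTRINSIC", "INTRINSIC")),
    "3" = ifelse(labels %in% intrinsic_classes(), labels, "EXCLUDED"),
    "4" = labels
  )
}

#' @rdname task_labels
#' @return `task_classes()`: the gold classes of a task, in the order used
#'   for macro-averaging and tie-breaking.
#' @export
task_classes <- function(task) {
  stopifnot(length(task) == 1L, task %in% 1:4)
  switch(as.character(task),
    "1" = c("NONSTRAT", "STRATEGY"),
    "2" = c("EXTRINSIC", "INTRINSIC"),
    "3" = sort(intrinsic_classes()),
    "4" = sort(strategy_classes())
  )
}
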
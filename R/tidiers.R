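# broom-style tidiers for the fitted result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a label-transfer result
#'
#' @param x A `transfer_result`.
#' @param ... Unused.
#' @return The per-cell tibble of labels, confidences and pass flags.
#' @export
tidy.transfer_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "transfer_result")
  for (a in c("anchors", "joint_ref", "joint_meas", "gates"))
    attr(out, a) <- NULL
  as_tibble(out)
}

#' One-row summary of a label-transfer result
#'
#' @param x A `transfer_result`.
#' @param ... Unused.
#' @return Tibble with cell counts, pass rates and mean confidences.
#' @export
glance.transfer_result <- function(x, ...) {
  tibble(n_cells = nrow(x),
         n_anchors = nrow(attr(x, "anchors") %||% tibble()),
         subclass_pass_rate = mean(x$subclass_pass, na.rm = TRUE),
         cluster_pass_rate = mean(x$cluster_pass, na.rm = TRUE),
         mean_subclass_confidence = mean(x$subclass_confidence, na.rm = TRUE),
         mean_cluster_confidence = mean(x$cluster_confidence, na.rm = TRUE))
}

#' Tidy an interaction-calls object
#'
#' @param x An `interaction_calls` from [call_pipeline()].
#' @param ... Unused.
#' @return The full per-pair interaction table (both modes).
#' @export
tidy.interaction_calls <- function(x, ...) as_tibble(x$interactions)

#' One-row summary of an interaction-calls object
#'
#' @param x An `interaction_calls`.
#' @param ... Unused.
#' @return Tibble with tested/called pair counts and LR hit counts.
#' @export
glance.interaction_calls <- function(x, ...) {
  tibble(n_tested = nrow(x$interactions) / 2,
         n_called = nrow(x$calls),
         n_called_strict = sum(x$calls$mode == "strict15"),
         n_called_relaxed = sum(x$calls$mode == "relaxed30"),
         n_lr_significant = if ("significant" %in% names(x$lr_hits))
           sum(x$lr_hits$significant) else 0L)
}
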
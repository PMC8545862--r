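#' Tidy a cross-validation result
#'
#' @param x A `gbc_cv` from [run_losocv()].
#' @param ... Unused.
#' @return Tibble with one row per fold (`fold`, `subject_id`, `truth`,
#'   `estimate`, scores).
#' @method tidy gbc_cv
#' @export
tidy.gbc_cv <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' One-row performance summary of a cross-validation result
#'
#' @param x A `gbc_cv`.
#' @param ... Unused.
#' @return One-row tibble: `n`, `n_classes`, `balanced_accuracy`,
#'   `total_accuracy`, `auc` (binary only).
#' @method glance gbc_cv
#' @export
glance.gbc_cv <- function(x, ...) {
  m <- compute_metrics(x)
  dplyr::bind_cols(
    tibble(n = nrow(x), n_classes = length(attr(x, "levels"))),
    m$overall
  )
}

#' Tidy a performance permutation test
#'
#' @param x A `gbc_permtest`.
#' @param ... Unused.
#' @return Tibble of null metric values, one row per permutation.
#' @method tidy gbc_permtest
#' @export
tidy.gbc_permtest <- function(x, ...) x$null

#' P-value summary of a performance permutation test
#'
#' @param x A `gbc_permtest`.
#' @param ... Unused.
#' @return Tibble with one row per metric: observed value, p, display label.
#' @method glance gbc_permtest
#' @export
glance.gbc_permtest <- function(x, ...) x$p

#' Tidy a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return The per-class metrics tibble.
#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' One-row summary of a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return The overall metrics tibble.
#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) x$overall
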
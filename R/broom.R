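#' Tidy a differential-expression result
#'
#' `tl_de` tibbles are already tidy; `tidy()` strips the class and
#' attributes so the result is a plain tibble, and `glance()` gives one-row
#' run-level information.
#'
#' @param x A `tl_de` tibble from [run_contrast()].
#' @param ... Unused.
#' @return `tidy()`: a tibble with one row per gene. `glance()`: a one-row
#'   tibble with `fraction`, `n_genes`, `n_significant` (q < 0.05),
#'   `pseudocount`, `dispersion`.
#' @export
tidy.tl_de <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "tl_de")
  attr(out, "pseudocount") <- NULL
  attr(out, "dispersion") <- NULL
  out
}

#' @rdname tidy.tl_de
#' @export
glance.tl_de <- function(x, ...) {
  tibble(fraction = unique(x$fraction),
         n_genes = nrow(x),
         n_significant = sum(x$q_value < 0.05),
         pseudocount = attr(x, "pseudocount") %||% NA_real_,
         dispersion = attr(x, "dispersion") %||% NA_real_)
}

#' Tidy a translatome classification
#'
#' @param x A `tl_classification` tibble from [classify_genes()].
#' @param ... Unused.
#' @return `tidy()`: plain per-gene tibble. `glance()`: one-row tibble with
#'   the thresholds used and the headline set sizes.
#' @export
tidy.tl_classification <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "tl_classification")
  attr(out, "thresholds") <- NULL
  out
}

#' @rdname tidy.tl_classification
#' @export
glance.tl_classification <- function(x, ...) {
  th <- attr(x, "thresholds") %||% c(up = NA_real_, down = NA_real_, q = NA_real_)
  s <- summarize_sets(x)
  n_of <- function(cat, lv) s$n[s$category == cat & s$level == lv]
  tibble(up_threshold = th[["up"]], down_threshold = th[["down"]],
         q_cut = th[["q"]],
         n_genes = nrow(x),
         transcriptional_up = n_of("transcriptional", "up"),
         transcriptional_down = n_of("transcriptional", "down"),
         transcriptional_unchanged = n_of("transcriptional", "unchanged"),
         trend_up = n_of("translational_trend", "up"),
         trend_down = n_of("translational_trend", "down"),
         significant_up = n_of("translational_significant", "up"),
         significant_down = n_of("translational_significant", "down"))
}

#' Glance at a pipeline run
#'
#' @param x A `tl_pipeline` object from [run_pipeline()].
#' @param ... Unused.
#' @return One-row tibble: seed, gene count, headline classification
#'   counts, TOP/TOP-like counts, and recovery metrics.
#' @export
glance.tl_pipeline <- function(x, ...) {
  cls <- glance(x$classification)
  ts <- top_summary(x$top_calls)
  m <- x$recovery$metrics
  tibble(seed = x$manifest$seed,
         n_genes = x$manifest$rows$truth,
         transcriptional_up = cls$transcriptional_up,
         transcriptional_down = cls$transcriptional_down,
         trend_up = cls$trend_up,
         trend_down = cls$trend_down,
         significant_up = cls$significant_up,
         significant_down = cls$significant_down,
         top = ts$n[ts$call == "TOP"],
         top_like = ts$n[ts$call == "TOP_like"],
         sensitivity = m$sensitivity,
         empirical_fdr = m$empirical_fdr)
}
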
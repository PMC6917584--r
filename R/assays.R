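ct_cell <- function(records, target, fraction, condition) {
  rows <- records %>%
    filter(.data$target == !!target, .data$condition == !!condition)
  if (!is.null(fraction)) rows <- filter(rows, .data$fraction == !!fraction)
  if (nrow(rows) == 0) {
    abort(sprintf("no Ct records for target '%s', condition '%s'%s",
                  target, condition,
                  if (is.null(fraction)) "" else sprintf(", fraction '%s'", fraction)))
  }
  rows
}

#' Relative quantification by the 2^-ddCt method
#'
#' Livak quantification: per condition, `dCt = mean Ct_target - mean
#' Ct_control`; `ddCt = dCt_test - dCt_ref`; the relative quantity is
#' `2^-ddCt`. Replicate spread is propagated as the SEM of the exponentiated
#' per-replicate values of the test condition (replicates paired by index,
#' each referenced to the mean dCt of the reference condition), matching
#' the "mean +/- SEM" convention of bench reports. Invariant to adding any
#' constant to every Ct.
#'
#' @param records Ct tibble with columns `target`, `condition`, `replicate`,
#'   `ct` and optionally `fraction` (see [generate_qpcr_table()]).
#' @param target,control Row ids of the quantified gene and the
#'   normalizer (internal control or spike).
#' @param condition_ref,condition_test Condition labels (e.g. `"PRE"`,
#'   `"SEN"`).
#' @param fraction Optional fraction filter (e.g. `"polysomal"`).
#' @return One-row tibble: `target`, `control`, `fraction`, `ratio`, `sem`,
#'   `n` (test replicates).
#' @export
#' @examples
#' ct <- generate_qpcr_table("Rps15", c(Rps15 = 0.25), noise_sd = 0, seed = 1)
#' ddct_ratio(ct, "Rps15", "Actb", fraction = "polysomal")
ddct_ratio <- function(records, target, control, condition_ref = "PRE",
                       condition_test = "SEN", fraction = NULL) {
  cells <- list(
    tt = ct_cell(records, target, fraction, condition_test),
    tr = ct_cell(records, target, fraction, condition_ref),
    ct = ct_cell(records, control, fraction, condition_test),
    cr = ct_cell(records, control, fraction, condition_ref)
  )
  if (any(vapply(cells, function(x) any(!is.finite(x$ct)), logical(1)))) {
    abort("Ct values must be finite")
  }
  dct_test <- mean(cells$tt$ct) - mean(cells$ct$ct)
  dct_ref <- mean(cells$tr$ct) - mean(cells$cr$ct)
  ratio <- 2^-(dct_test - dct_ref)
  paired <- inner_join(
    select(cells$tt, "replicate", ct_t = "ct"),
    select(cells$ct, "replicate", ct_c = "ct"),
    by = "replicate"
  )
  rel <- 2^-((paired$ct_t - paired$ct_c) - dct_ref)
  sem <- if (nrow(paired) > 1) sd(rel) / sqrt(nrow(paired)) else NA_real_
  tibble(target = target, control = control,
         fraction = fraction %||% NA_character_,
         ratio = ratio, sem = sem, n = nrow(cells$tt))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ratio of spike-normalized ratios
#'
#' The target's spike-normalized 2^-ddCt divided by the internal control's
#' spike-normalized 2^-ddCt. Because a global suppression hits target and
#' internal control alike but not the exogenous spike, each spike-normalized
#' ratio reveals the global shift while their quotient isolates the
#' target-specific change; with noiseless data the quotient equals
#' `ddct_ratio(target, internal_control)` exactly.
#'
#' @inheritParams ddct_ratio
#' @param internal_control Endogenous normalizer (e.g. `"Actb"`).
#' @param spike Exogenous spike row id.
#' @return One-row tibble: `target`, `internal_control`, `spike`,
#'   `target_vs_spike`, `control_vs_spike`, `double_ratio`.
#' @export
spike_double_ratio <- function(records, target, internal_control, spike,
                               condition_ref = "PRE", condition_test = "SEN",
                               fraction = NULL) {
  tvs <- ddct_ratio(records, target, spike, condition_ref, condition_test,
                    fraction)
  cvs <- ddct_ratio(records, internal_control, spike, condition_ref,
                    condition_test, fraction)
  tibble(target = target, internal_control = internal_control, spike = spike,
         target_vs_spike = tvs$ratio, control_vs_spike = cvs$ratio,
         double_ratio = tvs$ratio / cvs$ratio)
}

#' Cumulative population-doubling growth curve
#'
#' Per passage, the population doubling is `PD = log2(collected / plated)`;
#' the curve is the running sum of PD against culture time.
#'
#' @param records Tibble with columns `passage`, `day`, `plated`,
#'   `collected`, ordered by time.
#' @return Tibble of class `tl_growth`: input columns plus `pd` and
#'   `cumulative_pd`.
#' @export
#' @examples
#' growth_curve(tibble::tibble(passage = 1:3, day = c(3, 6, 9),
#'                             plated = 1e5, collected = 2e5))
growth_curve <- function(records) {
  need <- c("passage", "day", "plated", "collected")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    abort(paste0("growth records missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(records$plated <= 0) || any(records$collected <= 0)) {
    abort("plated and collected cell numbers must be positive")
  }
  out <- records %>%
    arrange(.data$day) %>%
    mutate(pd = log2(.data$collected / .data$plated),
           cumulative_pd = cumsum(.data$pd))
  class(out) <- c("tl_growth", class(out))
  out
}

#' SA-beta-gal positive rate with counting QC
#'
#' Percentage of stained cells, flagged when fewer cells were counted than
#' the per-condition minimum (by default 200 for presenescent and 100 for
#' senescent samples).
#'
#' @param counts Tibble with columns `sample`, `condition`, `positive`,
#'   `total`.
#' @param min_required Named vector of minimum counted cells per condition.
#' @return Input tibble plus `rate_pct` and `qc_pass`.
#' @export
#' @examples
#' betagal_rate(tibble::tibble(sample = "s1", condition = "PRE",
#'                             positive = 50, total = 200))
betagal_rate <- function(counts, min_required = c(PRE = 200, SEN = 100)) {
  need <- c("sample", "condition", "positive", "total")
  miss <- setdiff(need, names(counts))
  if (length(miss) > 0) {
    abort(paste0("beta-gal counts missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(counts$total <= 0)) abort("total counted cells must be positive")
  if (any(counts$positive < 0) || any(counts$positive > counts$total)) {
    abort("positive counts must lie in [0, total]")
  }
  unknown <- setdiff(unique(counts$condition), names(min_required))
  if (length(unknown) > 0) {
    abort(paste0("no counting minimum given for condition(s): ",
                 paste(unknown, collapse = ", ")))
  }
  counts %>%
    mutate(rate_pct = 100 * .data$positive / .data$total,
           qc_pass = unname(.data$total >= min_required[.data$condition]))
}
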
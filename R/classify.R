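#' Cross-classify genes into transcriptional versus translational regulation
#'
#' Implements the two-stage gate used for paired total/polysomal designs:
#' genes are first partitioned by the total-fraction ratio (`up` when
#' strictly above `up_threshold`, `down` when strictly below
#' `down_threshold`, `unchanged` otherwise). Only transcriptionally
#' unchanged genes receive a translational trend from the polysomal-fraction
#' ratio under the same thresholds, and a trend is flagged significant when
#' the polysomal BH q-value is strictly below `q_cut`. A gene at exactly a
#' threshold is unchanged (strict inequalities).
#'
#' @param de_total,de_polysomal `tl_de` tibbles from [run_contrast()] for
#'   the total and polysomal fractions; identical gene sets required.
#' @param up_threshold Ratio above which a trend is "up" (default 1.5).
#' @param down_threshold Ratio below which a trend is "down" (default
#'   0.667; 0.67 is also in circulation, so the value used is echoed in the
#'   `"thresholds"` attribute).
#' @param q_cut FDR cut for significance (default 0.05).
#' @return Tibble of class `tl_classification`: `gene_id`,
#'   `transcriptional_class`, `translational_trend` (`not_applicable` for
#'   transcriptionally changed genes), `translational_significant`,
#'   `t_ratio`, `p_ratio`, `q_polysomal`.
#' @export
#' @examples
#' # a transcriptionally flat gene halved on polysomes, q = 0.01:
#' de_t <- tibble::tibble(gene_id = "g1", ratio = 1.0, q_value = 0.50)
#' de_p <- tibble::tibble(gene_id = "g1", ratio = 0.5, q_value = 0.01)
#' classify_genes(de_t, de_p)
classify_genes <- function(de_total, de_polysomal, up_threshold = 1.5,
                           down_threshold = 0.667, q_cut = 0.05) {
  if (up_threshold <= down_threshold) {
    abort("up_threshold must exceed down_threshold")
  }
  if (!setequal(de_total$gene_id, de_polysomal$gene_id) ||
      nrow(de_total) != nrow(de_polysomal)) {
    abort("de_total and de_polysomal must cover identical gene sets")
  }
  joined <- inner_join(
    select(as_tibble(de_total), "gene_id", t_ratio = "ratio"),
    select(as_tibble(de_polysomal), "gene_id", p_ratio = "ratio",
           q_polysomal = "q_value"),
    by = "gene_id"
  )
  trend_of <- function(r) {
    dplyr::case_when(r > up_threshold ~ "up",
                     r < down_threshold ~ "down",
                     TRUE ~ "unchanged")
  }
  out <- joined %>%
    mutate(
      transcriptional_class = trend_of(.data$t_ratio),
      translational_trend = dplyr::if_else(
        .data$transcriptional_class == "unchanged",
        dplyr::recode(trend_of(.data$p_ratio), unchanged = "none"),
        "not_applicable"),
      translational_significant =
        .data$translational_trend %in% c("up", "down") &
        .data$q_polysomal < q_cut
    ) %>%
    select("gene_id", "transcriptional_class", "translational_trend",
           "translational_significant", "t_ratio", "p_ratio", "q_polysomal")
  attr(out, "thresholds") <- c(up = up_threshold, down = down_threshold,
                               q = q_cut)
  class(out) <- c("tl_classification", class(out))
  out
}

#' Summary counts of a translatome classification
#'
#' @param classifications `tl_classification` tibble from [classify_genes()].
#' @return Tibble with columns `category`
#'   (`transcriptional` / `translational_trend` / `translational_significant`),
#'   `level`, `n`; transcriptional counts sum to the total gene count.
#' @export
summarize_sets <- function(classifications) {
  cls <- as_tibble(classifications)
  count_lv <- function(x, lv) {
    vapply(lv, function(l) sum(x == l), integer(1))
  }
  trans <- count_lv(cls$transcriptional_class, c("up", "down", "unchanged"))
  trend <- count_lv(cls$translational_trend, c("up", "down", "none"))
  sig_up <- sum(cls$translational_significant & cls$translational_trend == "up")
  sig_down <- sum(cls$translational_significant & cls$translational_trend == "down")
  tibble(
    category = c(rep("transcriptional", 3), rep("translational_trend", 3),
                 rep("translational_significant", 2)),
    level = c(names(trans), names(trend), "up", "down"),
    n = as.integer(c(trans, trend, sig_up, sig_down))
  )
}

#' Recovery of designed translational regulation from a classification
#'
#' Scores the significant translational-down call against the simulator's
#' ground truth. A gene counts as a true positive when it was designed
#' translationally down with unchanged transcription (the only genes the
#' two-stage gate can, by design, call).
#'
#' @param classifications `tl_classification` tibble.
#' @param truth Truth tibble from [simulate_truth()] (needs `gene_id`,
#'   `trans_class`, `transl_class`).
#' @return List with `metrics` (one-row tibble: `sensitivity`,
#'   `specificity`, `empirical_fdr`, `tp`, `fp`, `fn`, `tn`) and
#'   `confusion` (2x2 tibble of designed vs called).
#' @export
recovery_report <- function(classifications, truth) {
  cls <- as_tibble(classifications)
  if (!setequal(cls$gene_id, truth$gene_id)) {
    abort("classification and truth gene sets differ")
  }
  joined <- inner_join(cls, truth, by = "gene_id")
  designed <- joined$transl_class == "down" & joined$trans_class == "unchanged"
  called <- joined$translational_significant &
    joined$translational_trend == "down"
  tp <- sum(designed & called); fp <- sum(!designed & called)
  fn <- sum(designed & !called); tn <- sum(!designed & !called)
  metrics <- tibble(
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    empirical_fdr = if (tp + fp > 0) fp / (tp + fp) else 0,
    tp = tp, fp = fp, fn = fn, tn = tn
  )
  confusion <- tibble(
    designed_down = c(TRUE, TRUE, FALSE, FALSE),
    called_down = c(TRUE, FALSE, TRUE, FALSE),
    n = c(tp, fn, fp, tn)
  )
  list(metrics = metrics, confusion = confusion)
}
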
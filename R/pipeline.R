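#' Configuration for the end-to-end synthetic translatome pipeline
#'
#' Bundles the simulator settings with every analysis threshold so a whole
#' run is reproducible from one object (and one seed). Stage seeds are
#' derived from `seed` by fixed offsets: truth +0, counts +1, UTRs +2,
#' qPCR +3.
#'
#' @param sim A [sim_config()] describing the simulated experiment.
#' @param up_threshold,down_threshold,q_cut Classification gates (see
#'   [classify_genes()]); must satisfy `up > 1 > down` and `q` in (0, 1).
#' @param trim_m,trim_a TMM trim fractions (see [tmm_factors()]).
#' @param test_mode `"binomial"` (exact conditional test at dispersion 0)
#'   or `"nb"` (fixed-dispersion negative binomial).
#' @param test_dispersion Dispersion used when `test_mode = "nb"`.
#' @param pseudocount FPKM pseudocount for ratios.
#' @param min_run,toplike_window,min_toplike_run,strict_max TOP-scanner
#'   parameters (see [scan_utr()]).
#' @param top_fraction_down,toplike_fraction_down Designed TOP / TOP-like
#'   fractions among translationally down genes when simulating UTRs
#'   (defaults mirror the ~3% / ~2% seen among translationally suppressed
#'   genes in senescent fibroblasts).
#' @param top_fraction_other,toplike_fraction_other Background fractions for
#'   all other genes.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            up_threshold = 1.5, down_threshold = 0.667,
                            q_cut = 0.05,
                            trim_m = 0.3, trim_a = 0.05,
                            test_mode = c("binomial", "nb"),
                            test_dispersion = 0.1,
                            pseudocount = 0.1,
                            min_run = 5L, toplike_window = 4L,
                            min_toplike_run = 5L, strict_max = FALSE,
                            top_fraction_down = 0.03,
                            toplike_fraction_down = 0.02,
                            top_fraction_other = 0.01,
                            toplike_fraction_other = 0.01) {
  test_mode <- match.arg(test_mode)
  if (!(up_threshold > 1 && down_threshold < 1 && down_threshold > 0)) {
    abort("thresholds must satisfy up_threshold > 1 > down_threshold > 0")
  }
  if (q_cut <= 0 || q_cut >= 1) abort("q_cut must lie in (0, 1)")
  stopifnot(inherits(sim, "sim_config"))
  structure(list(sim = sim, up_threshold = up_threshold,
                 down_threshold = down_threshold, q_cut = q_cut,
                 trim_m = trim_m, trim_a = trim_a, test_mode = test_mode,
                 test_dispersion = test_dispersion, pseudocount = pseudocount,
                 min_run = as.integer(min_run),
                 toplike_window = as.integer(toplike_window),
                 min_toplike_run = as.integer(min_toplike_run),
                 strict_max = strict_max,
                 top_fraction_down = top_fraction_down,
                 toplike_fraction_down = toplike_fraction_down,
                 top_fraction_other = top_fraction_other,
                 toplike_fraction_other = toplike_fraction_other),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file may set any argument of [pipeline_config()] at the top level
#' and any argument of [sim_config()] under a `sim:` key; unset fields keep
#' their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim %||% list()
  if (!is.null(sim_args$library_depths)) {
    sim_args$library_depths <- unlist(sim_args$library_depths)
  }
  if (!is.null(sim_args$class_proportions)) {
    sim_args$class_proportions <- unlist(sim_args$class_proportions)
  }
  raw$sim <- do.call(sim_config, sim_args)
  do.call(pipeline_config, raw)
}

utrs_for_truth <- function(truth, config) {
  down <- truth$trans_class == "unchanged" & truth$transl_class == "down"
  pieces <- list()
  if (any(down)) {
    pieces$down <- generate_utr_set(sum(down),
                                    top_fraction = config$top_fraction_down,
                                    toplike_fraction = config$toplike_fraction_down,
                                    ids = truth$gene_id[down],
                                    seed = config$sim$seed + 2L)
  }
  if (any(!down)) {
    pieces$other <- generate_utr_set(sum(!down),
                                     top_fraction = config$top_fraction_other,
                                     toplike_fraction = config$toplike_fraction_other,
                                     ids = truth$gene_id[!down],
                                     seed = config$sim$seed + 20L)
  }
  bind_rows(pieces) %>% arrange(match(.data$gene_id, truth$gene_id))
}

#' Run the full synthetic translatome pipeline
#'
#' Simulate -> TMM/FPKM -> exact tests (both fractions) -> classification ->
#' UTR simulation and TOP scan -> recovery metrics, writing every stage
#' table under `out_dir` along with a JSON run manifest. Rerunning with the
#' same configuration reproduces every file byte for byte.
#'
#' Files written: `counts.tsv`, `truth.tsv`, `normalization.tsv`,
#' `fpkm.tsv`, `de_total.tsv`, `de_polysomal.tsv`, `classification.tsv`,
#' `summary.tsv`, `utrs.fasta`, `top_calls.tsv`, `top_by_trend.tsv`,
#' `manifest.json`.
#'
#' @param config A [pipeline_config()] object.
#' @param out_dir Output directory (created if needed); `NULL` skips all
#'   file output.
#' @return (Invisibly) list of class `tl_pipeline` with elements `counts`,
#'   `truth`, `norm`, `fpkm`, `de_total`, `de_polysomal`, `classification`,
#'   `summary`, `utrs`, `top_calls`, `top_by_trend`, `recovery`,
#'   `manifest`.
#' @export
#' @examples
#' res <- run_pipeline(pipeline_config(sim_config(n_genes = 100, seed = 1)),
#'                     out_dir = NULL)
#' res$summary
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  sim <- stage("simulate", simulate_polysome_experiment(config$sim))
  norm <- stage("normalize", tmm_factors(sim$counts, trim_m = config$trim_m,
                                         trim_a = config$trim_a))
  fp <- stage("fpkm", fpkm(sim$counts, norm))
  disp <- if (config$test_mode == "nb") config$test_dispersion else 0
  de_t <- stage("detest_total",
                run_contrast(fp, sim$counts, norm, "total",
                             pseudocount = config$pseudocount,
                             dispersion = disp,
                             exclude = config$sim$spike_id))
  de_p <- stage("detest_polysomal",
                run_contrast(fp, sim$counts, norm, "polysomal",
                             pseudocount = config$pseudocount,
                             dispersion = disp,
                             exclude = config$sim$spike_id))
  cls <- stage("classify",
               classify_genes(de_t, de_p, up_threshold = config$up_threshold,
                              down_threshold = config$down_threshold,
                              q_cut = config$q_cut))
  summ <- stage("summarize", summarize_sets(cls))
  utrs <- stage("utr_simulate", utrs_for_truth(sim$truth, config))
  calls <- stage("topscan",
                 scan_utrs(utrs, min_run = config$min_run,
                           toplike_window = config$toplike_window,
                           min_toplike_run = config$min_toplike_run,
                           strict_max = config$strict_max))
  by_trend <- stage("top_intersect",
                    intersect_with_classification(calls, cls))
  recov <- stage("recovery", recovery_report(cls, sim$truth))
  manifest <- list(
    package = "polysomics",
    version = as.character(utils::packageVersion("polysomics")),
    seed = config$sim$seed,
    config = config_echo(config),
    reference_library = attr(norm, "reference"),
    rows = list(counts = nrow(sim$counts), truth = nrow(sim$truth),
                de_total = nrow(de_t), de_polysomal = nrow(de_p),
                classification = nrow(cls), utrs = nrow(utrs),
                top_calls = nrow(calls))
  )
  res <- structure(list(counts = sim$counts, truth = sim$truth, norm = norm,
                        fpkm = fp, de_total = de_t, de_polysomal = de_p,
                        classification = cls, summary = summ, utrs = utrs,
                        top_calls = calls, top_by_trend = by_trend,
                        recovery = recov, manifest = manifest),
                   class = "tl_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  invisible(res)
}

config_echo <- function(config) {
  out <- unclass(config)
  out$sim <- unclass(out$sim)
  out$sim$library_depths <- as.list(out$sim$library_depths)
  out$sim$class_proportions <- as.list(out$sim$class_proportions)
  out
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, file) readr::write_tsv(as_tibble(x), file.path(out_dir, file))
  w(res$counts, "counts.tsv")
  w(res$truth, "truth.tsv")
  w(res$norm, "normalization.tsv")
  w(res$fpkm, "fpkm.tsv")
  w(res$de_total, "de_total.tsv")
  w(res$de_polysomal, "de_polysomal.tsv")
  w(res$classification, "classification.tsv")
  w(res$summary, "summary.tsv")
  w(res$top_calls, "top_calls.tsv")
  w(res$top_by_trend, "top_by_trend.tsv")
  seqs <- Biostrings::DNAStringSet(setNames(res$utrs$utr5_seq,
                                            res$utrs$gene_id))
  Biostrings::writeXStringSet(seqs, file.path(out_dir, "utrs.fasta"))
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Validate pipeline input files
#'
#' Checks a counts TSV (header and four-library completeness, non-negative
#' counts), a UTR FASTA (readable, unique ids) and a qPCR Ct TSV (header)
#' without loading them into the pipeline. Returns a machine-readable issue
#' table; zero rows means all supplied files look usable.
#'
#' @param counts,fasta,qpcr Optional file paths; `NULL` entries are skipped.
#' @return Tibble with columns `file`, `issue`.
#' @export
validate_inputs <- function(counts = NULL, fasta = NULL, qpcr = NULL) {
  issues <- list()
  note <- function(file, issue) {
    issues[[length(issues) + 1]] <<- tibble(file = file, issue = issue)
  }
  if (!is.null(counts)) {
    if (!file.exists(counts)) {
      note(counts, "file not found")
    } else {
      tbl <- tryCatch(readr::read_tsv(counts, show_col_types = FALSE),
                      error = function(e) NULL)
      if (is.null(tbl)) {
        note(counts, "unreadable TSV")
      } else {
        miss <- setdiff(c("gene_id", "length_bp", LIBRARIES), names(tbl))
        for (m in miss) note(counts, paste0("missing column: ", m))
        libs <- intersect(LIBRARIES, names(tbl))
        if (length(libs) > 0 && any(as.matrix(tbl[libs]) < 0, na.rm = TRUE)) {
          note(counts, "negative counts")
        }
      }
    }
  }
  if (!is.null(fasta)) {
    seqs <- tryCatch(Biostrings::readDNAStringSet(fasta),
                     error = function(e) NULL)
    if (is.null(seqs)) {
      note(fasta, "unreadable FASTA")
    } else {
      ids <- sub("\\s.*$", "", names(seqs))
      for (d in unique(ids[duplicated(ids)])) {
        note(fasta, paste0("duplicate id: ", d))
      }
    }
  }
  if (!is.null(qpcr)) {
    tbl <- tryCatch(readr::read_tsv(qpcr, show_col_types = FALSE),
                    error = function(e) NULL)
    if (is.null(tbl)) {
      note(qpcr, "unreadable TSV")
    } else {
      miss <- setdiff(c("target", "fraction", "condition", "replicate", "ct"),
                      names(tbl))
      for (m in miss) note(qpcr, paste0("missing column: ", m))
    }
  }
  if (length(issues) == 0) {
    tibble(file = character(), issue = character())
  } else {
    bind_rows(issues)
  }
}
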
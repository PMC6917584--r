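#' Scan one TSS-anchored 5'UTR for a TOP or TOP-like pyrimidine tract
#'
#' Position 1 of the sequence is the transcription start site (+1 base of
#' the transcript). A transcript is called `TOP` when base 1 is `C` and the
#' maximal pyrimidine (`C`/`T`) run starting there has length at least
#' `min_run` (i.e. the C is followed by at least `min_run - 1` further
#' pyrimidines). It is called `TOP_like` when it is not TOP but some maximal
#' pyrimidine run of length at least `min_toplike_run` starts at a position
#' no greater than `toplike_window`. Otherwise the call is `none`. Any
#' character outside `A`, `C`, `G`, `T` (e.g. `N`) terminates a run;
#' lowercase input is uppercased.
#'
#' @param gene_id Identifier carried into the result.
#' @param utr5_seq Non-empty nucleotide string, 5' to 3' from the TSS.
#' @param min_run Minimum total run length (C plus following pyrimidines)
#'   for a TOP call.
#' @param toplike_window Latest start position (1-based) of a qualifying
#'   run for a TOP-like call.
#' @param min_toplike_run Minimum run length for a TOP-like call.
#' @param strict_max When `TRUE`, cap the TOP run at 14 pyrimidines after
#'   the TSS (total run length 15); longer runs then fall through to the
#'   TOP-like rule. Off by default, since rejecting longer tracts would be
#'   biologically arbitrary.
#' @return One-row tibble: `gene_id`, `call` (`TOP`/`TOP_like`/`none`),
#'   `run_start` (1-based, 0 when none), `run_length`, `run_seq`.
#' @export
#' @examples
#' scan_utr("Rps15", "CTTTCTGAAA")
scan_utr <- function(gene_id, utr5_seq, min_run = 5L, toplike_window = 4L,
                     min_toplike_run = 5L, strict_max = FALSE) {
  if (length(utr5_seq) != 1 || is.na(utr5_seq) || nchar(utr5_seq) == 0) {
    abort("utr5_seq must be a single non-empty sequence")
  }
  s <- toupper(utr5_seq)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  py <- chars %in% PYRIMIDINES
  r <- rle(py)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  run_starts <- starts[runs]
  run_lens <- r$lengths[runs]

  top_len <- if (length(runs) > 0 && run_starts[1] == 1L) run_lens[1] else 0L
  is_top <- chars[1] == "C" && top_len >= min_run &&
    (!strict_max || top_len <= 15L)
  if (is_top) {
    return(top_call(gene_id, "TOP", 1L, top_len, substr(s, 1, top_len)))
  }
  like <- which(run_starts <= toplike_window & run_lens >= min_toplike_run)
  if (length(like) > 0) {
    i <- like[1]
    return(top_call(gene_id, "TOP_like", run_starts[i], run_lens[i],
                    substr(s, run_starts[i], run_starts[i] + run_lens[i] - 1L)))
  }
  top_call(gene_id, "none", 0L, 0L, "")
}

top_call <- function(gene_id, call, run_start, run_length, run_seq) {
  out <- tibble(gene_id = gene_id, call = call,
                run_start = as.integer(run_start),
                run_length = as.integer(run_length), run_seq = run_seq)
  class(out) <- c("tl_topcalls", class(out))
  out
}

#' Scan a table of 5'UTRs
#'
#' Vectorised form of [scan_utr()] over a tibble with `gene_id` and
#' `utr5_seq` columns (e.g. the output of [generate_utr_set()]).
#'
#' @param utrs Tibble with columns `gene_id`, `utr5_seq`.
#' @inheritParams scan_utr
#' @return Tibble of calls, one row per input row, in input order.
#' @export
scan_utrs <- function(utrs, min_run = 5L, toplike_window = 4L,
                      min_toplike_run = 5L, strict_max = FALSE) {
  if (!all(c("gene_id", "utr5_seq") %in% names(utrs))) {
    abort("utrs must have columns gene_id and utr5_seq")
  }
  out <- purrr::map2_dfr(utrs$gene_id, utrs$utr5_seq, scan_utr,
                         min_run = min_run, toplike_window = toplike_window,
                         min_toplike_run = min_toplike_run,
                         strict_max = strict_max)
  class(out) <- c("tl_topcalls", setdiff(class(out), "tl_topcalls"))
  out
}

#' Scan a FASTA file of TSS-anchored 5'UTRs
#'
#' Reads the file with `Biostrings::readDNAStringSet()` and applies
#' [scan_utr()] to every record, preserving input order.
#'
#' @param path Path to a FASTA file; record ids must be unique.
#' @inheritParams scan_utr
#' @return Tibble of calls with a `"summary"` attribute holding the counts
#'   per class (also retrievable with [top_summary()]).
#' @export
scan_fasta <- function(path, min_run = 5L, toplike_window = 4L,
                       min_toplike_run = 5L, strict_max = FALSE) {
  seqs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e) {
                     abort(sprintf("malformed FASTA '%s': %s", path,
                                   conditionMessage(e)))
                   })
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate FASTA id(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (length(seqs) == 0) {
    calls <- top_call(character(0), character(0), integer(0), integer(0),
                      character(0))
  } else {
    calls <- scan_utrs(tibble(gene_id = ids,
                              utr5_seq = as.character(seqs)),
                       min_run = min_run, toplike_window = toplike_window,
                       min_toplike_run = min_toplike_run,
                       strict_max = strict_max)
  }
  attr(calls, "summary") <- top_summary(calls)
  calls
}

#' Count TOP-scanner calls per class
#'
#' @param calls Tibble of calls from [scan_utr()]/[scan_utrs()]/[scan_fasta()].
#' @return Tibble with columns `call` and `n` covering all three classes
#'   (zero-filled).
#' @export
top_summary <- function(calls) {
  lv <- c("TOP", "TOP_like", "none")
  calls %>%
    mutate(call = factor(.data$call, levels = lv)) %>%
    count(.data$call, .drop = FALSE, name = "n") %>%
    mutate(call = as.character(.data$call))
}

#' Join scanner calls with translatome classifications
#'
#' Inner join on `gene_id`; useful for asking how many TOP or TOP-like
#' transcripts fall in each translational trend (e.g. among translationally
#' down-regulated genes).
#'
#' @param calls Scanner calls tibble (`gene_id`, `call`, ...).
#' @param classifications Classification tibble from [classify_genes()].
#' @return Tibble `gene_id`, `call`, `translational_trend`,
#'   `translational_significant`; disjoint id sets yield an empty tibble.
#' @export
intersect_with_classification <- function(calls, classifications) {
  inner_join(
    select(as_tibble(calls), "gene_id", "call"),
    select(as_tibble(classifications), "gene_id", "translational_trend",
           "translational_significant"),
    by = "gene_id"
  )
}
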
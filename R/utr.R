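PYRIMIDINES <- c("C", "T")
PURINES <- c("A", "G")

rand_bases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

# random tail that cannot create a qualifying run in the scanner window:
# callers place it strictly after the window, so content is unconstrained
rand_tail <- function(n) if (n > 0) paste(rand_bases(n), collapse = "") else ""

#' Generate TSS-anchored 5'UTR sequences with known TOP status
#'
#' Constructs sequences in three designed classes. A designed TOP sequence
#' starts with C at the transcription start site followed by 4-13 further
#' pyrimidines (run of 5-14 total) terminated by a purine. A designed
#' TOP-like sequence carries a pyrimidine run of length 5-14 starting at
#' position 2-4 (purines before it), so it qualifies in the near-TSS window
#' but fails the strict TOP rule. Remaining sequences have a purine at
#' position 5, so no pyrimidine run of length >= 5 can start within the
#' first four positions.
#'
#' @param n Number of sequences.
#' @param top_fraction,toplike_fraction Fractions of designed TOP and
#'   TOP-like sequences; must lie in \[0, 1\] and sum to at most 1.
#' @param length_range Integer pair, inclusive range of sequence lengths;
#'   minimum allowed is 16 so every designed motif fits.
#' @param ids Optional character vector of gene ids (length `n`); defaults
#'   to `utr00001`, ...
#' @param seed Integer seed.
#' @return Tibble with columns `gene_id`, `utr5_seq`, `designed_class`
#'   (`"TOP"`, `"TOP_like"`, `"none"`).
#' @export
#' @examples
#' generate_utr_set(3, top_fraction = 1, toplike_fraction = 0, seed = 1)
generate_utr_set <- function(n, top_fraction = 0.1, toplike_fraction = 0.1,
                             length_range = c(30L, 120L), ids = NULL,
                             seed = 1L) {
  if (n < 0) abort("n must be non-negative")
  if (top_fraction < 0 || toplike_fraction < 0 ||
      top_fraction > 1 || toplike_fraction > 1 ||
      top_fraction + toplike_fraction > 1) {
    abort("fractions must lie in [0, 1] and sum to at most 1")
  }
  length_range <- as.integer(length_range)
  if (length(length_range) != 2 || length_range[1] > length_range[2] ||
      length_range[1] < 16L) {
    abort("length_range must be an increasing pair with minimum >= 16")
  }
  if (n == 0) {
    return(tibble(gene_id = character(), utr5_seq = character(),
                  designed_class = character()))
  }
  if (is.null(ids)) ids <- sprintf("utr%05d", seq_len(n))
  if (length(ids) != n) abort("ids must have length n")
  n_top <- round(n * top_fraction)
  n_like <- round(n * toplike_fraction)
  if (n_top + n_like > n) n_like <- n - n_top
  classes <- c(rep("TOP", n_top), rep("TOP_like", n_like),
               rep("none", n - n_top - n_like))
  withr::with_seed(seed, {
    classes <- sample(classes)
    lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
    seqs <- vapply(seq_len(n), function(i) {
      make_utr(classes[i], lens[i])
    }, character(1))
  })
  tibble(gene_id = ids, utr5_seq = seqs, designed_class = classes)
}

make_utr <- function(class, len) {
  if (class == "TOP") {
    run <- sample(4:min(13, len - 2L), 1)  # pyrimidines after the initial C
    head <- paste0("C", paste(sample(PYRIMIDINES, run, replace = TRUE),
                              collapse = ""),
                   sample(PURINES, 1))
  } else if (class == "TOP_like") {
    start <- sample(2:4, 1)
    run <- sample(5:min(14, len - start - 1L), 1)
    head <- paste0(paste(sample(PURINES, start - 1, replace = TRUE),
                         collapse = ""),
                   paste(sample(PYRIMIDINES, run, replace = TRUE),
                         collapse = ""),
                   sample(PURINES, 1))
  } else {
    # purine at position 5 caps any run touching the scan window at length 4
    head <- paste0(paste(rand_bases(4), collapse = ""), sample(PURINES, 1))
  }
  paste0(head, rand_tail(len - nchar(head)))
}
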
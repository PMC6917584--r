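#' Trimmed mean of M-values (TMM) scaling factors
#'
#' Between-library normalization for count tables: for each library against
#' a reference library, per-gene log2 ratios of count proportions (M) and
#' mean log2 proportions (A) are computed over genes with nonzero counts in
#' both libraries, the most extreme `trim_m` fraction of M values and
#' `trim_a` fraction of A values are discarded from each tail, and the
#' scaling factor is 2 raised to the (precision-weighted) mean of the
#' surviving M values. Factors are rescaled so their geometric mean is 1,
#' keeping effective sizes near the raw library sizes.
#'
#' Trimming keeps genes whose rank lies in
#' `[floor(n * trim) + 1, n - floor(n * trim)]` for both statistics; rank
#' ties are broken by input order. Precision weights are the inverse
#' approximate asymptotic variance of M (delta method):
#' `1 / ((N - x) / (N x) + (N_ref - x_ref) / (N_ref x_ref))`.
#'
#' @param counts Counts tibble with `gene_id`, `length_bp` and the four
#'   library columns (`total_PRE`, `total_SEN`, `polysomal_PRE`,
#'   `polysomal_SEN`).
#' @param reference Library id to normalize against, or `"auto"`: the
#'   library whose upper-quartile count proportion is closest to the mean
#'   upper quartile across libraries.
#' @param trim_m,trim_a Two-sided trim fractions for M and A (defaults 0.30
#'   and 0.05, the published TMM defaults).
#' @param weighted Use precision weights (`TRUE`, default) or the unweighted
#'   trimmed mean.
#' @return Tibble of class `tl_norm` with columns `library`, `lib_size`,
#'   `tmm_factor`, `effective_size`; the chosen reference is stored in the
#'   `"reference"` attribute.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 200, seed = 1)
#' sim <- simulate_polysome_experiment(cfg)
#' tmm_factors(sim$counts)
tmm_factors <- function(counts, reference = "auto", trim_m = 0.3,
                        trim_a = 0.05, weighted = TRUE) {
  assert_counts_table(counts, "tmm_factors()")
  mat <- as.matrix(counts[LIBRARIES])
  if (ncol(mat) < 2) abort("need at least two libraries")
  lib_size <- colSums(mat)
  if (any(lib_size == 0)) abort("every library needs at least one nonzero count")
  if (identical(reference, "auto")) {
    f75 <- apply(sweep(mat, 2, lib_size, "/"), 2, quantile, probs = 0.75)
    reference <- LIBRARIES[which.min(abs(f75 - mean(f75)))]
  }
  if (!reference %in% LIBRARIES) {
    abort(sprintf("unknown reference library '%s'", reference))
  }
  f <- vapply(LIBRARIES, function(lib) {
    tmm_pair(mat[, lib], mat[, reference], lib_size[lib], lib_size[reference],
             trim_m, trim_a, weighted)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  out <- tibble(library = LIBRARIES,
                lib_size = unname(lib_size),
                tmm_factor = unname(f),
                effective_size = unname(lib_size * f))
  attr(out, "reference") <- reference
  class(out) <- c("tl_norm", class(out))
  out
}

# one library against the reference; counts and sizes, not proportions, in
tmm_pair <- function(x, ref, n, n_ref, trim_m, trim_a, weighted) {
  keep <- x > 0 & ref > 0
  if (!any(keep)) abort("no genes with nonzero counts in both libraries")
  x <- x[keep]; ref <- ref[keep]
  p <- x / n; p_ref <- ref / n_ref
  m <- log2(p / p_ref)
  a <- 0.5 * (log2(p) + log2(p_ref))
  ng <- length(m)
  lo_m <- floor(ng * trim_m) + 1; hi_m <- ng - floor(ng * trim_m)
  lo_a <- floor(ng * trim_a) + 1; hi_a <- ng - floor(ng * trim_a)
  rk_m <- rank(m, ties.method = "first")
  rk_a <- rank(a, ties.method = "first")
  keep2 <- rk_m >= lo_m & rk_m <= hi_m & rk_a >= lo_a & rk_a <= hi_a
  if (!any(keep2)) abort("all genes trimmed; lower trim_m/trim_a")
  w <- if (weighted) {
    1 / ((n - x[keep2]) / (n * x[keep2]) + (n_ref - ref[keep2]) / (n_ref * ref[keep2]))
  } else {
    rep(1, sum(keep2))
  }
  2^(sum(w * m[keep2]) / sum(w))
}

#' Convert counts to FPKM
#'
#' `FPKM = count * 1e9 / (library size * length_bp)`, entrywise, where the
#' library size is by default the TMM-effective size
#' (`lib_size * tmm_factor`); set `use_effective = FALSE` for raw column
#' sums.
#'
#' @inheritParams tmm_factors
#' @param norm A `tl_norm` tibble from [tmm_factors()].
#' @param use_effective Use TMM-effective library sizes (default) or raw.
#' @return Tibble with `gene_id`, `length_bp` and one FPKM column per
#'   library, same shape and order as `counts`.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 200, seed = 1)
#' sim <- simulate_polysome_experiment(cfg)
#' fpkm(sim$counts, tmm_factors(sim$counts))
fpkm <- function(counts, norm, use_effective = TRUE) {
  assert_counts_table(counts, "fpkm()")
  stopifnot(inherits(norm, "tl_norm"))
  sizes <- if (use_effective) norm$effective_size else norm$lib_size
  sizes <- setNames(sizes, norm$library)[LIBRARIES]
  if (any(!is.finite(sizes)) || any(sizes <= 0)) {
    abort("effective library sizes must be positive")
  }
  mat <- as.matrix(counts[LIBRARIES])
  out <- sweep(mat, 2, sizes, "/") * 1e9 / counts$length_bp
  dplyr::bind_cols(counts[c("gene_id", "length_bp")], as_tibble(out))
}
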
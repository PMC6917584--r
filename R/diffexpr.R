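#' Exact conditional test for a two-library contrast without replicates
#'
#' With one library per condition, per-gene inference conditions on the
#' total count `t = x_pre + x_sen`. Under the null of equal underlying
#' abundance and `dispersion = 0`, `x_sen | t` is
#' `Binomial(t, n_sen_eff / (n_pre_eff + n_sen_eff))`; the two-sided p-value
#' is the sum of the probabilities of all outcomes no more likely than the
#' observed one (minimum-likelihood method), capped at 1. With
#' `dispersion = phi > 0` the conditional outcome probabilities are
#' proportional to the product of two negative-binomial masses at fixed
#' `phi` (size `1/phi`, null means split by effective size), conditioned on
#' the same total. `t = 0` gives p = 1.
#'
#' The p-value is symmetric in the two libraries and invariant to scaling
#' both effective sizes by a constant.
#'
#' @param x_pre,x_sen Non-negative integer counts (vectorised).
#' @param n_pre_eff,n_sen_eff Positive effective library sizes.
#' @param dispersion Negative-binomial dispersion phi; 0 (default) for the
#'   Poisson/binomial model.
#' @param two_sided `"minlik"` (default) sums outcomes with probability not
#'   exceeding the observed one; `"double"` doubles the smaller tail.
#' @return Numeric vector of p-values in \[0, 1\].
#' @export
#' @examples
#' exact_pair_test(0, 10, 1e6, 1e6)           # 2 * 0.5^10
#' exact_pair_test(5, 5, 1e6, 1e6)            # symmetric mode: 1
exact_pair_test <- function(x_pre, x_sen, n_pre_eff, n_sen_eff,
                            dispersion = 0, two_sided = c("minlik", "double")) {
  two_sided <- match.arg(two_sided)
  if (any(x_pre < 0) || any(x_sen < 0)) abort("counts must be non-negative")
  if (any(n_pre_eff <= 0) || any(n_sen_eff <= 0)) {
    abort("effective library sizes must be positive")
  }
  if (dispersion < 0) abort("dispersion must be non-negative")
  args <- vctrs_recycle(x_pre, x_sen, n_pre_eff, n_sen_eff)
  mapply(exact_pair_one, args[[1]], args[[2]], args[[3]], args[[4]],
         MoreArgs = list(phi = dispersion, two_sided = two_sided))
}

vctrs_recycle <- function(...) {
  xs <- list(...)
  n <- max(lengths(xs))
  lapply(xs, rep_len, length.out = n)
}

exact_pair_one <- function(x1, x2, n1, n2, phi, two_sided) {
  t <- x1 + x2
  if (t == 0) return(1)
  pr <- n2 / (n1 + n2)
  if (phi == 0) {
    if (t <= 1e5) {
      k <- 0:t
      pk <- dbinom(k, t, pr)
      tail_mass <- 0
    } else {
      # window covering the observed value and all but ~1e-15 of the null
      # mass; the excluded tails are strictly less likely than any outcome
      # inside and are counted into p below
      lo <- min(x2, qbinom(1e-15, t, pr))
      hi <- max(x2, qbinom(1e-15, t, pr, lower.tail = FALSE))
      k <- lo:hi
      pk <- dbinom(k, t, pr)
      tail_mass <- pbinom(lo - 1, t, pr) + pbinom(hi, t, pr, lower.tail = FALSE)
    }
    p_obs <- dbinom(x2, t, pr)
  } else {
    if (t > 5e6) abort("total count too large for exact NB enumeration")
    r <- 1 / phi
    k <- 0:t
    lw <- dnbinom(k, size = r, mu = t * pr, log = TRUE) +
      dnbinom(t - k, size = r, mu = t * (1 - pr), log = TRUE)
    pk <- exp(lw - max(lw))
    pk <- pk / sum(pk)
    p_obs <- pk[x2 + 1]
    tail_mass <- 0
  }
  if (two_sided == "minlik") {
    p <- sum(pk[pk <= p_obs * (1 + 1e-7)]) + tail_mass
  } else {
    lower <- sum(pk[k <= x2]) + if (phi == 0 && t > 1e5) pbinom(min(k) - 1, t, pr) else 0
    upper <- sum(pk[k >= x2]) + if (phi == 0 && t > 1e5) pbinom(max(k), t, pr, lower.tail = FALSE) else 0
    p <- 2 * min(lower, upper)
  }
  min(1, p)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted q-values: `q_i` is the minimum over ranks `j >= rank(i)`
#' of `p_(j) * m / j`, clipped to 1, returned in input order (computed via
#' [stats::p.adjust()]). Ties in rank are handled stably.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Differential test of SEN versus PRE within one fraction
#'
#' For every gene: the FPKM ratio with a pseudocount
#' (`(FPKM_SEN + eps) / (FPKM_PRE + eps)`), the exact conditional p-value
#' from the raw counts with TMM-effective library sizes, and the BH q-value
#' over the fraction's gene set.
#'
#' @param fpkm_tbl FPKM tibble from [fpkm()].
#' @param counts Counts tibble (same genes, same order as `fpkm_tbl`).
#' @param norm `tl_norm` tibble from [tmm_factors()].
#' @param fraction `"total"` or `"polysomal"`.
#' @param pseudocount FPKM pseudocount eps for the ratio (default 0.1).
#' @param dispersion Dispersion passed to [exact_pair_test()].
#' @param exclude Gene ids (e.g. the spike transcript) dropped before
#'   testing; they appear in neither the result nor the FDR correction.
#' @return Tibble of class `tl_de`: `gene_id`, `fraction`, `ratio`,
#'   `log2fc`, `p_value`, `q_value`.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 100, seed = 1)
#' sim <- simulate_polysome_experiment(cfg)
#' nf <- tmm_factors(sim$counts)
#' run_contrast(fpkm(sim$counts, nf), sim$counts, nf, "polysomal",
#'              exclude = cfg$spike_id)
run_contrast <- function(fpkm_tbl, counts, norm, fraction = c("polysomal", "total"),
                         pseudocount = 0.1, dispersion = 0, exclude = NULL) {
  fraction <- match.arg(fraction)
  assert_counts_table(counts, "run_contrast()")
  if (!identical(fpkm_tbl$gene_id, counts$gene_id)) {
    abort("fpkm_tbl and counts must list the same genes in the same order")
  }
  lib_pre <- library_label(fraction, "PRE")
  lib_sen <- library_label(fraction, "SEN")
  miss <- setdiff(c(lib_pre, lib_sen), names(counts))
  if (length(miss) > 0) {
    abort(paste0("missing library column(s): ", paste(miss, collapse = ", ")))
  }
  keep <- !(counts$gene_id %in% exclude)
  counts <- counts[keep, ]
  fpkm_tbl <- fpkm_tbl[keep, ]
  sizes <- setNames(norm$effective_size, norm$library)
  ratio <- (fpkm_tbl[[lib_sen]] + pseudocount) /
           (fpkm_tbl[[lib_pre]] + pseudocount)
  p <- exact_pair_test(counts[[lib_pre]], counts[[lib_sen]],
                       sizes[lib_pre], sizes[lib_sen],
                       dispersion = dispersion)
  out <- tibble(gene_id = counts$gene_id,
                fraction = fraction,
                ratio = ratio,
                log2fc = log2(ratio),
                p_value = p,
                q_value = bh_fdr(p))
  attr(out, "pseudocount") <- pseudocount
  attr(out, "dispersion") <- dispersion
  class(out) <- c("tl_de", class(out))
  out
}
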
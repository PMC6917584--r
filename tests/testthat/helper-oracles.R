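# Independent oracles, coded separately from the package's main paths.

# Brute-force TMM factor for one library against a reference: explicit
# data-frame bookkeeping, stable sorts and positional trimming, then a
# weighted mean. Returns unrescaled 2^mean(M); the caller applies the
# geometric-mean-1 convention.
oracle_tmm_pair <- function(x, ref, trim_m = 0.3, trim_a = 0.05,
                            weighted = TRUE) {
  n_x <- sum(x)
  n_r <- sum(ref)
  df <- data.frame(x = x, ref = ref)
  df <- df[df$x > 0 & df$ref > 0, ]
  df$m <- log2((df$x / n_x) / (df$ref / n_r))
  df$a <- 0.5 * (log2(df$x / n_x) + log2(df$ref / n_r))
  ng <- nrow(df)
  cut_m <- floor(ng * trim_m)
  cut_a <- floor(ng * trim_a)
  by_m <- order(df$m)                      # stable for ties
  keep_m <- rep(FALSE, ng)
  keep_m[by_m[seq.int(cut_m + 1, ng - cut_m)]] <- TRUE
  by_a <- order(df$a)
  keep_a <- rep(FALSE, ng)
  keep_a[by_a[seq.int(cut_a + 1, ng - cut_a)]] <- TRUE
  df <- df[keep_m & keep_a, ]
  w <- if (weighted) {
    1 / ((n_x - df$x) / (n_x * df$x) + (n_r - df$ref) / (n_r * df$ref))
  } else {
    rep(1, nrow(df))
  }
  2^(sum(w * df$m) / sum(w))
}

oracle_tmm_factors <- function(mat, reference) {
  f <- vapply(colnames(mat), function(lib) {
    oracle_tmm_pair(mat[, lib], mat[, reference])
  }, numeric(1))
  f / exp(mean(log(f)))
}

# One-line FPKM recomputation
oracle_fpkm <- function(count, length_bp, effective_size) {
  count * 1e9 / (effective_size * length_bp)
}

# Regex-based TOP/TOP-like caller at the default scanner parameters.
# [CT]{5,} matches are maximal pyrimidine runs; the first one starting at
# position <= 4 decides TOP-like.
oracle_top_call <- function(seq) {
  s <- toupper(seq)
  if (grepl("^C[CT]{4,}", s)) return("TOP")
  m <- gregexpr("[CT]{5,}", s)[[1]]
  if (m[1] != -1 && any(m <= 4)) return("TOP_like")
  "none"
}

# Spreadsheet-style growth-curve recomputation: explicit loop
oracle_growth <- function(plated, collected) {
  pd <- numeric(length(plated))
  acc <- 0
  for (i in seq_along(plated)) {
    acc <- acc + log(collected[i] / plated[i]) / log(2)
    pd[i] <- acc
  }
  pd
}

# small random counts table in the package's wide layout
random_counts_table <- function(n_genes, lambda = 80, seed = 1) {
  withr::with_seed(seed, {
    libs <- c("total_PRE", "total_SEN", "polysomal_PRE", "polysomal_SEN")
    mat <- matrix(rpois(n_genes * 4, lambda * rlnorm(n_genes, 0, 0.6)),
                  nrow = n_genes)
    colnames(mat) <- libs
    dplyr::bind_cols(
      tibble::tibble(gene_id = sprintf("g%04d", seq_len(n_genes)),
                     length_bp = sample(500:3000, n_genes, replace = TRUE)),
      tibble::as_tibble(mat)
    )
  })
}

random_utr <- function(len, py_prob = 0.5) {
  paste(sample(c("C", "T", "A", "G"), len, replace = TRUE,
               prob = c(py_prob / 2, py_prob / 2,
                        (1 - py_prob) / 2, (1 - py_prob) / 2)),
        collapse = "")
}
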
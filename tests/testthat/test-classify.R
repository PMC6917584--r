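de_stub <- function(ids, ratio, q = 1) {
  tibble::tibble(gene_id = ids, ratio = ratio, q_value = q)
}

test_that("the two-stage gate reproduces the documented example calls", {
  cls <- classify_genes(de_stub("g1", 1.0), de_stub("g1", 0.5, 0.01))
  expect_equal(cls$transcriptional_class, "unchanged")
  expect_equal(cls$translational_trend, "down")
  expect_true(cls$translational_significant)

  cls2 <- classify_genes(de_stub("g1", 2.0), de_stub("g1", 2.0, 0.001))
  expect_equal(cls2$transcriptional_class, "up")
  expect_equal(cls2$translational_trend, "not_applicable")
  expect_false(cls2$translational_significant)

  cls3 <- classify_genes(de_stub("g1", 1.0), de_stub("g1", 1.0, 1.0))
  expect_equal(cls3$transcriptional_class, "unchanged")
  expect_equal(cls3$translational_trend, "none")
  expect_false(cls3$translational_significant)
})

test_that("thresholds are strict: a gene exactly at the boundary is unchanged", {
  ids <- c("at_up", "at_down", "above", "below")
  cls <- classify_genes(de_stub(ids, c(1.5, 0.667, 1.5000001, 0.6669999)),
                        de_stub(ids, c(1, 1, 1, 1), 1))
  expect_equal(cls$transcriptional_class,
               c("unchanged", "unchanged", "up", "down"))
  # same boundary behaviour on the translational side
  cls2 <- classify_genes(de_stub(ids, 1),
                         de_stub(ids, c(1.5, 0.667, 1.6, 0.6), 0.01))
  expect_equal(cls2$translational_trend, c("none", "none", "up", "down"))
  expect_equal(cls2$translational_significant, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("classification is a partition and monotone in its thresholds", {
  withr::with_seed(31, {
    n <- 400
    ids <- sprintf("g%03d", 1:n)
    t_ratio <- exp(rnorm(n, 0, 0.7))
    p_ratio <- exp(rnorm(n, 0, 0.7))
    q <- runif(n)
  })
  de_t <- de_stub(ids, t_ratio)
  de_p <- de_stub(ids, p_ratio, q)
  cls <- classify_genes(de_t, de_p)
  expect_equal(nrow(cls), n)
  expect_setequal(cls$gene_id, ids)
  # mutually exclusive and exhaustive transcriptional classes
  expect_true(all(cls$transcriptional_class %in% c("up", "down", "unchanged")))
  # translational calls only in the unchanged stratum
  expect_true(all(cls$translational_trend[cls$transcriptional_class != "unchanged"]
                  == "not_applicable"))
  expect_true(all(cls$translational_trend[cls$translational_significant]
                  %in% c("up", "down")))
  # raising the up threshold never grows the up class
  for (up in c(1.2, 1.5, 2, 3)) {
    for (q_cut in c(0.01, 0.05, 0.2)) {
      c2 <- classify_genes(de_t, de_p, up_threshold = up, q_cut = q_cut)
      expect_lte(sum(c2$transcriptional_class == "up"),
                 sum(classify_genes(de_t, de_p, up_threshold = 1.2)$transcriptional_class == "up"))
      expect_lte(sum(classify_genes(de_t, de_p, q_cut = 0.01)$translational_significant),
                 sum(classify_genes(de_t, de_p, q_cut = 0.05)$translational_significant))
    }
  }
})

test_that("classification input contracts are enforced", {
  expect_error(classify_genes(de_stub("g1", 1), de_stub("g2", 1)),
               "identical gene sets")
  expect_error(classify_genes(de_stub("g1", 1), de_stub("g1", 1),
                              up_threshold = 0.5, down_threshold = 0.667),
               "exceed")
})

test_that("summary counts partition the gene list and track the design", {
  empty <- classify_genes(de_stub(character(0), numeric(0)),
                          de_stub(character(0), numeric(0)))
  s0 <- summarize_sets(empty)
  expect_true(all(s0$n == 0))

  ids <- sprintf("g%02d", 1:10)
  s1 <- summarize_sets(classify_genes(de_stub(ids, 1), de_stub(ids, 1, 1)))
  expect_equal(s1$n[s1$category == "transcriptional" & s1$level == "unchanged"], 10L)
  expect_equal(sum(s1$n[s1$category == "transcriptional"]), 10L)
  expect_equal(sum(s1$n[s1$category == "translational_trend"]), 10L)

  # seeded simulation: observed class counts stay within binomial bounds
  cfg <- sim_config(n_genes = 1500, dispersion = 0,
                    library_depths = setNames(rep(3e6, 4),
                                              c("total_PRE", "total_SEN",
                                                "polysomal_PRE", "polysomal_SEN")),
                    seed = 17)
  res <- run_pipeline(pipeline_config(cfg), out_dir = NULL)
  s <- summarize_sets(res$classification)
  n_up_design <- sum(res$truth$trans_class == "up")
  n_up_called <- s$n[s$category == "transcriptional" & s$level == "up"]
  # with Poisson noise at depth 3e6 and fc 2/0.4, designed trends are
  # recovered almost perfectly; allow 4-sigma binomial slack around design
  expect_lt(abs(n_up_called - n_up_design), 4 * sqrt(n_up_design) + 8)
  expect_equal(sum(s$n[s$category == "transcriptional"]), 1500L)
})

test_that("recovery metrics are exact for a perfect classifier and consistent otherwise", {
  truth <- tibble::tibble(gene_id = sprintf("g%02d", 1:20),
                          trans_class = rep("unchanged", 20),
                          transl_class = rep(c("down", "unchanged"), each = 10))
  cls <- classify_genes(
    de_stub(truth$gene_id, 1),
    de_stub(truth$gene_id, ifelse(truth$transl_class == "down", 0.4, 1),
            ifelse(truth$transl_class == "down", 0.001, 0.9))
  )
  rep1 <- recovery_report(cls, truth)
  expect_equal(rep1$metrics$sensitivity, 1)
  expect_equal(rep1$metrics$empirical_fdr, 0)
  expect_equal(rep1$metrics$specificity, 1)
  expect_equal(sum(rep1$confusion$n), 20)
  expect_error(recovery_report(cls, dplyr::mutate(truth, gene_id = paste0(gene_id, "x"))),
               "differ")
})

test_that("BH false positives on all-null simulations stay near nominal", {
  # 20 seeds of a 600-gene all-null Poisson design; expected BH discoveries
  # per run under the global null are at most q_cut
  fp <- vapply(1:20, function(s) {
    cfg <- sim_config(n_genes = 600, dispersion = 0,
                      library_depths = setNames(rep(6e5, 4),
                                                c("total_PRE", "total_SEN",
                                                  "polysomal_PRE", "polysomal_SEN")),
                      class_proportions = c(unchanged_unchanged = 1,
                                            setNames(rep(0, 8),
                                                     setdiff(names(default_class_proportions()),
                                                             "unchanged_unchanged"))),
                      seed = 100 + s)
    res <- run_pipeline(pipeline_config(cfg), out_dir = NULL)
    sum(res$classification$translational_significant)
  }, numeric(1))
  expect_lte(mean(fp), 2 * 0.05)
})
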
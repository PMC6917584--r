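test_that("exact conditional test reproduces enumerated binomial values", {
  # symmetric mode: every outcome is included
  expect_equal(exact_pair_test(5, 5, 1e6, 1e6), 1)
  # all mass at the two extreme outcomes of Binomial(10, 1/2)
  expect_equal(exact_pair_test(0, 10, 1e6, 1e6), 2 * 0.5^10, tolerance = 1e-12)
  expect_equal(exact_pair_test(10, 0, 1e6, 1e6), 2 * 0.5^10, tolerance = 1e-12)
  # zero total is uninformative
  expect_equal(exact_pair_test(0, 0, 1e6, 1e6), 1)
  expect_error(exact_pair_test(-1, 2, 1, 1), "non-negative")
})

test_that("binomial-mode p-values agree with stats::binom.test across a grid", {
  cases <- expand.grid(x1 = c(0, 1, 3, 12, 40), x2 = c(0, 2, 7, 25),
                       n1 = c(1e6, 2e6), n2 = c(1e6, 5e5))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    t <- cs$x1 + cs$x2
    if (t == 0) next
    pr <- cs$n2 / (cs$n1 + cs$n2)
    expect_equal(exact_pair_test(cs$x1, cs$x2, cs$n1, cs$n2),
                 stats::binom.test(cs$x2, t, pr)$p.value,
                 tolerance = 1e-12,
                 info = paste(unlist(cs), collapse = ","))
  }
})

test_that("exact test is symmetric and scale-invariant in effective sizes", {
  withr::with_seed(21, {
    for (i in 1:25) {
      x1 <- rpois(1, 40); x2 <- rpois(1, 60)
      n1 <- runif(1, 5e5, 2e6); n2 <- runif(1, 5e5, 2e6)
      phi <- sample(c(0, 0.1), 1)
      p <- exact_pair_test(x1, x2, n1, n2, dispersion = phi)
      expect_equal(p, exact_pair_test(x2, x1, n2, n1, dispersion = phi),
                   tolerance = 1e-12)
      expect_equal(p, exact_pair_test(x1, x2, 7.3 * n1, 7.3 * n2,
                                      dispersion = phi),
                   tolerance = 1e-12)
      expect_gte(p, 0); expect_lte(p, 1)
    }
  })
})

test_that("NB-mode probabilities match direct product enumeration", {
  # independent recomputation of the conditional NB outcome weights
  direct_nb_p <- function(x1, x2, n1, n2, phi) {
    t <- x1 + x2
    pr <- n2 / (n1 + n2)
    k <- 0:t
    w <- dnbinom(k, size = 1 / phi, mu = t * pr) *
      dnbinom(t - k, size = 1 / phi, mu = t * (1 - pr))
    w <- w / sum(w)
    min(1, sum(w[w <= w[x2 + 1] * (1 + 1e-7)]))
  }
  cases <- list(c(3, 15), c(20, 20), c(0, 8), c(100, 40))
  for (cs in cases) {
    expect_equal(exact_pair_test(cs[1], cs[2], 1e6, 1e6, dispersion = 0.1),
                 direct_nb_p(cs[1], cs[2], 1e6, 1e6, 0.1),
                 tolerance = 1e-10)
  }
  # NB mode is wider-tailed than binomial for the same split
  expect_gt(exact_pair_test(10, 40, 1e6, 1e6, dispersion = 0.2),
            exact_pair_test(10, 40, 1e6, 1e6))
})

test_that("BH adjustment reproduces the hand-evaluated step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 7)), rep(0.2, 7))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  # permutation equivariance and rank monotonicity
  p <- withr::with_seed(5, runif(50))
  perm <- withr::with_seed(6, sample(50))
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  expect_true(all(diff(bh_fdr(sort(p))) >= -1e-15))
})

test_that("run_contrast wires ratios, tests and FDR together", {
  tbl <- random_counts_table(40, seed = 8)
  tbl$total_SEN <- tbl$total_PRE        # identical libraries in the fraction
  nf <- tmm_factors(tbl, reference = "total_PRE")
  fp <- fpkm(tbl, nf)
  de <- run_contrast(fp, tbl, nf, "total")
  # equal counts and equal effective sizes give ratio 1, p 1
  eq_sizes <- abs(nf$effective_size[1] - nf$effective_size[2]) < 1e-6
  if (eq_sizes) {
    expect_equal(de$ratio, rep(1, 40), tolerance = 1e-12)
    expect_equal(de$p_value, rep(1, 40))
  }
  expect_true(all(de$q_value >= 0 & de$q_value <= 1))
  # a designed 4-fold gene at high depth attains the minimum q
  cfg <- sim_config(n_genes = 200, dispersion = 0, fc_down = 0.25,
                    library_depths = setNames(rep(5e6, 4),
                                              c("total_PRE", "total_SEN",
                                                "polysomal_PRE", "polysomal_SEN")),
                    class_proportions = c(unchanged_unchanged = 1,
                                          setNames(rep(0, 8),
                                                   setdiff(names(default_class_proportions()),
                                                           "unchanged_unchanged"))),
                    seed = 14)
  truth <- simulate_truth(cfg)
  truth$translational_fc[7] <- 4
  sim <- simulate_experiment(truth, cfg)
  nf2 <- tmm_factors(sim$counts)
  de2 <- run_contrast(fpkm(sim$counts, nf2), sim$counts, nf2, "polysomal",
                      exclude = cfg$spike_id)
  expect_false(cfg$spike_id %in% de2$gene_id)
  expect_equal(de2$gene_id[which.min(de2$q_value + de2$p_value)],
               truth$gene_id[7])
})

test_that("designed strong effects yield stochastically smaller p than weak ones", {
  # FC 4 versus FC 2 at matched depth, compared over replicate simulations
  p_for_fc <- function(fc, seed) {
    cfg <- sim_config(n_genes = 100, dispersion = 0,
                      library_depths = setNames(rep(2e5, 4),
                                                c("total_PRE", "total_SEN",
                                                  "polysomal_PRE", "polysomal_SEN")),
                      class_proportions = c(unchanged_unchanged = 1,
                                            setNames(rep(0, 8),
                                                     setdiff(names(default_class_proportions()),
                                                             "unchanged_unchanged"))),
                      seed = seed)
    truth <- simulate_truth(cfg)
    truth$translational_fc[1] <- fc
    sim <- simulate_experiment(truth, cfg)
    nf <- tmm_factors(sim$counts)
    de <- run_contrast(fpkm(sim$counts, nf), sim$counts, nf, "polysomal",
                       exclude = cfg$spike_id)
    de$p_value[1]
  }
  p4 <- vapply(1:40, function(s) p_for_fc(4, s), numeric(1))
  p2 <- vapply(1:40, function(s) p_for_fc(2, s), numeric(1))
  expect_lt(median(log10(p4 + 1e-300)), median(log10(p2 + 1e-300)))
})
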
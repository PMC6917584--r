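#' Default design-class proportions for the simulator
#'
#' Genes are assigned to one of nine design classes, the cross of
#' transcriptional trend (up / down / unchanged, total fraction) and
#' translational trend (up / down / unchanged, polysomal enrichment).
#' By default 70% of genes are doubly unchanged and the remaining 30% is
#' split evenly across the eight effect classes.
#'
#' @return Named numeric vector of nine proportions summing to 1, with names
#'   of the form `"<transcriptional>_<translational>"`.
#' @export
#' @examples
#' default_class_proportions()
default_class_proportions <- function() {
  classes <- as.vector(outer(c("up", "down", "unchanged"),
                             c("up", "down", "unchanged"),
                             paste, sep = "_"))
  p <- setNames(rep(0.3 / 8, 9), classes)
  p["unchanged_unchanged"] <- 0.7
  p
}

#' Simulation configuration for a paired total/polysomal experiment
#'
#' Collects every knob of the no-replicate 2x2 design simulator: one library
#' per (fraction, condition) cell, negative-binomial counts, a global
#' multiplicative suppression of the senescent polysomal fraction, and an
#' exogenous spike transcript added to the polysomal libraries only at a
#' condition-invariant abundance.
#'
#' @param n_genes Number of genes to simulate (spike excluded).
#' @param library_depths Named vector of expected total read counts, one per
#'   library `total_PRE`, `total_SEN`, `polysomal_PRE`, `polysomal_SEN`.
#' @param dispersion Negative-binomial dispersion phi, so that
#'   `Var = mu + phi * mu^2`; `0` gives Poisson counts.
#' @param global_polysomal_scalar Multiplier applied to every endogenous
#'   gene's abundance in the senescent polysomal library, modelling a global
#'   reduction of translation. The spike transcript is not scaled.
#' @param spike_abundance Relative abundance of the spike transcript,
#'   identical in both conditions.
#' @param spike_id,spike_length_bp Identifier and transcript length used for
#'   the spike row.
#' @param class_proportions Named vector over the nine design classes (see
#'   [default_class_proportions()]); must sum to 1.
#' @param fc_up,fc_down Designed fold changes for "up" and "down" classes.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-gene baseline abundance.
#' @param seed Integer seed; all randomness of the simulator flows from it.
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 100, seed = 1)
#' cfg$dispersion
sim_config <- function(n_genes = 2000,
                       library_depths = c(total_PRE = 2e6, total_SEN = 2e6,
                                          polysomal_PRE = 2e6, polysomal_SEN = 2e6),
                       dispersion = 0.1,
                       global_polysomal_scalar = 0.5,
                       spike_abundance = 1,
                       spike_id = "spike_mScarlet",
                       spike_length_bp = 1000L,
                       class_proportions = default_class_proportions(),
                       fc_up = 2,
                       fc_down = 0.4,
                       baseline_meanlog = log(5),
                       baseline_sdlog = 1,
                       seed = 1L) {
  if (n_genes < 1) abort("n_genes must be a positive integer")
  if (!setequal(names(library_depths), LIBRARIES)) {
    abort(sprintf("library_depths must have exactly the four keys: %s",
                  paste(LIBRARIES, collapse = ", ")))
  }
  library_depths <- library_depths[LIBRARIES]
  if (any(library_depths <= 0)) abort("library depths must be positive")
  if (dispersion < 0) abort("dispersion must be non-negative")
  if (global_polysomal_scalar <= 0) abort("global_polysomal_scalar must be positive")
  if (spike_abundance <= 0) abort("spike_abundance must be positive")
  if (fc_up <= 0 || fc_down <= 0) abort("fold-change magnitudes must be positive")
  expected <- names(default_class_proportions())
  if (!setequal(names(class_proportions), expected)) {
    abort("class_proportions must be named over the nine design classes")
  }
  class_proportions <- class_proportions[expected]
  if (any(class_proportions < 0) ||
      abs(sum(class_proportions) - 1) > 1e-9) {
    abort("class_proportions must be non-negative and sum to 1 (tolerance 1e-9)")
  }
  structure(list(n_genes = as.integer(n_genes),
                 library_depths = library_depths,
                 dispersion = dispersion,
                 global_polysomal_scalar = global_polysomal_scalar,
                 spike_abundance = spike_abundance,
                 spike_id = spike_id,
                 spike_length_bp = as.integer(spike_length_bp),
                 class_proportions = class_proportions,
                 fc_up = fc_up,
                 fc_down = fc_down,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 seed = as.integer(seed)),
            class = "sim_config")
}

fc_for <- function(class, fc_up, fc_down) {
  unname(c(up = fc_up, down = fc_down, unchanged = 1)[class])
}

#' Draw a per-gene ground-truth table
#'
#' Assigns each gene a design class from `config$class_proportions`, a
#' log-normal baseline abundance, a transcript length and the designed
#' transcriptional/translational fold changes implied by its class.
#' Randomness uses `config$seed` (stream offset 0).
#'
#' @param config A [sim_config()] object.
#' @return Tibble with columns `gene_id`, `length_bp`, `baseline_abundance`,
#'   `transcriptional_fc`, `translational_fc`, `trans_class`, `transl_class`.
#' @export
#' @examples
#' simulate_truth(sim_config(n_genes = 5, seed = 1))
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  withr::with_seed(config$seed, {
    cls <- sample(names(config$class_proportions), n, replace = TRUE,
                  prob = config$class_proportions)
    parts <- strsplit(cls, "_", fixed = TRUE)
    trans <- vapply(parts, `[[`, "", 1L)
    transl <- vapply(parts, `[[`, "", 2L)
    tibble(
      gene_id = sprintf("gene%05d", seq_len(n)),
      length_bp = pmax(200L, as.integer(round(rlnorm(n, log(1500), 0.4)))),
      baseline_abundance = rlnorm(n, config$baseline_meanlog, config$baseline_sdlog),
      transcriptional_fc = fc_for(trans, config$fc_up, config$fc_down),
      translational_fc = fc_for(transl, config$fc_up, config$fc_down),
      trans_class = trans,
      transl_class = transl
    )
  })
}

assert_truth <- function(truth) {
  need <- c("gene_id", "length_bp", "baseline_abundance",
            "transcriptional_fc", "translational_fc")
  miss <- setdiff(need, names(truth))
  if (length(miss) > 0) {
    abort(paste0("truth table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(truth) == 0) abort("truth table must be non-empty")
  if (any(truth$transcriptional_fc <= 0) || any(truth$translational_fc <= 0)) {
    abort("fold changes in the truth table must be positive")
  }
  if (any(truth$length_bp < 1)) abort("gene lengths must be >= 1 bp")
  if (any(!is.finite(truth$baseline_abundance)) || any(truth$baseline_abundance <= 0)) {
    abort("baseline abundances must be finite and positive")
  }
  invisible(truth)
}

#' Expected counts of the simulated design
#'
#' Deterministic part of the simulator: the expected count of gene g in
#' library L is proportional to
#' `baseline x (transcriptional_fc if SEN) x (translational_fc and
#' global_polysomal_scalar if polysomal AND SEN) x length_bp`,
#' rescaled so that each library column sums to its configured depth.
#' The spike transcript appears in the polysomal libraries only, at a
#' condition-invariant abundance that is not touched by the global scalar.
#'
#' @inheritParams simulate_experiment
#' @return Tibble `gene_id`, `length_bp` plus one expected-count column per
#'   library (the spike row last).
#' @export
expected_counts <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  assert_truth(truth)
  s <- config$global_polysomal_scalar
  ab <- cbind(
    total_PRE     = truth$baseline_abundance,
    total_SEN     = truth$baseline_abundance * truth$transcriptional_fc,
    polysomal_PRE = truth$baseline_abundance,
    polysomal_SEN = truth$baseline_abundance * truth$transcriptional_fc *
                      truth$translational_fc * s
  )
  lens <- c(truth$length_bp, config$spike_length_bp)
  ab <- rbind(ab, spike = c(0, 0, config$spike_abundance, config$spike_abundance))
  w <- ab * lens
  mu <- sweep(w, 2, colSums(w), "/")
  mu <- sweep(mu, 2, config$library_depths[colnames(mu)], "*")
  out <- tibble(gene_id = c(truth$gene_id, config$spike_id), length_bp = lens)
  dplyr::bind_cols(out, as_tibble(mu))
}

#' Simulate a paired total/polysomal RNA-seq count table
#'
#' Draws one count library per (fraction, condition) cell of the 2x2 design
#' around the means of [expected_counts()]: negative binomial with
#' `Var = mu + phi mu^2` when `config$dispersion > 0`, Poisson when 0.
#' Randomness uses `config$seed + 1` (stream offset 1), so that the counts
#' stream is independent of the truth-table stream.
#'
#' @param truth Tibble of per-gene ground truth, as from [simulate_truth()]
#'   (columns `gene_id`, `length_bp`, `baseline_abundance`,
#'   `transcriptional_fc`, `translational_fc`).
#' @param config A [sim_config()] object.
#' @return List with elements `counts` (tibble `gene_id`, `length_bp`, one
#'   integer column per library, spike row included) and `truth` (the input
#'   truth table with design classes).
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 50, seed = 1)
#' sim <- simulate_experiment(simulate_truth(cfg), cfg)
#' head(sim$counts)
simulate_experiment <- function(truth, config) {
  mu_tbl <- expected_counts(truth, config)
  mu <- as.matrix(mu_tbl[LIBRARIES])
  phi <- config$dispersion
  counts <- withr::with_seed(config$seed + 1L, {
    if (phi == 0) {
      matrix(rpois(length(mu), lambda = mu), nrow = nrow(mu))
    } else {
      matrix(rnbinom(length(mu), size = 1 / phi, mu = mu), nrow = nrow(mu))
    }
  })
  colnames(counts) <- LIBRARIES
  counts_tbl <- dplyr::bind_cols(mu_tbl[c("gene_id", "length_bp")],
                                 as_tibble(counts))
  list(counts = counts_tbl, truth = truth)
}

#' One-call simulator: truth plus counts
#'
#' Convenience wrapper running [simulate_truth()] then
#' [simulate_experiment()] under a single configuration.
#'
#' @inheritParams simulate_experiment
#' @return As [simulate_experiment()].
#' @export
simulate_polysome_experiment <- function(config) {
  simulate_experiment(simulate_truth(config), config)
}

#' Simulate a qPCR Ct table with spike and internal-control rows
#'
#' Generates threshold-cycle values under the model
#' `Ct = offset - log2(quantity) + N(0, noise_sd)`. Target quantities are 1
#' in the reference condition; in the test condition of the polysomal
#' fraction they are multiplied by the target's designed fold change and by
#' `global_scalar` (the global suppression that an endogenous internal
#' control cannot reveal). The spike transcript is condition-invariant and
#' appears in the polysomal fraction only; the internal control has fold
#' change 1 but is still subject to `global_scalar`. Total-fraction
#' quantities are unchanged between conditions (the effects are
#' translational).
#'
#' @param targets Character vector of target gene ids.
#' @param effects Named numeric vector mapping (a subset of) targets to
#'   positive fold changes; unnamed targets default to 1.
#' @param global_scalar Global polysomal suppression multiplier (SEN,
#'   polysomal fraction, all endogenous rows).
#' @param noise_sd Gaussian Ct noise, in cycles.
#' @param n_replicates Replicate measurements per well.
#' @param internal_control,spike_id Row ids for the endogenous control and
#'   the exogenous spike.
#' @param fractions Fractions to emit (`"total"`, `"polysomal"`).
#' @param base_ct Machine offset in cycles (cancels in any ddCt).
#' @param seed Integer seed.
#' @return Tibble with columns `target`, `fraction`, `condition`,
#'   `replicate`, `ct`.
#' @export
#' @examples
#' generate_qpcr_table("Rps15", c(Rps15 = 0.25), noise_sd = 0, seed = 1)
generate_qpcr_table <- function(targets,
                                effects = NULL,
                                global_scalar = 1,
                                noise_sd = 0.2,
                                n_replicates = 3,
                                internal_control = "Actb",
                                spike_id = "spike_mScarlet",
                                fractions = c("total", "polysomal"),
                                base_ct = 20,
                                seed = 1L) {
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  if (global_scalar <= 0) abort("global_scalar must be positive")
  fractions <- match.arg(fractions, FRACTIONS, several.ok = TRUE)
  fc <- setNames(rep(1, length(targets)), targets)
  if (!is.null(effects)) {
    if (is.null(names(effects)) || !all(names(effects) %in% targets)) {
      abort("effects must be named after entries of `targets`")
    }
    if (any(effects <= 0)) abort("fold changes must be positive")
    fc[names(effects)] <- effects
  }
  rows <- tidyr::expand_grid(
    target = unique(c(targets, internal_control, spike_id)),
    fraction = fractions,
    condition = CONDITIONS,
    replicate = seq_len(n_replicates)
  )
  rows <- rows %>%
    filter(!(.data$target == spike_id & .data$fraction == "total"))
  quantity <- rep(1, nrow(rows))
  sen_poly <- rows$condition == "SEN" & rows$fraction == "polysomal"
  endo <- rows$target != spike_id
  quantity[sen_poly & endo] <- quantity[sen_poly & endo] *
    global_scalar * fc_lookup(fc, rows$target[sen_poly & endo], internal_control)
  withr::with_seed(seed, {
    offs <- setNames(base_ct + rnorm(length(unique(rows$target)), 0, 2),
                     unique(rows$target))
    rows %>%
      mutate(ct = offs[.data$target] - log2(quantity) +
               rnorm(nrow(rows), 0, noise_sd)) %>%
      arrange(.data$target, .data$fraction, .data$condition, .data$replicate)
  })
}

fc_lookup <- function(fc, targets, internal_control) {
  out <- rep(1, length(targets))
  known <- targets %in% names(fc)
  out[known] <- fc[targets[known]]
  out[targets == internal_control] <- 1
  out
}
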
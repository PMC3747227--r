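#' Draws from the Poisson-lognormal observation model
#'
#' `y ~ Poisson(rate)`, `log(rate) ~ N(mu, v)`.  The marginal mean is
#' `exp(mu + v/2)` and the variance is `mean + mean^2 * (exp(v) - 1)` —
#' overdispersed relative to Poisson, collapsing to Poisson as `v -> 0`.
#'
#' @param n number of draws.
#' @param mu log-rate mean.
#' @param v log-rate variance (>= 0).
#' @return integer vector of counts.
#' @export
rpln <- function(n, mu, v) {
  if (v < 0) qpcr_error("qpcr_domain_error", "log-variance must be >= 0")
  rpois(n, exp(rnorm(n, mu, sqrt(v))))
}

#' Describe a generative truth for simulation
#'
#' Fixes every parameter of the generative hierarchy: gene intercepts and
#' treatment effects on the natural-log scale, the loading SD, per-gene
#' grouping / sample SDs and residual log-variances, the factorial layout,
#' and per-gene amplification efficiencies and single-molecule cycles used
#' to back-convert counts to Cq.
#'
#' @param genes data.frame with columns `gene`, `intercept` (log scale),
#'   `E`, `cq1`.
#' @param factors named list of factor level vectors (first level is the
#'   reference).
#' @param interactions list of factor-name tuples.
#' @param effects numeric matrix, genes x terms, with term columns labeled
#'   as produced by the design builder (e.g. `"condition=heat"`); entries
#'   are natural-log fold changes.
#' @param n_groups number of grouping levels (0 for no grouping factor).
#' @param samples_per_cell biological samples per factor cell (per group if
#'   `n_groups > 0`).
#' @param tech_reps technical replicates per sample.
#' @param sd_loading SD of the shared sample loading effect.
#' @param sd_group,sd_sample per-gene SDs of the grouping and sample
#'   effects (recycled).
#' @param v_resid per-gene residual log-variance (recycled).
#' @return object of class `simulation_truth`.
#' @export
simulation_truth <- function(genes, factors, interactions = list(),
                             effects = NULL,
                             n_groups = 0, samples_per_cell = 2,
                             tech_reps = 2,
                             sd_loading = 0.3, sd_group = 0.3,
                             sd_sample = 0.2, v_resid = 0.04) {
  G <- nrow(genes)
  reference <- lapply(factors, `[`, 1L)
  terms <- enumerate_terms(factors, reference, interactions)
  if (is.null(effects))
    effects <- matrix(0, G, length(terms),
                      dimnames = list(genes$gene, names(terms)))
  if (!all(colnames(effects) %in% names(terms)))
    qpcr_error("qpcr_config_error", "effects has unknown term columns")
  sd_group <- rep_len(sd_group, G); sd_sample <- rep_len(sd_sample, G)
  v_resid <- rep_len(v_resid, G)
  if (any(c(sd_loading, sd_group, sd_sample, v_resid) < 0))
    qpcr_error("qpcr_domain_error", "variance parameters must be >= 0")
  n_cells <- prod(lengths(factors))
  n_samples_cell <- samples_per_cell * max(n_groups, 1)
  if (n_samples_cell < 2)
    qpcr_error("qpcr_config_error", "need >= 2 samples per factor cell")
  structure(list(genes = genes, factors = factors,
                 interactions = interactions, reference = reference,
                 terms = terms, effects = effects,
                 n_groups = n_groups, samples_per_cell = samples_per_cell,
                 tech_reps = tech_reps, sd_loading = sd_loading,
                 sd_group = sd_group, sd_sample = sd_sample,
                 v_resid = v_resid, n_cells = n_cells),
            class = "simulation_truth")
}

#' Coral-study-like simulation preset
#'
#' A 2 x 2 factorial (condition: control/heat, timepoint: t1/t2, with
#' interaction) over 8 genotype groups, one sample per cell per group
#' (32 samples), 2 technical replicates and 15 genes whose baseline
#' abundances span 5 to 5000 molecules per reaction — so the lowest genes
#' produce no-amplification trials, exercising the zero-count pathway.
#' Two mid-abundance genes are designated stable controls.  All assays
#' amplify with efficiency 2 and single-molecule cycle 37.
#'
#' @param effects optional genes x terms effect matrix (log scale); default
#'   all zero (a null dataset).
#' @param n_genes number of genes (default 15).
#' @return `simulation_truth` (control genes in attribute
#'   `control_genes`).
#' @export
coral_truth <- function(effects = NULL, n_genes = 15) {
  gene_names <- sprintf("gene%02d", seq_len(n_genes))
  ctrl <- gene_names[c(ceiling(n_genes / 2), ceiling(n_genes / 2) + 1L)]
  genes <- data.frame(gene = gene_names,
                      intercept = seq(log(5), log(5000),
                                      length.out = n_genes),
                      E = 2, cq1 = 37, stringsAsFactors = FALSE)
  tr <- simulation_truth(
    genes,
    factors = list(condition = c("control", "heat"),
                   timepoint = c("t1", "t2")),
    interactions = list(c("condition", "timepoint")),
    effects = effects,
    n_groups = 8, samples_per_cell = 1, tech_reps = 2)
  attr(tr, "control_genes") <- ctrl
  tr
}

#' Simulate a dataset from a known truth
#'
#' Draws the loading, grouping, sample and residual effects from their
#' Gaussians, forms the Poisson rate
#' `exp(I_g + B_ig + t_k + a_jg + s_kg + e)`, draws counts, and
#' back-converts counts to Cq through the exponential amplification model
#' (`Cq = Cq1 - log_E(count)`; zero counts become no-amplification trials).
#' Deterministic under the seed.
#'
#' @param truth a [simulation_truth()].
#' @param seed integer seed.
#' @return list with `cq` (`cq_dataset`), `counts` (`count_dataset`),
#'   `eff` (`efficiency_table`) and the `truth` echo.
#' @export
simulate_dataset <- function(truth, seed = 1) {
  set.seed(seed)
  G <- nrow(truth$genes)
  cells <- expand.grid(truth$factors, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  n_cells <- nrow(cells)
  groups <- if (truth$n_groups > 0)
    sprintf("group%02d", seq_len(truth$n_groups)) else "nogroup"
  # one row per biological sample
  samples <- expand.grid(cell = seq_len(n_cells), group = groups,
                         rep = seq_len(truth$samples_per_cell),
                         stringsAsFactors = FALSE)
  samples$sample_id <- sprintf("s%03d", seq_len(nrow(samples)))
  K <- nrow(samples)

  t_k <- rnorm(K, 0, truth$sd_loading)
  # no grouping factor => no grouping effect (the placeholder level exists
  # only to keep the layout bookkeeping uniform)
  a_jg <- if (truth$n_groups > 0)
    matrix(rnorm(length(groups) * G), length(groups), G) *
      rep(truth$sd_group, each = length(groups))
  else matrix(0, 1, G)
  s_kg <- matrix(rnorm(K * G), K, G) * rep(truth$sd_sample, each = K)

  # effect of each cell on each gene under treatment coding
  active <- vapply(truth$terms, function(term) {
    m <- rep(TRUE, n_cells)
    for (f in names(term)) m <- m & (cells[[f]] == term[[f]])
    m
  }, logical(n_cells))
  eff_ct <- matrix(0, n_cells, G)  # cells x genes
  for (tn in colnames(truth$effects))
    eff_ct <- eff_ct + outer(active[, tn], truth$effects[, tn])

  rows <- vector("list", K)
  for (k in seq_len(K)) {
    cell <- samples$cell[k]
    gidx <- match(samples$group[k], groups)
    n_obs <- G * truth$tech_reps
    e <- rnorm(n_obs, 0, rep(sqrt(truth$v_resid), truth$tech_reps))
    lograte <- rep(truth$genes$intercept + eff_ct[cell, ] +
                     t_k[k] + a_jg[gidx, ] + s_kg[k, ], truth$tech_reps) + e
    if (any(lograte > 700))
      qpcr_error("qpcr_truth_error", "log-rate overflow (> 700)")
    y <- rpois(n_obs, exp(lograte))
    df <- data.frame(
      sample_id = samples$sample_id[k],
      tech_rep = rep(seq_len(truth$tech_reps), each = G),
      cells[rep(cell, n_obs), , drop = FALSE],
      gene = rep(truth$genes$gene, truth$tech_reps),
      count = y, row.names = NULL, check.names = FALSE,
      stringsAsFactors = FALSE)
    if (truth$n_groups > 0) df$group <- samples$group[k]
    rows[[k]] <- df
  }
  long <- do.call(rbind, rows)
  facs <- c(names(truth$factors), if (truth$n_groups > 0) "group")

  gi <- match(long$gene, truth$genes$gene)
  E <- truth$genes$E[gi]; cq1 <- truth$genes$cq1[gi]
  cq <- ifelse(long$count >= 1, cq1 - log(long$count) / log(E), NA_real_)
  status <- ifelse(long$count >= 1, "ok", "no_amp")

  cqd <- cq_dataset(
    data.frame(long[c("sample_id", "tech_rep", facs, "gene")],
               cq = cq, status = status, check.names = FALSE,
               stringsAsFactors = FALSE),
    factors = facs, genes = truth$genes$gene)
  cnt <- structure(
    long[c("sample_id", "tech_rep", facs, "gene", "count")],
    factors = facs, genes = truth$genes$gene,
    drop_report = list(not_measured = 0L),
    class = c("count_dataset", "data.frame"))
  eff <- efficiency_table(truth$genes$gene, truth$genes$E, truth$genes$cq1)
  list(cq = cqd, counts = cnt, eff = eff, truth = truth)
}

#' Build a null dataset by subtract-and-shuffle
#'
#' Converts the observed Cq to efficiency-corrected values
#' (`Cq * log2(E)`, the cycles that a perfectly doubling assay would have
#' shown), removes each trial's inferred fixed treatment effects
#' (posterior means, converted from natural-log to cycle scale), and then
#' reassigns whole samples uniformly at random across the observed factor
#' combinations.  The result preserves the replicate structure but carries
#' no true treatment signal, so refits against it probe the null
#' distribution of the p-values.
#'
#' @param data the `cq_dataset` the posterior was fitted on.
#' @param post `qpcr_posterior` fitted on (the count transform of) `data`.
#' @param eff `efficiency_table` used for the conversion.
#' @param seed integer seed for the sample shuffle.
#' @return `cq_dataset` of corrected null Cq values; amplify with
#'   efficiency 2 downstream (attribute `efficiency` echoes this).
#' @export
make_null_dataset <- function(data, post, eff, seed = 1) {
  stopifnot(inherits(data, "cq_dataset"))
  design <- post$design
  if (!setequal(unique(data$gene), design$genes))
    qpcr_error("qpcr_labeling_error",
               "posterior was fitted on a different gene set")
  key_design <- paste(design$obs_info$sample_id, design$obs_info$tech_rep,
                      design$obs_info$gene, sep = "\r")
  eff_cols <- design$col_info$type == "effect"
  beta_mean <- colMeans(post$beta)
  trial_eff <- drop(design$X[, eff_cols, drop = FALSE] %*%
                      beta_mean[eff_cols])
  key_data <- paste(data$sample_id, data$tech_rep, data$gene, sep = "\r")
  idx <- match(key_data, key_design)
  if (all(is.na(idx)))
    qpcr_error("qpcr_labeling_error",
               "posterior trials do not match this dataset")
  effect <- ifelse(is.na(idx), 0, trial_eff[idx])

  E <- eff$E[eff_lookup(eff, data$gene)]
  out <- as.data.frame(data)
  ok <- data$status == "ok"
  # corrected Cq, plus the inferred effect converted to cycles: removing an
  # effect from abundance adds cycles
  out$cq[ok] <- data$cq[ok] * log2(E[ok]) + effect[ok] / log(2)

  set.seed(seed)
  facs <- attr(data, "factors")
  fixed_facs <- intersect(facs, names(design$levels_by_factor))
  smp <- unique(out[, c("sample_id", fixed_facs)])
  perm <- sample(nrow(smp))
  new_levels <- smp[perm, fixed_facs, drop = FALSE]
  for (f in fixed_facs) {
    map <- stats::setNames(new_levels[[f]], smp$sample_id)
    out[[f]] <- as.character(map[out$sample_id])
  }
  res <- cq_dataset(out, factors = facs, genes = attr(data, "genes"))
  attr(res, "efficiency") <- 2
  res
}
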
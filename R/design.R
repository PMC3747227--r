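#' Describe the model to be fitted
#'
#' Captures the fixed/random structure of the joint gene-expression model
#' and the control-gene prior regime.  Fixed effects are gene-specific:
#' every gene gets an intercept (its expression under the reference
#' combination of factor levels) plus one effect per non-reference level of
#' each fixed factor and per declared interaction cell, under
#' treatment-contrast (dummy) coding.  Random terms: a sample-level loading
#' effect shared across genes (`include_loading`), gene-specific effects of
#' any grouping factors (block, genotype, ...), and a gene-specific
#' sample effect separable from the residual only when technical replicates
#' exist.
#'
#' @param fixed_factors character vector of fixed factor names.
#' @param interactions list of character vectors, each a tuple of fixed
#'   factor names whose interaction enters the model.
#' @param reference_levels named character vector overriding the default
#'   (lexicographically first) reference level per factor.
#' @param grouping_factors character vector of grouping (random) factor
#'   names; may be empty.
#' @param control_genes genes assumed near-stable across conditions.
#' @param stability the average fold-change control genes are allowed
#'   across conditions (default 1.2; 1 means perfectly stable).
#' @param stability_scale how "vary m-fold on average" maps to a prior SD on
#'   the log scale: `"mean_abs"` sets the prior mean absolute log fold-change
#'   to `log(m)` (SD `log(m) * sqrt(pi/2)`); `"sd"` uses `log(m)` directly.
#' @param fix_control_fixed_effects if `TRUE`, control-gene effects are
#'   pinned to zero (prior variance 1e-6) — the "fixed" regime.
#' @param fix_control_variances optional positive value at which the
#'   control genes' grouping and sample variance components are fixed.
#' @param include_loading include the sample loading effect (`TRUE` for the
#'   count models; the classic model drops it after normalization).
#' @param gene_specific_residual one residual log-variance per gene
#'   (default) or a single shared one.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(fixed_factors, interactions = list(),
                       reference_levels = NULL,
                       grouping_factors = character(),
                       control_genes = character(),
                       stability = 1.2,
                       stability_scale = c("mean_abs", "sd"),
                       fix_control_fixed_effects = FALSE,
                       fix_control_variances = NULL,
                       include_loading = TRUE,
                       gene_specific_residual = TRUE) {
  stability_scale <- match.arg(stability_scale)
  if (stability < 1)
    qpcr_error("qpcr_domain_error", "stability parameter must be >= 1")
  if (!is.null(fix_control_variances) && fix_control_variances <= 0)
    qpcr_error("qpcr_domain_error", "fix_control_variances must be positive")
  for (ia in interactions)
    if (!all(ia %in% fixed_factors))
      qpcr_error("qpcr_config_error",
                 "interaction names a factor not in fixed_factors")
  structure(list(
    fixed_factors = fixed_factors, interactions = interactions,
    reference_levels = reference_levels,
    grouping_factors = grouping_factors,
    control_genes = control_genes, stability = stability,
    stability_scale = stability_scale,
    fix_control_fixed_effects = fix_control_fixed_effects,
    fix_control_variances = fix_control_variances,
    include_loading = include_loading,
    gene_specific_residual = gene_specific_residual
  ), class = "model_spec")
}

# Enumerate fixed-effect terms under treatment coding.  Each term is a named
# character vector of factor = level requirements; its label joins them as
# "factor=level" with ":".  Shared by the design builder, the simulator and
# the contrast resolver so that all three agree on the parameterization.
enumerate_terms <- function(levels_by_factor, reference, interactions) {
  terms <- list()
  for (f in names(levels_by_factor)) {
    for (l in setdiff(levels_by_factor[[f]], reference[[f]]))
      terms[[length(terms) + 1L]] <- stats::setNames(l, f)
  }
  for (ia in interactions) {
    cells <- expand.grid(lapply(ia, function(f)
      setdiff(levels_by_factor[[f]], reference[[f]])),
      stringsAsFactors = FALSE)
    names(cells) <- ia
    for (r in seq_len(nrow(cells)))
      terms[[length(terms) + 1L]] <-
        stats::setNames(as.character(cells[r, ]), ia)
  }
  names(terms) <- vapply(terms, function(tt)
    paste(paste0(names(tt), "=", tt), collapse = ":"), "")
  terms
}

term_matches <- function(term, factor_cols) {
  m <- rep(TRUE, nrow(factor_cols))
  for (f in names(term)) m <- m & (factor_cols[[f]] == term[[f]])
  m
}

#' Build design matrices for the joint mixed model
#'
#' Expands a `model_spec` against a dataset into the fixed-effect incidence
#' matrix (gene intercepts and gene-by-treatment effect columns) and the
#' random-effect blocks: the shared sample loading block, one
#' (grouping level, gene) block per grouping factor, and the (sample, gene)
#' block, which is included only when technical replicates are present —
#' without them its variance is not separable from the residual and is
#' merged into it.
#'
#' @param spec a [model_spec()].
#' @param data a `count_dataset` or `la_dataset`.
#' @return object of class `qpcr_design`: fixed matrix `X` with parseable
#'   column metadata `col_info` (gene, term, type), random `blocks`, residual
#'   grouping, and the observation table.
#' @export
build_design <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"))
  facs <- attr(data, "factors")
  miss <- setdiff(c(spec$fixed_factors, spec$grouping_factors), facs)
  if (length(miss))
    qpcr_error("qpcr_config_error",
               paste0("factor(s) not in dataset: ", paste(miss, collapse = ", ")))
  genes <- sort(unique(data$gene))
  bad <- setdiff(spec$control_genes, genes)
  if (length(bad))
    qpcr_error("qpcr_config_error",
               paste0("control gene(s) absent from data: ",
                      paste(bad, collapse = ", ")))
  n <- nrow(data)
  levels_by_factor <- lapply(spec$fixed_factors, function(f)
    sort(unique(as.character(data[[f]]))))
  names(levels_by_factor) <- spec$fixed_factors
  single <- names(levels_by_factor)[lengths(levels_by_factor) < 2L]
  if (length(single))
    qpcr_error("qpcr_design_error",
               paste0("fixed factor(s) with a single observed level: ",
                      paste(single, collapse = ", ")))
  reference <- lapply(levels_by_factor, `[`, 1L)
  for (f in names(spec$reference_levels)) {
    if (!(spec$reference_levels[[f]] %in% levels_by_factor[[f]]))
      qpcr_error("qpcr_config_error",
                 paste0("reference level '", spec$reference_levels[[f]],
                        "' not observed for factor '", f, "'"))
    reference[[f]] <- spec$reference_levels[[f]]
  }
  terms <- enumerate_terms(levels_by_factor, reference, spec$interactions)
  G <- length(genes); Tn <- length(terms)
  gene_idx <- match(data$gene, genes)
  factor_cols <- as.data.frame(data)[, spec$fixed_factors, drop = FALSE]

  X <- matrix(0, n, G * (1L + Tn))
  col_info <- data.frame(gene = character(0), term = character(0),
                         type = character(0), stringsAsFactors = FALSE)
  cn <- character(ncol(X))
  col <- 0L
  for (g in seq_len(G)) {
    col <- col + 1L
    X[gene_idx == g, col] <- 1
    cn[col] <- paste0("gene=", genes[g], "|(intercept)")
    col_info[col, ] <- list(genes[g], "(intercept)", "intercept")
  }
  term_mask <- lapply(terms, term_matches, factor_cols = factor_cols)
  for (g in seq_len(G)) {
    gm <- gene_idx == g
    for (ti in seq_along(terms)) {
      col <- col + 1L
      X[gm & term_mask[[ti]], col] <- 1
      cn[col] <- paste0("gene=", genes[g], "|", names(terms)[ti])
      col_info[col, ] <- list(genes[g], names(terms)[ti], "effect")
    }
  }
  colnames(X) <- cn

  sample_f <- factor(data$sample_id)
  blocks <- list()
  if (spec$include_loading) {
    blocks$loading <- list(
      name = "loading",
      index = as.integer(sample_f), ncol = nlevels(sample_f),
      labels = paste0("loading|", levels(sample_f)),
      vargroup = rep(1L, nlevels(sample_f)),
      vg_labels = "loading", vg_gene = NA_character_)
  }
  for (gf in spec$grouping_factors) {
    gl <- factor(as.character(data[[gf]]))
    comb <- factor(paste0(as.character(gl), "\r", data$gene))
    lv <- levels(comb)
    lv_gene <- sub("^.*\r", "", lv)
    blocks[[paste0("group:", gf)]] <- list(
      name = paste0("group:", gf),
      index = as.integer(comb), ncol = length(lv),
      labels = paste0(gf, "|", sub("\r", ":", lv)),
      vargroup = match(lv_gene, genes),
      vg_labels = paste0(gf, ":", genes), vg_gene = genes)
  }
  has_tech_reps <- anyDuplicated(paste(data$sample_id, data$gene, sep = "\r")) > 0L
  if (has_tech_reps) {
    comb <- factor(paste0(data$sample_id, "\r", data$gene))
    lv <- levels(comb)
    lv_gene <- sub("^.*\r", "", lv)
    blocks$sample_gene <- list(
      name = "sample_gene",
      index = as.integer(comb), ncol = length(lv),
      labels = paste0("sample|", sub("\r", ":", lv)),
      vargroup = match(lv_gene, genes),
      vg_labels = paste0("sample:", genes), vg_gene = genes)
  }
  if (spec$gene_specific_residual) {
    res_group <- gene_idx
    res_labels <- paste0("residual:", genes)
    res_gene <- genes
  } else {
    res_group <- rep(1L, n)
    res_labels <- "residual"
    res_gene <- NA_character_
  }
  obs_info <- data.frame(sample_id = data$sample_id, tech_rep = data$tech_rep,
                         factor_cols, gene = data$gene,
                         check.names = FALSE, stringsAsFactors = FALSE)
  structure(list(
    X = X, col_info = col_info, blocks = blocks,
    res_group = res_group, res_labels = res_labels, res_gene = res_gene,
    genes = genes, terms = terms, reference = reference,
    levels_by_factor = levels_by_factor,
    has_tech_reps = has_tech_reps, obs_info = obs_info, spec = spec
  ), class = "qpcr_design")
}

#' Build the prior specification for a design
#'
#' Fixed effects get independent zero-mean normal priors: diffuse
#' (variance 1e8) except for control-gene treatment effects, whose variance
#' encodes the stability assumption — under the default mapping the prior
#' mean absolute log fold-change equals `log(m)`, so
#' `sd = log(m) * sqrt(pi/2)`; the "fixed" regime pins them near zero
#' (variance 1e-6).  Variance components get near-flat inverse-gamma priors
#' (shape = scale = 1e-3) so that posterior means approximate maximum
#' likelihood, except control-gene grouping/sample components optionally
#' fixed at a given value.
#'
#' @param spec the [model_spec()] the design was built from.
#' @param design a [build_design()] result.
#' @return object of class `qpcr_priors` with `beta_var` (per fixed column)
#'   and `vc` (one row per variance component).
#' @export
build_priors <- function(spec, design) {
  ci <- design$col_info
  beta_var <- rep(1e8, nrow(ci))
  is_control_eff <- ci$type == "effect" & ci$gene %in% spec$control_genes
  if (any(is_control_eff)) {
    if (spec$fix_control_fixed_effects) {
      sc2 <- 1e-6
    } else {
      s <- log(spec$stability)
      if (spec$stability_scale == "mean_abs") s <- s * sqrt(pi / 2)
      sc2 <- max(s^2, 1e-6)
    }
    beta_var[is_control_eff] <- sc2
  }
  vc <- data.frame(block = character(0), label = character(0),
                   gene = character(0), kind = character(0),
                   shape = numeric(0), scale = numeric(0), value = numeric(0),
                   stringsAsFactors = FALSE)
  add_vc <- function(vc, block, labels, gene) {
    kind <- rep("weak", length(labels))
    value <- rep(NA_real_, length(labels))
    if (!is.null(spec$fix_control_variances) &&
        block %in% c("group", "sample_gene")) {
      fixed <- !is.na(gene) & gene %in% spec$control_genes
      kind[fixed] <- "fixed"
      value[fixed] <- spec$fix_control_variances
    }
    rbind(vc, data.frame(block = block, label = labels, gene = gene,
                         kind = kind, shape = 1e-3, scale = 1e-3,
                         value = value, stringsAsFactors = FALSE))
  }
  for (b in design$blocks) {
    block_kind <- if (startsWith(b$name, "group:")) "group" else b$name
    vc <- add_vc(vc, block_kind, b$vg_labels,
                 if (is.null(b$vg_gene)) NA_character_ else b$vg_gene)
  }
  vc_res <- data.frame(block = "residual", label = design$res_labels,
                       gene = design$res_gene, kind = "weak",
                       shape = 1e-3, scale = 1e-3, value = NA_real_,
                       stringsAsFactors = FALSE)
  structure(list(beta_var = beta_var, vc = vc, vc_res = vc_res),
            class = "qpcr_priors")
}
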
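#' Write a Cq dataset as a wide CSV table
#'
#' Inverse of [read_cq_table()]: one row per (sample, technical replicate),
#' factor columns, then one Cq column per gene.  No-amplification trials
#' are written as the `no_amp` token, unmeasured wells as empty cells.
#'
#' @param data `cq_dataset`.
#' @param path output CSV path.
#' @param no_amp token for failed amplifications.
#' @return `path`, invisibly.
#' @export
write_cq_table <- function(data, path, no_amp = "ND") {
  facs <- attr(data, "factors")
  genes <- attr(data, "genes")
  base <- unique(as.data.frame(data)[, c("sample_id", "tech_rep", facs)])
  names(base)[1:2] <- c("sample", "tech.rep")
  key <- paste(data$sample_id, data$tech_rep, sep = "\r")
  bkey <- paste(base$sample, base$tech.rep, sep = "\r")
  for (g in genes) {
    rows <- data$gene == g
    cell <- rep("", nrow(base))
    i <- match(key[rows], bkey)
    val <- ifelse(data$status[rows] == "ok",
                  formatC(data$cq[rows], digits = 10, format = "g"),
                  ifelse(data$status[rows] == "no_amp", no_amp, ""))
    cell[i] <- val
    base[[g]] <- cell
  }
  write.csv(base, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an efficiency table from CSV
#'
#' Columns: `gene`, `E`, optional `cq1`.
#'
#' @param path CSV path.
#' @return `efficiency_table`.
#' @export
read_efficiency_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "E") %in% names(tab)))
    qpcr_error("qpcr_schema_error",
               "efficiency table needs columns 'gene' and 'E'")
  efficiency_table(tab$gene, tab$E, if ("cq1" %in% names(tab)) tab$cq1)
}

model_spec_from_config <- function(mc, kind) {
  model_spec(
    fixed_factors = as.character(mc$fixed_factors),
    interactions = lapply(mc$interactions %||% list(), as.character),
    reference_levels = mc$reference_levels,
    grouping_factors = as.character(mc$grouping_factors %||% character()),
    control_genes = as.character(mc$control_genes %||% character()),
    stability = mc$stability %||% 1.2,
    stability_scale = mc$stability_scale %||% "mean_abs",
    fix_control_fixed_effects = identical(kind, "fixed"),
    fix_control_variances = mc$fix_control_variances,
    include_loading = !identical(kind, "classic"),
    gene_specific_residual = mc$gene_specific_residual %||% TRUE)
}

#' Run the full analysis pipeline from a configuration
#'
#' Convert, design, fit, summarize and diagnose in one call, writing all
#' artifacts (effect summary, posterior draws, diagnostics, drop reports
#' and a run log) into an output directory.  The configuration is a list
#' or a YAML file with blocks `input` (`cq_table`, `efficiency_table`,
#' `factor_names`, `gene_names`, optional `no_amp` token), `model`
#' (fixed/grouping factors, interactions, control genes, stability),
#' `mcmc` (nitt/burnin/thin/seed), plus `model_kind` (one of `naive`,
#' `informed`, `fixed`, `classic`, `lognormal`), `cq1_policy`/`cq1_value`
#' and `outdir`.
#'
#' @param config list or YAML file path.
#' @return invisibly, a list with the fitted posterior, the effect summary
#'   and the artifact paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  kind <- match.arg(config$model_kind,
                    c("naive", "informed", "fixed", "classic", "lognormal"))
  mc <- config$model %||% list()
  if (kind %in% c("informed", "fixed", "classic") &&
      length(mc$control_genes %||% character()) == 0)
    qpcr_error("qpcr_config_error",
               paste0("model kind '", kind, "' requires control genes"))
  if (kind == "naive") mc$control_genes <- character()

  inp <- config$input
  data <- read_cq_table(inp$cq_table, as.character(inp$factor_names),
                        as.character(inp$gene_names),
                        sample_col = inp$sample_col %||% "sample",
                        rep_col = inp$rep_col %||% "tech.rep",
                        no_amp = inp$no_amp %||% "ND")
  eff <- read_efficiency_table(inp$efficiency_table)
  spec <- model_spec_from_config(mc, kind)
  settings <- do.call(mcmc_settings, c(config$mcmc %||% list(),
                                       list(retain_latents = TRUE)))

  outdir <- config$outdir %||% "."
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)

  if (kind == "classic") {
    la <- cq_to_log_abundance(data, eff)
    post <- fit_classic(la, spec, settings)
    write_long_table(la, p("log_abundance.csv"))
  } else if (kind == "lognormal") {
    la <- cq_to_log_abundance(data, eff)
    design <- build_design(spec, la)
    post <- fit_lognormal_glmm(la, design, build_priors(spec, design),
                               settings)
    write_long_table(la, p("log_abundance.csv"))
  } else {
    counts <- cq_to_counts(data, eff,
                           cq1_policy = config$cq1_policy %||% "uniform",
                           cq1_value = config$cq1_value %||% 37)
    design <- build_design(spec, counts)
    post <- fit_pln_glmm(counts, design, build_priors(spec, design),
                         settings)
    write_long_table(counts, p("counts.csv"))
  }
  effects <- summarize_effects(post)
  write_summary(effects, p("effects.csv"))
  write_posterior(post, p("posterior.csv"))
  diag <- compute_diagnostics(post)
  write_diagnostics(diag, p("diagnostics.csv"))
  log <- list(model_kind = kind, settings = unclass(post$settings),
              control_genes = spec$control_genes,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(log, p("run.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(posterior = post, effects = effects, diagnostics = diag,
                 outdir = outdir))
}
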
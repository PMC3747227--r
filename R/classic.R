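#' Multi-gene geometric-mean normalization
#'
#' Classic qPCR normalization: within each (sample, technical replicate)
#' trial group, the arithmetic mean of the control genes' log abundances
#' (equivalently, the log of the geometric mean of their abundances) is
#' subtracted from every gene's log abundance.  Normalizing per trial group
#' rather than per sample also removes technical-replicate loading noise.
#'
#' @param data `la_dataset`.
#' @param control_genes one or more control genes; with a single gene this
#'   reduces to the classic delta-Ct against that gene.
#' @return `normalized_dataset`: the input with `la` replaced by normalized
#'   values and a `normalizer` column recording what was subtracted.
#' @export
normalize_multigene <- function(data, control_genes) {
  stopifnot(inherits(data, "la_dataset") ||
            inherits(data, "normalized_dataset"))
  if (length(control_genes) < 1)
    qpcr_error("qpcr_config_error", "need at least one control gene")
  grp <- paste(data$sample_id, data$tech_rep, sep = "\r")
  is_ctrl <- data$gene %in% control_genes
  ctrl_n <- tapply(data$gene[is_ctrl], grp[is_ctrl],
                   function(g) length(unique(g)))
  full <- names(ctrl_n)[ctrl_n == length(unique(control_genes))]
  bad <- setdiff(unique(grp), full)
  if (length(bad))
    qpcr_error("qpcr_normalization_error",
               paste0("trial group(s) missing a control gene: ",
                      paste(gsub("\r", "/", head(bad, 5)), collapse = ", ")))
  norm <- tapply(data$la[is_ctrl], grp[is_ctrl], mean)
  normalizer <- as.numeric(norm[grp])
  out <- as.data.frame(data)
  out$la <- out$la - normalizer
  out$normalizer <- normalizer
  structure(out, factors = attr(data, "factors"),
            genes = attr(data, "genes"),
            control_genes = control_genes,
            drop_report = attr(data, "drop_report"),
            class = c("normalized_dataset", "la_dataset", "data.frame"))
}

#' Fit the classic normalized lognormal model
#'
#' The single-model Bayesian version of the traditional analysis:
#' efficiency-corrected log abundances are normalized against the control
#' genes' geometric mean and then fitted with the joint lognormal mixed
#' model *without* the sample-loading term (normalization already removed
#' loading variation).  Control genes stay in the fit with diffuse effect
#' priors; their (near-zero) estimated effects act as sanity indicators.
#' Because the response is log-scale, trials with no amplification cannot
#' enter and are dropped upstream; this route suits datasets whose
#' abundances stay well clear of the shot-noise zone.
#'
#' @param data `la_dataset` from [cq_to_log_abundance()].
#' @param spec [model_spec()] with non-empty `control_genes`.
#' @param settings [mcmc_settings()].
#' @return `qpcr_posterior`.
#' @export
fit_classic <- function(data, spec, settings = mcmc_settings()) {
  if (length(spec$control_genes) == 0)
    qpcr_error("qpcr_config_error",
               "the classic model requires control genes")
  dr <- attr(data, "drop_report")
  if (!is.null(dr) && (dr$no_amp %||% 0) > 0)
    warning(dr$no_amp, " no-amplification trial(s) were dropped before the ",
            "classic (log-scale) fit", call. = FALSE)
  nd <- normalize_multigene(data, spec$control_genes)
  spec_fit <- spec
  spec_fit$include_loading <- FALSE
  design <- build_design(spec_fit, nd)
  # normalization already encodes the stability assumption; effects of all
  # genes, controls included, get diffuse priors here
  spec_prior <- spec_fit
  spec_prior$control_genes <- character()
  priors <- build_priors(spec_prior, design)
  fit_lognormal_glmm(nd, design, priors, settings)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
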
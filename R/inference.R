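#' Bayesian tail-area and z-test p-values for one parameter
#'
#' `p_mcmc` is twice the fraction of draws lying on the opposite side of
#' zero from the posterior mean, floored at `2/M` (the smallest non-zero
#' value resolvable from M draws).  `p_z` approximates the posterior by a
#' normal and reports the two-tailed standard-normal tail of
#' mean/SD — it can go below the `2/M` floor and, on approximately normal
#' posteriors, agrees closely with the tail-area value.
#'
#' @param draws numeric vector of at least 100 finite posterior draws.
#' @return list with `p_mcmc` and `p_z`, both in (0, 1].
#' @export
posterior_pvalues <- function(draws) {
  if (length(draws) < 100 || any(!is.finite(draws)))
    qpcr_error("qpcr_domain_error", "need >= 100 finite draws")
  m <- mean(draws); s <- sd(draws)
  if (s == 0)
    qpcr_error("qpcr_degenerate_error",
               "degenerate (zero-variance) posterior sample")
  M <- length(draws)
  k <- if (m >= 0) sum(draws <= 0) else sum(draws >= 0)
  p_mcmc <- min(1, max(2 * k / M, 2 / M))
  p_z <- min(1, 2 * pnorm(-abs(m / s)))
  list(p_mcmc = p_mcmc, p_z = max(p_z, .Machine$double.xmin))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' @param p vector of p-values in (0, 1].
#' @return adjusted p-values (step-up, monotone in the input ranks).
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p > 1))
    qpcr_error("qpcr_domain_error", "p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

# Shortest interval containing a given posterior mass; falls back to
# quantile intervals on request.
interval_from_draws <- function(draws, level, type = c("hpd", "quantile")) {
  type <- match.arg(type)
  if (type == "quantile") {
    q <- quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2),
                  names = FALSE)
    return(c(lower = q[1], upper = q[2]))
  }
  h <- coda::HPDinterval(coda::mcmc(as.matrix(draws)), prob = level)
  c(lower = h[1, "lower"], upper = h[1, "upper"])
}

#' Summarize fixed effects of a fitted model
#'
#' One row per (gene, term): posterior mean (a natural-log fold change for
#' treatment terms), a credible interval (highest posterior density by
#' default), the Bayesian tail-area and z-test p-values, and z-test
#' p-values FDR-adjusted jointly across all treatment-effect tests of the
#' model.  Gene intercepts are reported for completeness but carry no
#' adjusted p-value (a baseline abundance is not a null-hypothesis test).
#'
#' @param post `qpcr_posterior`.
#' @param alpha 1 - credible level (default 0.05 for 95% intervals).
#' @param interval `"hpd"` or `"quantile"`.
#' @return data.frame of class `effect_summary`.
#' @export
summarize_effects <- function(post, alpha = 0.05,
                              interval = c("hpd", "quantile")) {
  interval <- match.arg(interval)
  ci <- post$col_info
  level <- 1 - alpha
  out <- ci
  out$mean <- colMeans(post$beta)
  ints <- t(apply(post$beta, 2, interval_from_draws,
                  level = level, type = interval))
  out$lower <- ints[, 1]; out$upper <- ints[, 2]
  pv <- apply(post$beta, 2, posterior_pvalues)
  out$p_mcmc <- vapply(pv, `[[`, 0, "p_mcmc")
  out$p_z <- vapply(pv, `[[`, 0, "p_z")
  out$p_adj <- NA_real_
  eff <- out$type == "effect"
  out$p_adj[eff] <- bh_adjust(out$p_z[eff])
  out$is_control <- out$gene %in% post$design$spec$control_genes
  rownames(out) <- NULL
  structure(out, alpha = alpha, interval = interval,
            class = c("effect_summary", "data.frame"))
}

# Map a factor-combination (named character vector, unset factors at their
# reference level) to, per gene, the fixed-effect columns it activates.
resolve_combination <- function(design, combination) {
  combo <- vapply(design$reference, identity, "")
  if (length(combination)) {
    bad <- setdiff(names(combination), names(combo))
    if (length(bad))
      qpcr_error("qpcr_config_error",
                 paste0("unknown factor(s) in combination: ",
                        paste(bad, collapse = ", ")))
    for (f in names(combination)) {
      if (!(combination[[f]] %in% design$levels_by_factor[[f]]))
        qpcr_error("qpcr_config_error",
                   paste0("level '", combination[[f]],
                          "' not observed for factor '", f, "'"))
      combo[f] <- combination[[f]]
    }
  }
  active <- vapply(design$terms, function(term)
    all(combo[names(term)] == term), TRUE)
  list(combo = combo, active_terms = names(design$terms)[active])
}

combo_label <- function(combo)
  paste(paste0(names(combo), "=", combo), collapse = ",")

# M x G matrix of draws of the linear predictor at a combination
# (optionally without the gene intercepts).
combination_draws <- function(post, combination, include_intercept = TRUE) {
  design <- post$design
  rc <- resolve_combination(design, combination)
  ci <- post$col_info
  genes <- design$genes
  out <- matrix(0, nrow(post$beta), length(genes),
                dimnames = list(NULL, genes))
  for (g in genes) {
    keep <- ci$gene == g &
      ((include_intercept & ci$type == "intercept") |
         (ci$type == "effect" & ci$term %in% rc$active_terms))
    if (any(keep))
      out[, g] <- rowSums(post$beta[, keep, drop = FALSE])
  }
  attr(out, "label") <- combo_label(rc$combo)
  out
}

#' Pairwise contrasts between factor combinations
#'
#' Draw-wise differences of the linear predictor between two factor
#' combinations, per gene — useful when factors have more than two levels,
#' where single model coefficients only compare against the reference.
#' Gene intercepts cancel, so a contrast is a log fold-change.
#'
#' @param post `qpcr_posterior`.
#' @param pairs list of pairs; each pair is a list of two named character
#'   vectors (factor = level; unset factors sit at the reference level).
#' @inheritParams summarize_effects
#' @return data.frame of class `contrast_summary` with one row per
#'   (gene, pair); p-values FDR-adjusted within this contrast family.
#' @export
pairwise_contrasts <- function(post, pairs, alpha = 0.05,
                               interval = c("hpd", "quantile")) {
  interval <- match.arg(interval)
  level <- 1 - alpha
  rows <- list()
  for (pr in pairs) {
    da <- combination_draws(post, pr[[1]], include_intercept = FALSE)
    db <- combination_draws(post, pr[[2]], include_intercept = FALSE)
    lab <- paste0(attr(da, "label"), " - ", attr(db, "label"))
    for (g in colnames(da)) {
      d <- da[, g] - db[, g]
      m <- mean(d)
      if (sd(d) == 0) {
        # contrast of a combination with itself: exactly zero by construction
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, contrast = lab, mean = 0, lower = 0, upper = 0,
          p_mcmc = 1, p_z = 1, stringsAsFactors = FALSE)
        next
      }
      int <- interval_from_draws(d, level, interval)
      pv <- posterior_pvalues(d)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, contrast = lab, mean = m,
        lower = int[1], upper = int[2],
        p_mcmc = pv$p_mcmc, p_z = pv$p_z, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p_z)
  rownames(out) <- NULL
  structure(out, alpha = alpha,
            class = c("contrast_summary", "data.frame"))
}

#' Posterior predicted log abundances per condition
#'
#' Draw-wise gene intercept plus all treatment effects active at each
#' requested factor combination, summarized with credible intervals — the
#' model's estimate of (log) transcript abundance of each gene under each
#' condition of interest.
#'
#' @param post `qpcr_posterior`.
#' @param combinations list of named character vectors (factor = level);
#'   unset factors sit at the reference level.
#' @inheritParams summarize_effects
#' @return data.frame with one row per (gene, combination).
#' @export
predict_abundances <- function(post, combinations, alpha = 0.05,
                               interval = c("hpd", "quantile")) {
  interval <- match.arg(interval)
  level <- 1 - alpha
  rows <- list()
  for (cmb in combinations) {
    d <- combination_draws(post, cmb, include_intercept = TRUE)
    lab <- attr(d, "label")
    for (g in colnames(d)) {
      int <- interval_from_draws(d[, g], level, interval)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, combination = lab, mean = mean(d[, g]),
        lower = int[1], upper = int[2], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an effect or contrast summary as CSV
#' @param x summary data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
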
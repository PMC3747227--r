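#' MCMC run settings
#'
#' @param nitt total iterations (default 13000).
#' @param burnin discarded initial iterations (default 3000); proposal
#'   adaptation happens only here, so detailed balance holds afterwards.
#' @param thin keep every `thin`-th post-burnin iteration (default 10,
#'   giving M = 1000 retained draws — the resolution of the 2/M tail-area
#'   p-value floor).
#' @param seed integer seed; fits are bitwise reproducible given the seed.
#' @param adapt_target Metropolis acceptance rate targeted during burn-in.
#' @param retain_latents keep per-observation linear predictors and latent
#'   log-rates for goodness-of-fit diagnostics (costs memory).
#' @return object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(nitt = 13000, burnin = 3000, thin = 10, seed = 1,
                          adapt_target = 0.44, retain_latents = FALSE) {
  if (thin < 1 || burnin < 0 || nitt <= burnin)
    qpcr_error("qpcr_config_error", "need nitt > burnin >= 0 and thin >= 1")
  M <- floor((nitt - burnin) / thin)
  if (M < 100)
    qpcr_error("qpcr_config_error",
               paste0("settings retain only ", M,
                      " draws; need at least 100"))
  structure(list(nitt = as.integer(nitt), burnin = as.integer(burnin),
                 thin = as.integer(thin), seed = as.integer(seed),
                 adapt_target = adapt_target,
                 retain_latents = retain_latents, M = M),
            class = "mcmc_settings")
}

# Shared Metropolis-within-Gibbs engine.
#
# Hierarchical form: y_i ~ Poisson(exp(psi_i)), psi_i ~ N(eta_i, v_g(i)),
# eta = X beta + sum_b Z_b u_b.  The psi_i are data-augmentation variables:
# integrating them out recovers the Poisson-lognormal observation model.
# Conditional on psi the model is linear-Gaussian; all location effects
# (beta and every u_b) are drawn in ONE Gaussian block from the sparse
# mixed-model equations — separate block updates mix far too slowly here
# because the loading effects are strongly correlated with the
# gene-by-treatment effects.  Variance components have conjugate
# inverse-gamma updates; psi is updated by elementwise random-walk
# Metropolis (its conditionals are independent across observations).  The
# Gaussian family sets psi = observed log abundance and skips the
# Metropolis step, leaving a plain Gibbs sampler for the lognormal model.
run_mwg <- function(y, family, design, priors, settings) {
  set.seed(settings$seed)
  X <- design$X
  n <- nrow(X); P <- ncol(X)
  res_group <- design$res_group
  nres <- length(design$res_labels)
  n_per_res <- tabulate(res_group, nres)
  blocks <- design$blocks
  nb <- length(blocks)

  # variance-component bookkeeping: block components then residuals
  vc_tab <- rbind(priors$vc, priors$vc_res)
  vg_offset <- integer(nb)
  u_offset <- integer(nb)
  off <- 0L; uoff <- 0L
  for (bi in seq_len(nb)) {
    vg_offset[bi] <- off
    off <- off + length(blocks[[bi]]$vg_labels)
    u_offset[bi] <- uoff
    uoff <- uoff + blocks[[bi]]$ncol
  }
  res_offset <- off
  Q <- uoff
  nvc <- nrow(vc_tab)
  stopifnot(nvc == res_offset + nres)
  vc_fixed <- vc_tab$kind == "fixed"
  vc_shape <- vc_tab$shape; vc_scale <- vc_tab$scale

  # sparse joint incidence matrix C = [X | Z_1 | ... | Z_nb]
  Xs <- methods::as(Matrix::Matrix(X, sparse = TRUE), "CsparseMatrix")
  Zs <- lapply(seq_len(nb), function(bi) {
    b <- blocks[[bi]]
    Matrix::sparseMatrix(i = seq_len(n), j = b$index, x = 1,
                         dims = c(n, b$ncol))
  })
  C <- do.call(cbind, c(list(Xs), Zs))
  Ct <- Matrix::t(C)
  # map each u column to its variance-component row
  u_vcidx <- unlist(lapply(seq_len(nb), function(bi)
    vg_offset[bi] + blocks[[bi]]$vargroup))

  # initial state: least squares on the log scale, variances at 1
  z0 <- if (family == "pln") log(y + 0.5) else y
  beta <- tryCatch(qr.coef(qr(X), z0), error = function(e) rep(0, P))
  beta[!is.finite(beta)] <- 0
  theta <- c(beta, numeric(Q))
  sigma2 <- rep(1, nvc)
  sigma2[vc_fixed] <- vc_tab$value[vc_fixed]
  psi <- z0
  step <- rep(0.5, n)
  chol_sym <- NULL  # symbolic factorization, reused across iterations

  M <- settings$M
  beta_draws <- matrix(NA_real_, M, P,
                       dimnames = list(NULL, colnames(X)))
  vc_draws <- matrix(NA_real_, M, nvc,
                     dimnames = list(NULL, vc_tab$label))
  mu_draws <- if (settings$retain_latents) matrix(NA_real_, M, n) else NULL
  psi_draws <- if (settings$retain_latents && family == "pln")
    matrix(NA_real_, M, n) else NULL
  acc_sum <- numeric(n); acc_n <- 0L

  eta <- as.numeric(C %*% theta)
  m <- 0L
  for (iter in seq_len(settings$nitt)) {
    v_res <- sigma2[res_offset + seq_len(nres)]
    w <- 1 / v_res[res_group]

    if (family == "pln") {
      # elementwise random-walk Metropolis on the latent log-rates
      for (sweep in 1:2) {
        prop <- psi + step * rnorm(n)
        llr <- y * (prop - psi) - (exp(prop) - exp(psi)) -
          0.5 * w * ((prop - eta)^2 - (psi - eta)^2)
        acc <- log(runif(n)) < llr
        psi[acc] <- prop[acc]
        if (iter <= settings$burnin) {
          gamma <- min(0.05, 1 / sqrt(iter))
          step <- step * exp(gamma * (acc - settings$adapt_target))
          step <- pmin(pmax(step, 1e-3), 10)
        } else {
          acc_sum <- acc_sum + acc
          acc_n <- acc_n + 1L
        }
      }
    }

    # joint draw of all location effects | psi, variances
    prior_prec <- c(1 / priors$beta_var, 1 / sigma2[u_vcidx])
    A <- Matrix::forceSymmetric(
      Ct %*% (w * C) + Matrix::Diagonal(x = prior_prec))
    if (is.null(chol_sym)) {
      chol_sym <- Matrix::Cholesky(A, LDL = FALSE, perm = TRUE)
    } else {
      chol_sym <- Matrix::update(chol_sym, A)
    }
    b_vec <- as.numeric(Ct %*% (w * psi))
    mean_t <- as.numeric(Matrix::solve(chol_sym, b_vec, system = "A"))
    zdraw <- rnorm(P + Q)
    pert <- Matrix::solve(chol_sym,
                          Matrix::solve(chol_sym, zdraw, system = "Lt"),
                          system = "Pt")
    theta <- mean_t + as.numeric(pert)
    beta <- theta[seq_len(P)]
    eta <- as.numeric(C %*% theta)

    # variance components of the random-effect blocks
    u_all <- theta[P + seq_len(Q)]
    for (bi in seq_len(nb)) {
      b <- blocks[[bi]]
      u_b <- u_all[u_offset[bi] + seq_len(b$ncol)]
      idx <- vg_offset[bi] + seq_along(b$vg_labels)
      SS <- as.vector(rowsum(u_b^2, b$vargroup))
      nj <- tabulate(b$vargroup, length(b$vg_labels))
      draw <- (vc_scale[idx] + SS / 2) /
        rgamma(length(idx), vc_shape[idx] + nj / 2)
      keep_fixed <- vc_fixed[idx]
      draw[keep_fixed] <- sigma2[idx][keep_fixed]
      sigma2[idx] <- pmax(draw, 1e-10)
    }

    # gene-specific residual variances
    e <- psi - eta
    idx <- res_offset + seq_len(nres)
    SSe <- as.vector(rowsum(e^2, res_group))
    draw <- (vc_scale[idx] + SSe / 2) /
      rgamma(nres, vc_shape[idx] + n_per_res / 2)
    keep_fixed <- vc_fixed[idx]
    draw[keep_fixed] <- sigma2[idx][keep_fixed]
    sigma2[idx] <- pmax(draw, 1e-10)

    if (!all(is.finite(theta)) || !all(is.finite(psi)))
      qpcr_error("qpcr_runtime_error",
                 paste0("chain diverged (non-finite state) at iteration ",
                        iter))

    if (iter > settings$burnin &&
        (iter - settings$burnin) %% settings$thin == 0L && m < M) {
      m <- m + 1L
      beta_draws[m, ] <- beta
      vc_draws[m, ] <- sigma2
      if (!is.null(mu_draws)) mu_draws[m, ] <- eta
      if (!is.null(psi_draws)) psi_draws[m, ] <- psi
    }
  }

  ess <- tryCatch(as.numeric(coda::effectiveSize(coda::mcmc(beta_draws))),
                  error = function(e) rep(NA_real_, P))
  names(ess) <- colnames(X)
  low <- names(ess)[!is.na(ess) & ess < 100]
  if (length(low))
    warning("effective sample size below 100 for ",
            length(low), " parameter(s), e.g. ", low[1], call. = FALSE)

  structure(list(
    beta = beta_draws, vc = vc_draws, vc_info = vc_tab,
    col_info = design$col_info, design = design, family = family,
    settings = settings, y = y,
    acceptance = if (acc_n > 0) acc_sum / acc_n else NULL,
    ess = ess,
    latents = if (settings$retain_latents)
      list(mu = mu_draws, psi = psi_draws) else NULL
  ), class = "qpcr_posterior")
}

#' Fit the joint Poisson-lognormal mixed model
#'
#' Samples the posterior of the full hierarchical count model: counts are
#' Poisson with a lognormal rate whose log is the sum of gene intercepts,
#' gene-specific treatment effects, a shared sample-loading effect,
#' grouping and sample random effects, and a gene-specific residual.
#' Zero counts (failed amplifications) contribute likelihood and are never
#' dropped.  See [mcmc_settings()] for chain control; runs are
#' deterministic under a fixed seed.
#'
#' @param data a `count_dataset` from [cq_to_counts()] or
#'   [simulate_dataset()].
#' @param design a [build_design()] result.
#' @param priors a [build_priors()] result.
#' @param settings an [mcmc_settings()] object.
#' @return object of class `qpcr_posterior` holding labeled draw matrices
#'   for fixed effects (`beta`) and variance components (`vc`), effective
#'   sample sizes, acceptance rates and (optionally) latent states.
#' @export
fit_pln_glmm <- function(data, design, priors, settings = mcmc_settings()) {
  stopifnot(inherits(data, "count_dataset"))
  y <- data$count
  if (any(y < 0) || any(y != round(y)))
    qpcr_error("qpcr_type_error", "counts must be non-negative integers")
  zero_genes <- names(which(tapply(y, data$gene, function(x) all(x == 0))))
  if (length(zero_genes))
    warning("gene(s) with no detected amplification at all: ",
            paste(zero_genes, collapse = ", "),
            " - their posteriors will be wide", call. = FALSE)
  run_mwg(as.numeric(y), "pln", design, priors, settings)
}

#' Fit the lognormal mixed model on log relative abundances
#'
#' The Gaussian-observation counterpart of [fit_pln_glmm()], used when
#' abundances are high enough that shot noise is negligible, and as the
#' engine of the classic normalized analysis.  Fully conjugate Gibbs
#' updates; same posterior contract and reproducibility guarantees.
#'
#' @param data a `la_dataset` from [cq_to_log_abundance()] or a
#'   `normalized_dataset`.
#' @inheritParams fit_pln_glmm
#' @return `qpcr_posterior`.
#' @export
fit_lognormal_glmm <- function(data, design, priors,
                               settings = mcmc_settings()) {
  stopifnot(inherits(data, "la_dataset") ||
            inherits(data, "normalized_dataset"))
  la <- data$la
  if (any(!is.finite(la)))
    qpcr_error("qpcr_type_error", "log abundances must be finite")
  run_mwg(as.numeric(la), "gaussian", design, priors, settings)
}

#' @export
print.qpcr_posterior <- function(x, ...) {
  cat("qpcr_posterior:", x$settings$M, "draws of", ncol(x$beta),
      "fixed effects and", ncol(x$vc), "variance components\n")
  cat("  family:", x$family, "\n")
  cat("  genes:", length(x$design$genes), " observations:",
      nrow(x$design$X), "\n")
  if (!is.null(x$acceptance))
    cat("  mean latent acceptance:",
        round(mean(x$acceptance), 3), "\n")
  invisible(x)
}

#' Export posterior draws
#'
#' Writes fixed-effect and variance-component draws as one CSV (columns =
#' labeled parameters) and a JSON sidecar with settings and diagnostics.
#'
#' @param post `qpcr_posterior`.
#' @param path CSV path; sidecar goes to `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_posterior <- function(post, path) {
  write.csv(cbind(as.data.frame(post$beta), as.data.frame(post$vc)),
            path, row.names = FALSE)
  meta <- list(settings = unclass(post$settings), family = post$family,
               ess = as.list(post$ess),
               mean_acceptance = if (!is.null(post$acceptance))
                 mean(post$acceptance) else NULL)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
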
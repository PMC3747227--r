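#' Goodness-of-fit diagnostics for a fitted model
#'
#' Builds the four standard checks on one bundle: (a) lognormal residuals
#' against predicted log values (linearity), (b) square-root absolute
#' standardized residuals against predicted values (homoscedasticity;
#' a fitted trend slope is reported), (c) normal QQ pairs of standardized
#' residuals, and (d), for count fits, randomized probability-integral-
#' transform (PIT) values of each observed count under its sampled Poisson
#' rate paired with uniform theoretical quantiles — under a correct model
#' these are uniform, confirming that low-abundance variance inflation is
#' pure Poisson shot noise.
#'
#' @param post `qpcr_posterior` fitted with `retain_latents = TRUE`.
#' @param draw_policy `"posterior_mean"` uses posterior-mean latents for
#'   residuals; `"single_draw"` conditions everything on one retained draw.
#'   PIT values always condition on a single draw (`draw_index`).
#' @param draw_index which retained draw to use (default: last).
#' @return object of class `diagnostics_bundle`: per-observation table,
#'   sorted QQ pairs, sorted PIT pairs (counts only) and the
#'   scale-location trend test.
#' @export
compute_diagnostics <- function(post,
                                draw_policy = c("posterior_mean",
                                                "single_draw"),
                                draw_index = NULL) {
  draw_policy <- match.arg(draw_policy)
  if (is.null(post$latents))
    qpcr_error("qpcr_state_error",
               "latent states were not retained; refit with mcmc_settings(retain_latents = TRUE)")
  if (is.null(draw_index)) draw_index <- nrow(post$beta)
  mu <- if (draw_policy == "single_draw") post$latents$mu[draw_index, ]
        else colMeans(post$latents$mu)
  design <- post$design
  res_cols <- match(design$res_labels, colnames(post$vc))
  v_g <- if (draw_policy == "single_draw") post$vc[draw_index, res_cols]
         else colMeans(post$vc[, res_cols, drop = FALSE])
  v_obs <- as.numeric(v_g)[design$res_group]

  proxy <- if (post$family == "pln") log(post$y + 0.5) else post$y
  resid <- proxy - mu
  std <- resid / sqrt(v_obs)
  tab <- cbind(design$obs_info,
               predicted = mu, residual = resid, std_residual = std,
               sqrt_abs_std = sqrt(abs(std)))

  qq <- data.frame(theoretical = qnorm(ppoints(length(std))),
                   observed = sort(std))

  pit <- NULL
  if (post$family == "pln") {
    lambda <- exp(post$latents$psi[draw_index, ])
    y <- post$y
    u <- ppois(y - 1, lambda) + runif(length(y)) * dpois(y, lambda)
    pit <- data.frame(theoretical = ppoints(length(u)),
                      observed = sort(u))
  }

  fit <- lm(sqrt(abs(std)) ~ mu)
  sl <- summary(fit)$coefficients
  trend <- list(slope = unname(sl["mu", "Estimate"]),
                p = unname(sl["mu", "Pr(>|t|)"]))

  structure(list(table = tab, qq = qq, pit = pit, trend = trend,
                 draw_policy = draw_policy, draw_index = draw_index,
                 family = post$family),
            class = "diagnostics_bundle")
}

#' Plot a diagnostics bundle
#'
#' Four base-graphics panels: residuals vs predicted, scale-location,
#' normal QQ, and (for count fits) the PIT uniformity plot.
#'
#' @param x `diagnostics_bundle`.
#' @param ... ignored.
#' @export
plot.diagnostics_bundle <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  with(x$table, {
    plot(predicted, residual, pch = 16, cex = 0.5,
         main = "Residuals vs predicted")
    graphics::abline(h = 0, col = 2)
    plot(predicted, sqrt_abs_std, pch = 16, cex = 0.5,
         main = "Scale-location")
    graphics::abline(lm(sqrt_abs_std ~ predicted), col = 2)
  })
  plot(x$qq$theoretical, x$qq$observed, pch = 16, cex = 0.5,
       main = "Normal QQ", xlab = "theoretical", ylab = "observed")
  graphics::abline(0, 1, col = 2)
  if (!is.null(x$pit)) {
    plot(x$pit$theoretical, x$pit$observed, pch = 16, cex = 0.5,
         main = "Poisson PIT", xlab = "uniform quantile", ylab = "PIT")
    graphics::abline(0, 1, col = 2)
  }
  invisible(x)
}

#' Write a diagnostics bundle as CSV
#' @param x `diagnostics_bundle`.
#' @param path output path for the per-observation table; QQ and PIT pairs
#'   go to `<path>.qq.csv` / `<path>.pit.csv`.
#' @return `path`, invisibly.
#' @export
write_diagnostics <- function(x, path) {
  write.csv(x$table, path, row.names = FALSE)
  write.csv(x$qq, paste0(path, ".qq.csv"), row.names = FALSE)
  if (!is.null(x$pit))
    write.csv(x$pit, paste0(path, ".pit.csv"), row.names = FALSE)
  invisible(path)
}
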
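toy3_post <- function() cached("toy3_post", {
  genes <- data.frame(gene = c("g01", "g02", "g03"),
                      intercept = log(c(2000, 6000, 15000)),
                      E = 2, cq1 = 37)
  tr <- simulation_truth(genes,
                         factors = list(condition = c("a", "b", "c")),
                         samples_per_cell = 4, tech_reps = 2)
  tr$effects["g01", "condition=b"] <- log(3)
  sim <- simulate_dataset(tr, seed = 12)
  la <- cq_to_log_abundance(sim$cq, sim$eff)
  spec <- model_spec(fixed_factors = "condition")
  d <- build_design(spec, la)
  suppressWarnings(
    fit_lognormal_glmm(la, d, build_priors(spec, d),
                       quick_settings(seed = 5)))
})

test_that("tail-area p-values follow the 2/M floor and z-test rules", {
  set.seed(1)
  all_pos <- abs(rnorm(1000)) + 0.01
  p <- posterior_pvalues(all_pos)
  expect_equal(p$p_mcmc, 0.002)           # 2/M at M = 1000

  x <- c(rnorm(975, 5, 0.5), -abs(rnorm(25, 1, 0.2)))  # 25 cross zero
  expect_equal(posterior_pvalues(x)$p_mcmc, 0.05)

  sym <- c(rnorm(500), 0) ; sym <- c(sym, -sym)         # exactly mean 0
  expect_equal(posterior_pvalues(sym)$p_z, 1)

  set.seed(2)
  strong <- rnorm(1000, log(4), 0.01)
  ps <- posterior_pvalues(strong)
  expect_lt(ps$p_z, 1e-6)
  expect_equal(mean(strong), log(4), tolerance = 0.01)

  expect_error(posterior_pvalues(rep(1, 1000)),
               class = "qpcr_degenerate_error")
  expect_error(posterior_pvalues(rnorm(50)), class = "qpcr_domain_error")
})

test_that("BH adjustment reproduces the step-up rule", {
  # by hand: p_(i) * m / i = {0.04, 0.04, 0.04, 0.04} after monotonization
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.1, 0)), class = "qpcr_domain_error")
  expect_error(bh_adjust(c(0.1, 1.2)), class = "qpcr_domain_error")
})

test_that("effect summaries satisfy their interval and p-value contracts", {
  es <- summarize_effects(toy3_post())
  expect_s3_class(es, "effect_summary")
  expect_true(all(es$lower <= es$mean & es$mean <= es$upper))
  expect_true(all(es$p_mcmc > 0 & es$p_mcmc <= 1))
  eff <- es[es$type == "effect", ]
  expect_true(all(eff$p_adj >= eff$p_z))
  expect_true(all(is.na(es$p_adj[es$type == "intercept"])))
  # the planted 3-fold effect is detected
  hit <- eff[eff$gene == "g01" & eff$term == "condition=b", ]
  expect_lt(hit$lower, log(3)); expect_gt(hit$upper, log(3))
  expect_lt(hit$p_adj, 0.01)
  # quantile intervals selectable
  esq <- summarize_effects(toy3_post(), interval = "quantile")
  expect_true(all(esq$lower <= esq$mean & esq$mean <= esq$upper))
})

test_that("contrasts reduce to coefficients and subtract draw-wise", {
  post <- toy3_post()
  es <- summarize_effects(post)
  # (b vs reference) contrast is exactly the condition=b coefficient
  cb <- pairwise_contrasts(post, list(list(c(condition = "b"),
                                           c(condition = "a"))))
  for (g in post$design$genes) {
    expect_equal(cb$mean[cb$gene == g],
                 es$mean[es$gene == g & es$term == "condition=b"])
  }
  # three-level factor: contrast(b, c) = B_b - B_c per draw
  cbc <- pairwise_contrasts(post, list(list(c(condition = "b"),
                                            c(condition = "c"))))
  for (g in post$design$genes) {
    manual <- post$beta[, paste0("gene=", g, "|condition=b")] -
      post$beta[, paste0("gene=", g, "|condition=c")]
    expect_equal(cbc$mean[cbc$gene == g], mean(manual))
  }
  # self-contrast is identically zero with p = 1
  self <- pairwise_contrasts(post, list(list(c(condition = "b"),
                                             c(condition = "b"))))
  expect_true(all(self$mean == 0 & self$p_mcmc == 1))
  # antisymmetry under pair swap
  rev <- pairwise_contrasts(post, list(list(c(condition = "c"),
                                            c(condition = "b"))))
  expect_equal(rev$mean, -cbc$mean)
  expect_equal(rev$p_z, cbc$p_z)
  expect_error(
    pairwise_contrasts(post, list(list(c(condition = "zz"),
                                       c(condition = "a")))),
    class = "qpcr_config_error")
})

toy22_post <- function() cached("toy22_post", {
  genes <- data.frame(gene = c("g01", "g02"),
                      intercept = log(c(3000, 9000)), E = 2, cq1 = 37)
  tr <- simulation_truth(genes,
                         factors = list(condition = c("control", "heat"),
                                        timepoint = c("t1", "t2")),
                         interactions = list(c("condition", "timepoint")),
                         samples_per_cell = 2, tech_reps = 2)
  tr$effects["g01", "condition=heat"] <- log(2)
  tr$effects["g01", "condition=heat:timepoint=t2"] <- -log(2)
  sim <- simulate_dataset(tr, seed = 7)
  la <- cq_to_log_abundance(sim$cq, sim$eff)
  spec <- model_spec(fixed_factors = c("condition", "timepoint"),
                     interactions = list(c("condition", "timepoint")))
  d <- build_design(spec, la)
  suppressWarnings(
    fit_lognormal_glmm(la, d, build_priors(spec, d),
                       quick_settings(seed = 11)))
})

test_that("abundance predictions assemble the right linear combinations", {
  post <- toy22_post()
  es <- summarize_effects(post)
  pr <- predict_abundances(post, list(
    c(condition = "control", timepoint = "t1"),
    c(condition = "heat", timepoint = "t2")))
  for (g in post$design$genes) {
    # reference combination is the intercept alone
    ref <- pr[pr$gene == g & grepl("control", pr$combination), ]
    expect_equal(ref$mean,
                 es$mean[es$gene == g & es$term == "(intercept)"])
    # treated cell includes main effects plus the interaction
    manual <- post$beta[, paste0("gene=", g, "|(intercept)")] +
      post$beta[, paste0("gene=", g, "|condition=heat")] +
      post$beta[, paste0("gene=", g, "|timepoint=t2")] +
      post$beta[, paste0("gene=", g, "|condition=heat:timepoint=t2")]
    trt <- pr[pr$gene == g & grepl("heat", pr$combination), ]
    expect_equal(trt$mean, mean(manual))
  }
  # prediction difference reproduces the effect summary (linearity)
  ct <- pairwise_contrasts(post, list(list(
    c(condition = "heat", timepoint = "t1"),
    c(condition = "control", timepoint = "t1"))))
  for (g in post$design$genes)
    expect_equal(ct$mean[ct$gene == g],
                 es$mean[es$gene == g & es$term == "condition=heat"])
})
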
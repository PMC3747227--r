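coral_fixture <- function() cached("coral_design", {
  sim <- simulate_dataset(coral_truth(), seed = 5)
  spec <- model_spec(fixed_factors = c("condition", "timepoint"),
                     interactions = list(c("condition", "timepoint")),
                     grouping_factors = "group",
                     control_genes = attr(coral_truth(), "control_genes"))
  list(sim = sim, spec = spec, design = build_design(spec, sim$counts))
})

test_that("fixed-effect columns enumerate gene intercepts and treatment cells", {
  d <- coral_fixture()$design
  ci <- d$col_info
  expect_equal(sum(ci$type == "intercept"), 15L)
  expect_equal(sum(ci$type == "effect"), 45L)  # 15 genes x 3 terms
  expect_setequal(unique(ci$term[ci$type == "effect"]),
                  c("condition=heat", "timepoint=t2",
                    "condition=heat:timepoint=t2"))
  # identifiability on the complete factorial
  expect_equal(qr(d$X)$rank, ncol(d$X))
  # reference combination maps to the intercept alone
  ref_rows <- d$obs_info$condition == "control" & d$obs_info$timepoint == "t1"
  expect_true(all(d$X[ref_rows, ci$type == "effect"] == 0))
})

test_that("a one-gene one-factor design is minimal", {
  tr <- toy_truth(log(100))
  sim <- simulate_dataset(tr, seed = 2)
  d <- build_design(toy_spec(), sim$counts)
  expect_equal(nrow(d$col_info), 2L)
  expect_equal(d$col_info$term, c("(intercept)", "condition=b"))
})

test_that("the sample-gene block needs technical replicates", {
  tr1 <- toy_truth(c(log(100), log(200)), tech_reps = 1)
  d1 <- build_design(toy_spec(), simulate_dataset(tr1, seed = 3)$counts)
  expect_false("sample_gene" %in% names(d1$blocks))
  expect_false(d1$has_tech_reps)
  tr2 <- toy_truth(c(log(100), log(200)), tech_reps = 2)
  d2 <- build_design(toy_spec(), simulate_dataset(tr2, seed = 3)$counts)
  expect_true("sample_gene" %in% names(d2$blocks))
})

test_that("loading block is shared across genes, grouping blocks are not", {
  d <- coral_fixture()$design
  expect_equal(length(d$blocks$loading$vg_labels), 1L)
  expect_equal(d$blocks$loading$ncol, 32L)           # one column per sample
  expect_equal(d$blocks$`group:group`$ncol, 8L * 15L) # (colony, gene)
  expect_equal(length(d$blocks$`group:group`$vg_labels), 15L)
})

test_that("design errors are specific", {
  sim <- coral_fixture()$sim
  expect_error(build_design(model_spec("nonexistent"), sim$counts),
               class = "qpcr_config_error")
  expect_error(
    build_design(model_spec(c("condition", "timepoint"),
                            control_genes = "nosuchgene"), sim$counts),
    class = "qpcr_config_error")
  one_level <- sim$counts[sim$counts$condition == "control", ]
  attr(one_level, "factors") <- attr(sim$counts, "factors")
  attr(one_level, "genes") <- attr(sim$counts, "genes")
  class(one_level) <- class(sim$counts)
  expect_error(build_design(model_spec(c("condition", "timepoint")),
                            one_level),
               class = "qpcr_design_error")
})

test_that("stability maps to a prior whose mean absolute effect is log(m)", {
  fx <- coral_fixture()
  pri <- build_priors(fx$spec, fx$design)
  ctrl <- fx$design$col_info$type == "effect" &
    fx$design$col_info$gene %in% fx$spec$control_genes
  sc <- sqrt(unique(pri$beta_var[ctrl]))
  expect_equal(sc, log(1.2) * sqrt(pi / 2), tolerance = 1e-12)
  # E|N(0, sc^2)| = sc * sqrt(2/pi) must recover log(m)
  expect_equal(sc * sqrt(2 / pi), log(1.2), tolerance = 1e-12)
  expect_true(all(pri$beta_var[!ctrl] == 1e8))

  # alternative mapping: sd = log(m) directly
  spec_sd <- fx$spec; spec_sd$stability_scale <- "sd"
  pri_sd <- build_priors(spec_sd, fx$design)
  expect_equal(sqrt(unique(pri_sd$beta_var[ctrl])), log(1.2))
})

test_that("prior regimes are ordered: fixed < informed < naive", {
  fx <- coral_fixture()
  informed <- build_priors(fx$spec, fx$design)
  spec_fix <- fx$spec; spec_fix$fix_control_fixed_effects <- TRUE
  fixed <- build_priors(spec_fix, fx$design)
  spec_naive <- fx$spec; spec_naive$control_genes <- character()
  naive <- build_priors(spec_naive, build_design(spec_naive, fx$sim$counts))
  ctrl <- fx$design$col_info$type == "effect" &
    fx$design$col_info$gene %in% fx$spec$control_genes
  expect_lt(unique(fixed$beta_var[ctrl]), unique(informed$beta_var[ctrl]))
  expect_lt(unique(informed$beta_var[ctrl]), 1e8)
  expect_true(all(naive$beta_var == 1e8))

  # perfectly stable limit m = 1
  spec1 <- fx$spec; spec1$stability <- 1
  pri1 <- build_priors(spec1, fx$design)
  expect_equal(unique(pri1$beta_var[ctrl]), 1e-6)
  expect_error(model_spec("condition", stability = 0.8),
               class = "qpcr_domain_error")
})

test_that("control variance fixation targets grouping and sample components", {
  fx <- coral_fixture()
  spec_v <- fx$spec; spec_v$fix_control_variances <- 0.01
  pri <- build_priors(spec_v, fx$design)
  fixed_rows <- pri$vc$kind == "fixed"
  expect_true(all(pri$vc$gene[fixed_rows] %in% fx$spec$control_genes))
  expect_true(all(pri$vc$block[fixed_rows] %in% c("group", "sample_gene")))
  expect_equal(sum(fixed_rows), 2L * 2L)  # 2 controls x {group, sample}
  expect_true(all(pri$vc$value[fixed_rows] == 0.01))
  expect_true(all(pri$vc_res$kind == "weak"))
})
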
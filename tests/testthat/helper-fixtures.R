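# Fixtures are built in code; heavier fits are cached for the session so
# several test files can share one chain.

fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_env))
    assign(key, force(expr), envir = fixture_env)
  get(key, envir = fixture_env)
}

# quick chain settings for unit tests (M = 250 retained draws)
quick_settings <- function(seed = 1, ...)
  mcmc_settings(nitt = 3000, burnin = 500, thin = 10, seed = seed, ...)

# a small 2-condition truth: `genes` baseline log-abundances, one fixed
# factor, no grouping, optional per-gene "condition=b" effects
toy_truth <- function(intercepts, effects_b = NULL, samples_per_cell = 4,
                      tech_reps = 2, ...) {
  G <- length(intercepts)
  genes <- data.frame(gene = sprintf("g%02d", seq_len(G)),
                      intercept = intercepts, E = 2, cq1 = 37)
  tr <- simulation_truth(genes,
                         factors = list(condition = c("a", "b")),
                         samples_per_cell = samples_per_cell,
                         tech_reps = tech_reps, ...)
  if (!is.null(effects_b)) tr$effects[, "condition=b"] <- effects_b
  tr
}

toy_spec <- function(...) model_spec(fixed_factors = "condition", ...)

# build an la_dataset directly (for conjugate sub-case checks)
manual_la <- function(la, gene = "g1", factors = character()) {
  n <- length(la)
  df <- data.frame(sample_id = sprintf("s%03d", seq_len(n)),
                   tech_rep = 1L, gene = gene, la = la,
                   cq_corrected = -la / log(2),
                   stringsAsFactors = FALSE)
  structure(df, factors = factors, genes = unique(gene),
            drop_report = list(no_amp = 0L, not_measured = 0L),
            class = c("la_dataset", "data.frame"))
}

# wide toy Cq CSV on disk; returns the path
write_toy_csv <- function(lines, file = tempfile(fileext = ".csv")) {
  writeLines(lines, file)
  file
}
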
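test_that("wide Cq tables expand row-by-gene with the sentinel dialect", {
  path <- write_toy_csv(c(
    "sample,tech.rep,condition,timepoint,geneA,geneB",
    "s1,1,control,t1,21.5,30.0",
    "s1,2,control,t1,21.7,ND",
    "s2,1,heat,t2,19.9,",
    "s2,2,heat,t2,20.1,31.2"))
  ds <- read_cq_table(path, c("condition", "timepoint"), c("geneA", "geneB"))
  expect_s3_class(ds, "cq_dataset")
  expect_equal(nrow(ds), 8L)
  rep <- attr(ds, "cell_report")
  expect_equal(unname(rep["numeric"]), 6L)
  expect_equal(unname(rep["no_amp"]), 1L)
  expect_equal(unname(rep["not_measured"]), 1L)
  expect_equal(ds$status[ds$sample_id == "s1" & ds$tech_rep == 2 &
                           ds$gene == "geneB"], "no_amp")
  expect_equal(ds$status[ds$sample_id == "s2" & ds$tech_rep == 1 &
                           ds$gene == "geneB"], "not_measured")
  # every cell maps to exactly one state
  expect_true(all(ds$status %in% c("ok", "no_amp", "not_measured")))
  expect_true(all(is.finite(ds$cq[ds$status == "ok"])))
  expect_true(all(is.na(ds$cq[ds$status != "ok"])))
})

test_that("schema, uniqueness and parse violations are rejected by name", {
  base <- c("sample,tech.rep,condition,geneA",
            "s1,1,a,21.5", "s1,2,a,22.0")
  expect_error(
    read_cq_table(write_toy_csv(base), c("condition", "missing"), "geneA"),
    class = "qpcr_schema_error")
  expect_error(
    read_cq_table(write_toy_csv(base), "condition", c("geneA", "geneZ")),
    "geneZ", class = "qpcr_schema_error")
  dup <- c("sample,tech.rep,condition,geneA",
           "s1,1,a,21.5", "s1,1,a,22.0")
  expect_error(read_cq_table(write_toy_csv(dup), "condition", "geneA"),
               class = "qpcr_uniqueness_error")
  bad <- c("sample,tech.rep,condition,geneA",
           "s1,1,a,21.5", "s2,1,a,oops")
  expect_error(read_cq_table(write_toy_csv(bad), "condition", "geneA"),
               "oops", class = "qpcr_parse_error")
  incons <- c("sample,tech.rep,condition,geneA",
              "s1,1,a,21.5", "s1,2,b,22.0")
  expect_error(read_cq_table(write_toy_csv(incons), "condition", "geneA"),
               class = "qpcr_schema_error")
})

test_that("Cq1 estimators agree at the perfect-doubling anchor", {
  expect_identical(estimate_cq1(2, "empirical"), 36)
  expect_equal(estimate_cq1(2, "single_efficiency_model"), 36)
  expect_equal(estimate_cq1(1.8, "empirical"), 40.3)
  # strictly decreasing in E for both estimators
  grid <- seq(1.5, 2.2, by = 0.05)
  expect_true(all(diff(estimate_cq1(grid, "empirical")) < 0))
  expect_true(all(diff(estimate_cq1(grid, "single_efficiency_model")) < 0))
  expect_error(estimate_cq1(1), class = "qpcr_domain_error")
  expect_error(estimate_cq1(0.9), class = "qpcr_domain_error")
})

make_cq <- function(cq, status = "ok", gene = "g1", E = 2, cq1 = 37) {
  n <- length(cq)
  ds <- cq_dataset(
    data.frame(sample_id = sprintf("s%d", seq_len(n)), tech_rep = 1L,
               gene = gene, cq = cq, status = status),
    factors = character(), genes = unique(gene))
  list(ds = ds, eff = efficiency_table(unique(gene), E, cq1))
}

test_that("Cq-to-count conversion inverts exponential amplification", {
  x <- make_cq(c(37, 27))
  cnt <- cq_to_counts(x$ds, x$eff, cq1_policy = "uniform", cq1_value = 37)
  expect_identical(cnt$count, c(1L, 1024L))

  # no-amplification -> informative zero; not-measured -> dropped
  y <- make_cq(c(30, NA, NA), status = c("ok", "no_amp", "not_measured"))
  cnt <- cq_to_counts(y$ds, y$eff)
  expect_identical(cnt$count, c(128L, 0L))
  expect_equal(attr(cnt, "drop_report")$not_measured, 1L)

  # round trip: integer counts survive Cq encoding exactly
  set.seed(4)
  nvec <- c(1L, 2L, 7L, sample(1:100000, 20))
  z <- make_cq(37 - log2(nvec))
  expect_identical(cq_to_counts(z$ds, z$eff)$count, nvec)

  # non-increasing in Cq; detected trials clamp to >= 1
  w <- make_cq(seq(20, 45, by = 0.5))
  cw <- cq_to_counts(w$ds, w$eff)
  expect_true(all(diff(cw$count) <= 0))
  expect_true(all(cw$count >= 1L))

  expect_error(cq_to_counts(x$ds, efficiency_table("other", 2)),
               class = "qpcr_lookup_error")
  expect_error(cq_to_counts(x$ds, efficiency_table("g1", 2), "per_gene"),
               class = "qpcr_config_error")
})

test_that("log-abundance transform corrects for efficiency", {
  x <- make_cq(30)
  la <- cq_to_log_abundance(x$ds, x$eff)
  expect_equal(la$la, -30 * log(2))
  expect_equal(la$cq_corrected, 30)

  y <- make_cq(30, E = 2.2)  # efficiency above 2: corrected Cq grows
  la2 <- cq_to_log_abundance(y$ds, y$eff)
  expect_equal(la2$cq_corrected, 30 * log2(2.2))

  # one fewer cycle for every gene = ln(E) more log abundance
  a <- make_cq(c(25, 30, 35), gene = c("g1", "g2", "g3"))
  b <- make_cq(c(24, 29, 34), gene = c("g1", "g2", "g3"))
  expect_equal(cq_to_log_abundance(b$ds, b$eff)$la,
               cq_to_log_abundance(a$ds, a$eff)$la + log(2))

  # sentinel trials are dropped and reported
  z <- make_cq(c(30, NA), status = c("ok", "no_amp"))
  laz <- cq_to_log_abundance(z$ds, z$eff)
  expect_equal(nrow(laz), 1L)
  expect_equal(attr(laz, "drop_report")$no_amp, 1L)
})

test_that("efficiency table validates its domain", {
  expect_error(efficiency_table("g", 1.0), class = "qpcr_domain_error")
  expect_error(efficiency_table("g", 2.5), class = "qpcr_domain_error")
  expect_error(efficiency_table(c("g", "g"), c(2, 2)),
               class = "qpcr_schema_error")
})
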
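#' @importFrom stats rnorm rpois rgamma runif pnorm qnorm quantile sd var
#'   ppoints coef lsfit p.adjust ks.test cor lm rbinom dpois ppois
#' @importFrom utils read.csv write.csv head
NULL

# condition helper: all package errors carry a subclass so callers/tests can
# distinguish schema problems from parse problems etc.
qpcr_error <- function(subclass, msg, ...) {
  stop(structure(
    class = c(subclass, "qpcr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Construct a long-form Cq dataset
#'
#' A `cq_dataset` holds one row per amplification trial: a biological sample,
#' a technical replicate, the experimental factor levels of that sample, a
#' gene, and the observed quantification cycle.  Failed amplifications
#' (`status = "no_amp"`) are informative — they correspond to zero template
#' molecules — and are kept distinct from wells that were never run
#' (`status = "not_measured"`).
#'
#' @param trials data.frame with columns `sample_id`, `tech_rep`, one column
#'   per experimental factor, `gene`, `cq` (numeric, `NA` for sentinel rows)
#'   and `status` (one of `"ok"`, `"no_amp"`, `"not_measured"`).
#' @param factors character vector of factor column names.
#' @param genes character vector of gene names present in the data.
#' @return object of class `cq_dataset` (a data.frame with metadata
#'   attributes `factors` and `genes`).
#' @export
cq_dataset <- function(trials, factors, genes) {
  needed <- c("sample_id", "tech_rep", factors, "gene", "cq", "status")
  miss <- setdiff(needed, names(trials))
  if (length(miss))
    qpcr_error("qpcr_schema_error",
               paste0("missing column(s): ", paste(miss, collapse = ", ")))
  trials <- as.data.frame(trials)[, needed]
  trials$sample_id <- as.character(trials$sample_id)
  trials$gene <- as.character(trials$gene)
  trials$tech_rep <- as.integer(trials$tech_rep)
  if (any(trials$tech_rep < 1L))
    qpcr_error("qpcr_schema_error", "tech_rep must be a positive integer")
  if (!all(trials$status %in% c("ok", "no_amp", "not_measured")))
    qpcr_error("qpcr_schema_error", "status must be ok/no_amp/not_measured")
  key <- paste(trials$sample_id, trials$tech_rep, trials$gene, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    qpcr_error("qpcr_uniqueness_error",
               paste0("duplicate (sample_id, tech_rep, gene) trial: ",
                      gsub("\r", " / ", d)))
  }
  ok <- trials$status == "ok"
  if (any(!is.finite(trials$cq[ok])) ||
      any(trials$cq[ok] <= 0 | trials$cq[ok] >= 100))
    qpcr_error("qpcr_parse_error", "numeric Cq values must lie in (0, 100)")
  # factor levels must be constant within a sample
  for (f in factors) {
    lv <- tapply(as.character(trials[[f]]), trials$sample_id,
                 function(x) length(unique(x)))
    if (any(lv > 1L))
      qpcr_error("qpcr_schema_error",
                 paste0("sample(s) with inconsistent levels of factor '", f,
                        "': ", paste(names(lv)[lv > 1L], collapse = ", ")))
  }
  structure(trials, factors = factors, genes = genes,
            class = c("cq_dataset", "data.frame"))
}

#' Read a wide Cq table from CSV
#'
#' Expects a header row, one row per (sample, technical replicate), the
#' declared factor columns, and one column per gene holding the Cq value of
#' that trial.  Cell dialect: an empty cell means the well was not measured;
#' the `no_amp` token (default `"ND"`, not detected) means the reaction was
#' run but never crossed the detection threshold — an informative zero count.
#'
#' @param path CSV file path.
#' @param factor_names names of the experimental factor columns.
#' @param gene_names names of the gene columns.
#' @param sample_col,rep_col column names of the sample identifier and the
#'   technical replicate index.
#' @param no_amp token marking a failed amplification.
#' @return `cq_dataset`; attribute `cell_report` counts numeric / no-amp /
#'   not-measured cells.
#' @export
read_cq_table <- function(path, factor_names, gene_names,
                          sample_col = "sample", rep_col = "tech.rep",
                          no_amp = "ND") {
  raw <- read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c(sample_col, rep_col, factor_names, gene_names)
  miss <- setdiff(need, names(raw))
  if (length(miss))
    qpcr_error("qpcr_schema_error",
               paste0("column(s) not found in ", path, ": ",
                      paste(miss, collapse = ", ")))
  if (anyDuplicated(paste(raw[[sample_col]], raw[[rep_col]], sep = "\r"))) {
    qpcr_error("qpcr_uniqueness_error",
               "duplicate (sample, tech_rep) rows in input table")
  }
  n <- nrow(raw)
  G <- length(gene_names)
  parse_cell <- function(x, gene, row) {
    x <- trimws(x)
    if (is.na(x) || x == "" || toupper(x) == "NA")
      return(list(cq = NA_real_, status = "not_measured"))
    if (x == no_amp) return(list(cq = NA_real_, status = "no_amp"))
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v))
      qpcr_error("qpcr_parse_error",
                 paste0("cannot parse Cq cell '", x, "' (row ", row,
                        ", gene ", gene, ")"))
    list(cq = v, status = "ok")
  }
  out <- vector("list", G)
  for (gi in seq_len(G)) {
    g <- gene_names[gi]
    cells <- lapply(seq_len(n), function(r) parse_cell(raw[[g]][r], g, r))
    out[[gi]] <- data.frame(
      sample_id = raw[[sample_col]], tech_rep = as.integer(raw[[rep_col]]),
      raw[factor_names], gene = g,
      cq = vapply(cells, `[[`, 0, "cq"),
      status = vapply(cells, `[[`, "", "status"),
      check.names = FALSE, stringsAsFactors = FALSE)
  }
  trials <- do.call(rbind, out)
  ds <- cq_dataset(trials, factors = factor_names, genes = gene_names)
  attr(ds, "cell_report") <- c(
    numeric = sum(ds$status == "ok"),
    no_amp = sum(ds$status == "no_amp"),
    not_measured = sum(ds$status == "not_measured"))
  ds
}

#' Per-gene amplification efficiencies
#'
#' @param gene gene names.
#' @param E amplification factor per cycle; perfect doubling is `E = 2`.
#'   Must lie in (1, 2.2].
#' @param cq1 optional per-gene quantification cycle of a single target
#'   molecule.
#' @return data.frame of class `efficiency_table`.
#' @export
efficiency_table <- function(gene, E, cq1 = NULL) {
  if (any(!is.finite(E) | E <= 1 | E > 2.2))
    qpcr_error("qpcr_domain_error",
               "amplification efficiency must lie in (1, 2.2]")
  tab <- data.frame(gene = as.character(gene), E = as.numeric(E),
                    cq1 = if (is.null(cq1)) NA_real_ else as.numeric(cq1),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(tab$gene))
    qpcr_error("qpcr_schema_error", "duplicate gene in efficiency table")
  structure(tab, class = c("efficiency_table", "data.frame"))
}

eff_lookup <- function(eff, genes) {
  i <- match(genes, eff$gene)
  if (anyNA(i))
    qpcr_error("qpcr_lookup_error",
               paste0("no efficiency entry for gene(s): ",
                      paste(unique(genes[is.na(i)]), collapse = ", ")))
  i
}

#' Single-molecule quantification cycle from amplification efficiency
#'
#' `Cq1` is the cycle at which a reaction seeded with one target molecule
#' crosses the detection threshold.  Two estimators are offered:
#' `"empirical"`, the linear calibration `Cq1 = 79 - 21.5 E` fitted to
#' dilution series extended below one molecule per well; and
#' `"single_efficiency_model"`, the idealized exponential-amplification
#' model pinned so that a perfectly doubling assay (`E = 2`) has
#' `Cq1 = 36`, i.e. `Cq1 = 36 log(2) / log(E)`.
#'
#' @param E amplification efficiency (factor per cycle), in (1, 2.2].
#' @param method `"empirical"` (default) or `"single_efficiency_model"`.
#' @return Cq1 in cycles.
#' @export
estimate_cq1 <- function(E, method = c("empirical", "single_efficiency_model")) {
  method <- match.arg(method)
  if (any(!is.finite(E) | E <= 1))
    qpcr_error("qpcr_domain_error",
               "efficiency must exceed 1 (no amplification otherwise)")
  if (any(E > 2.2))
    qpcr_error("qpcr_domain_error", "efficiency above 2.2 is not physical")
  switch(method,
         empirical = 79 - 21.5 * E,
         single_efficiency_model = 36 * log(2) / log(E))
}

resolve_cq1 <- function(eff, genes, cq1_policy, cq1_value) {
  i <- eff_lookup(eff, genes)
  switch(cq1_policy,
         uniform = rep(cq1_value, length(genes)),
         empirical = estimate_cq1(eff$E[i], "empirical"),
         per_gene = {
           if (anyNA(eff$cq1[i]))
             qpcr_error("qpcr_config_error",
                        paste0("cq1_policy = 'per_gene' but Cq1 missing for: ",
                               paste(unique(genes[is.na(eff$cq1[i])]),
                                     collapse = ", ")))
           eff$cq1[i]
         },
         qpcr_error("qpcr_config_error",
                    paste0("unknown cq1_policy '", cq1_policy, "'")))
}

#' Convert Cq values to estimated molecule counts
#'
#' Inverts the exponential amplification process: a trial observed at cycle
#' `Cq` with per-cycle efficiency `E` started from about
#' `E^(Cq1 - Cq)` molecules, rounded to the nearest integer.  A detected
#' amplification implies at least one template molecule, so rounded counts
#' are clamped to a minimum of 1; failed amplifications become informative
#' zero counts; unmeasured wells are dropped (and reported).
#'
#' @param data `cq_dataset`.
#' @param eff `efficiency_table`.
#' @param cq1_policy how to resolve the single-molecule cycle per gene:
#'   `"uniform"` (one shared value, default 37), `"empirical"` (from the
#'   efficiency calibration, see [estimate_cq1()]) or `"per_gene"` (the
#'   `cq1` column of `eff`).
#' @param cq1_value the shared Cq1 under `cq1_policy = "uniform"`.
#' @return `count_dataset`: same keys plus integer column `count`; attribute
#'   `drop_report` lists dropped not-measured trials.
#' @export
cq_to_counts <- function(data, eff, cq1_policy = c("uniform", "empirical",
                                                   "per_gene"),
                         cq1_value = 37) {
  cq1_policy <- match.arg(cq1_policy)
  stopifnot(inherits(data, "cq_dataset"))
  keep <- data$status != "not_measured"
  dropped <- sum(!keep)
  d <- data[keep, , drop = FALSE]
  cq1 <- resolve_cq1(eff, d$gene, cq1_policy, cq1_value)
  E <- eff$E[eff_lookup(eff, d$gene)]
  count <- integer(nrow(d))
  ok <- d$status == "ok"
  count[ok] <- pmax(1L, as.integer(round(E[ok]^(cq1[ok] - d$cq[ok]))))
  count[!ok] <- 0L
  out <- d[, c("sample_id", "tech_rep", attr(data, "factors"), "gene")]
  out$count <- count
  structure(out, factors = attr(data, "factors"), genes = attr(data, "genes"),
            drop_report = list(not_measured = dropped),
            class = c("count_dataset", "data.frame"))
}

#' Convert Cq values to log relative abundances
#'
#' Efficiency-corrected log-scale transform for the lognormal ("classic")
#' analysis route: `la = -Cq * log(E)` (natural log of relative abundance,
#' defined up to a per-gene additive constant that cancels in all
#' normalizations and within-gene contrasts) and
#' `cq_corrected = Cq * log2(E)`, the cycle count that would have been
#' observed had the assay amplified with efficiency exactly 2.  Trials with
#' no amplification or no measurement carry no finite log value and are
#' dropped (counted in the attached drop report).
#'
#' @inheritParams cq_to_counts
#' @return `la_dataset` with columns `la` and `cq_corrected`; attribute
#'   `drop_report`.
#' @export
cq_to_log_abundance <- function(data, eff) {
  stopifnot(inherits(data, "cq_dataset"))
  keep <- data$status == "ok"
  rep_ <- list(no_amp = sum(data$status == "no_amp"),
               not_measured = sum(data$status == "not_measured"))
  d <- data[keep, , drop = FALSE]
  E <- eff$E[eff_lookup(eff, d$gene)]
  out <- d[, c("sample_id", "tech_rep", attr(data, "factors"), "gene")]
  out$la <- -d$cq * log(E)
  out$cq_corrected <- d$cq * log2(E)
  structure(out, factors = attr(data, "factors"), genes = attr(data, "genes"),
            drop_report = rep_,
            class = c("la_dataset", "data.frame"))
}

#' Write a long-form dataset and its drop report
#'
#' @param x `count_dataset` or `la_dataset`.
#' @param path output CSV path; the drop report goes to `<path>.drops.json`.
#' @return `path`, invisibly.
#' @export
write_long_table <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  dr <- attr(x, "drop_report")
  if (!is.null(dr))
    jsonlite::write_json(dr, paste0(path, ".drops.json"), auto_unbox = TRUE)
  invisible(path)
}
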
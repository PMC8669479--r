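## Write a TSV with a provenance comment header (tool version + parameters).
.write_tsv <- function(tab, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("cgprofiler"))
  writeLines(sprintf("# cgprofiler %s", ver), con)
  if (!is.null(params))
    writeLines(sprintf("# %s", paste(names(params), unlist(params),
                                     sep = "=", collapse = " ")), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run a pooled screen end to end
#'
#' Orchestrates the full chain on pre-demultiplexed FASTQ files: per-sample
#' barcode counting, count-matrix assembly, per-compound differential
#' abundance with hit calling, PCA of shifted-log profiles, and a
#' Table-1-style hit report (enriched strains as candidate importers,
#' depleted strains as candidate exporters). Fully deterministic given the
#' inputs; all result tables can be written under `outdir`.
#'
#' @param fastq Named character vector of FASTQ paths (names = sample ids).
#' @param reference A `barcode_reference` (or path to its TSV).
#' @param sample_sheet Data frame with `sample_id`, `compound`, `condition`,
#'   `replicate` (or path to its TSV).
#' @param config An [assign_config()].
#' @param criteria A [hit_criteria()].
#' @param outdir Optional output directory for TSV results.
#' @return List of class `screen_result`: `matrix` (count matrix),
#'   `assignment_stats` (per-sample), `tables` (per-compound
#'   `diffabund_table`s), `hits` (the [compound_hit_summary()]), `pca`.
#' @export
run_screen <- function(fastq, reference, sample_sheet,
                       config = assign_config(), criteria = hit_criteria(),
                       outdir = NULL) {
  if (is.character(reference)) reference <- parse_barcode_reference(reference)
  if (is.character(sample_sheet))
    sample_sheet <- utils::read.delim(sample_sheet, stringsAsFactors = FALSE)
  if (is.null(names(fastq)) || any(!nzchar(names(fastq))))
    stop("fastq must be a named vector (names = sample ids)", call. = FALSE)
  per_sample <- list()
  stats <- list()
  for (s in names(fastq)) {
    res <- tryCatch(count_sample(fastq[[s]], reference, config),
                    error = function(e)
                      stop("counting stage failed for sample '", s, "': ",
                           conditionMessage(e), call. = FALSE))
    per_sample[[s]] <- res$counts
    stats[[s]] <- res$stats
  }
  stats_tab <- data.frame(sample_id = names(stats),
                          do.call(rbind, stats), row.names = NULL)
  cm <- build_count_matrix(per_sample, sample_sheet, reference = reference)
  compounds <- unique(cm$sample_meta$compound[cm$sample_meta$condition ==
                                                "treated"])
  tables <- lapply(compounds, function(cp)
    tryCatch(diffabund(cm, cp, criteria),
             error = function(e)
               stop("differential-abundance stage failed for compound '",
                    cp, "': ", conditionMessage(e), call. = FALSE)))
  names(tables) <- compounds
  hits <- compound_hit_summary(tables, criteria)
  sf <- compute_size_factors(cm)
  pca <- run_pca(shifted_log_transform(cm, sf))
  out <- structure(list(matrix = cm, assignment_stats = stats_tab,
                        tables = tables, hits = hits, pca = pca),
                   class = "screen_result")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    params <- c(max_distance = config$max_distance,
                lfc = criteria$lfc_threshold, padj = criteria$padj_max,
                p = criteria$p_max)
    write_count_matrix(cm, file.path(outdir, "counts.tsv"),
                       file.path(outdir, "samples.tsv"))
    .write_tsv(stats_tab, file.path(outdir, "assignment_stats.tsv"), params)
    for (cp in names(tables))
      .write_tsv(as.data.frame(tables[[cp]]),
                 file.path(outdir, sprintf("diffabund_%s.tsv", cp)), params)
    .write_tsv(hits$report, file.path(outdir, "hit_report.tsv"), params)
    scores <- data.frame(sample_id = rownames(pca$scores),
                         pca$scores[, seq_len(min(4, ncol(pca$scores))),
                                    drop = FALSE])
    .write_tsv(scores, file.path(outdir, "pca_scores.tsv"), params)
  }
  out
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("screen_result: %d barcodes x %d samples; %d compound(s); %d with >= 1 enriched hit\n",
              nrow(x$matrix$counts), ncol(x$matrix$counts),
              length(x$tables), x$hits$n_compounds_with_enriched))
  invisible(x)
}

#' Summarize hits across compounds
#'
#' Applies one set of hit criteria uniformly to every compound's
#' differential-abundance table and reports, per compound, the enriched
#' strains (candidate importer deletions, with their log2 fold changes) and
#' depleted strains (candidate exporter deletions), plus the number of
#' compounds selecting at least one enriched strain.
#'
#' @param tables Named list of data frames with `barcode_id`, `log2fc`,
#'   `p_value` (and optionally `padj`), one per compound.
#' @param criteria A [hit_criteria()].
#' @return List with `n_compounds_with_enriched`, `per_compound` (list of
#'   `enriched` / `depleted` data frames) and `report` (long data frame:
#'   compound, strain, log2fc, call).
#' @export
compound_hit_summary <- function(tables, criteria = hit_criteria()) {
  if (length(tables) < 1L) stop("need at least one table", call. = FALSE)
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("tables must be named by compound", call. = FALSE)
  per_compound <- list()
  rows <- list()
  for (cp in names(tables)) {
    called <- call_hits(as.data.frame(tables[[cp]]), criteria)
    enr <- called[called$call == "enriched", , drop = FALSE]
    dep <- called[called$call == "depleted", , drop = FALSE]
    enr <- enr[order(-enr$log2fc), , drop = FALSE]
    dep <- dep[order(dep$log2fc), , drop = FALSE]
    per_compound[[cp]] <- list(enriched = enr, depleted = dep)
    if (nrow(enr) + nrow(dep) > 0L)
      rows[[cp]] <- data.frame(compound = cp,
                               barcode_id = c(enr$barcode_id, dep$barcode_id),
                               log2fc = c(enr$log2fc, dep$log2fc),
                               call = c(enr$call, dep$call),
                               stringsAsFactors = FALSE)
  }
  n_enriched <- sum(vapply(per_compound,
                           function(x) nrow(x$enriched) > 0L, TRUE))
  report <- if (length(rows) > 0L) do.call(rbind, c(rows, make.row.names = FALSE))
  else data.frame(compound = character(0), barcode_id = character(0),
                  log2fc = numeric(0), call = character(0))
  list(n_compounds_with_enriched = n_enriched, per_compound = per_compound,
       report = report)
}
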
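#' Median-of-ratios size factors
#'
#' Per-sample scale factors computed by the library size factor method:
#' for each barcode present in every sample, the ratio of its count to its
#' across-sample geometric mean is formed, and the size factor of a sample
#' is the median of these ratios over the reference barcode set.
#'
#' @param x A `count_matrix` or a counts matrix (barcodes x samples).
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
compute_size_factors <- function(x) {
  m <- if (inherits(x, "count_matrix")) x$counts else x
  stopifnot(is.matrix(m))
  ref <- rowSums(m > 0) == ncol(m)
  if (!any(ref))
    stop("no barcode has nonzero counts in every sample; cannot form the ",
         "median-of-ratios reference set (consider a pseudo-reference ",
         "fallback)", call. = FALSE)
  logm <- log(m[ref, , drop = FALSE])
  loggeo <- rowMeans(logm)
  sf <- apply(logm, 2L, function(col) exp(stats::median(col - loggeo)))
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("degenerate size factors", call. = FALSE)
  sf
}

#' Method-of-moments negative-binomial dispersion
#'
#' Per-barcode dispersion alpha of the NB variance function
#' `var = mu + alpha * mu^2`, estimated on normalized counts with the overall
#' mean and the pooled within-condition variance (so a genuine treatment
#' effect does not inflate alpha), floored at `floor`.
#'
#' With few replicates the raw per-barcode moment estimate is very noisy and
#' its underestimates make the LRT anti-conservative; `moderate = TRUE`
#' (default) therefore floors every barcode's dispersion at the median
#' moment estimate across barcodes, a common-dispersion moderation in the
#' spirit of tagwise/common estimation (no trend fitting).
#'
#' @param x A `count_matrix` or counts matrix.
#' @param size_factors Size factors from [compute_size_factors()].
#' @param condition Factor/character of length `ncol` giving the condition of
#'   each sample; every condition needs >= 2 replicates.
#' @param floor Lower bound for alpha (default 1e-8).
#' @param moderate Floor per-barcode estimates at the across-barcode median
#'   (default TRUE).
#' @return Named numeric vector of dispersions with attribute `flagged`
#'   (logical: barcodes with zero mean, set to the floor).
#' @export
estimate_dispersions <- function(x, size_factors, condition, floor = 1e-8,
                                 moderate = TRUE) {
  m <- if (inherits(x, "count_matrix")) x$counts else x
  condition <- as.factor(condition)
  if (any(table(condition) < 2L))
    stop("dispersion estimation needs >= 2 replicates per condition",
         call. = FALSE)
  k <- sweep(m, 2L, size_factors, "/")
  mu <- rowMeans(k)
  groups <- split(seq_len(ncol(k)), condition)
  ss <- 0; df <- 0
  for (idx in groups) {
    kg <- k[, idx, drop = FALSE]
    ss <- ss + rowSums((kg - rowMeans(kg))^2)
    df <- df + length(idx) - 1L
  }
  v <- ss / df
  alpha <- ifelse(mu > 0, pmax(floor, (v - mu) / mu^2), floor)
  if (moderate && any(mu > 0)) {
    common <- stats::median(alpha[mu > 0])
    alpha <- pmax(alpha, common)
  }
  names(alpha) <- rownames(m)
  attr(alpha, "flagged") <- mu == 0
  alpha
}

## NB log-likelihood ratio test for one barcode; theta = 1/alpha fixed.
.lrt_one <- function(y, sf, theta, condition) {
  fam <- MASS::negative.binomial(theta = theta)
  off <- log(sf)
  fit2 <- function(formula) {
    suppressWarnings(stats::glm(formula, family = fam,
                                data = data.frame(y = y, condition = condition,
                                                  off = off),
                                offset = off))
  }
  full <- tryCatch(fit2(y ~ condition), error = function(e) NULL)
  null <- tryCatch(fit2(y ~ 1), error = function(e) NULL)
  if (is.null(full) || is.null(null)) return(c(stat = NA_real_))
  c(stat = max(0, stats::deviance(null) - stats::deviance(full)))
}

#' Negative-binomial likelihood-ratio test of differential barcode abundance
#'
#' For every barcode, fits the NB model with condition-specific means (full)
#' and with one shared mean (null), size factors entering as offsets and the
#' dispersion fixed at its per-barcode estimate, and tests the condition
#' effect by the likelihood ratio against chi-square with 1 df. The reported
#' log2 fold change is the ratio of the group mean normalized counts
#' (weighted means `sum(y)/sum(s)`), with a +0.5 pseudo-normalized-count
#' applied only when a group mean is zero; the test itself never uses the
#' pseudocount.
#'
#' @param x A `count_matrix` or counts matrix.
#' @param size_factors Size factors.
#' @param dispersions Per-barcode alpha from [estimate_dispersions()].
#' @param condition Factor with exactly two levels; fold changes are the
#'   second level over the first (use
#'   `factor(..., levels = c("control", "treated"))`).
#' @return Data frame with `barcode_id`, `base_mean` (mean normalized count),
#'   `log2fc`, `p_value` and logical `flagged` (degenerate all-zero fits,
#'   reported as `log2fc = 0`, `p = 1`).
#' @export
lrt_test <- function(x, size_factors, dispersions, condition) {
  m <- if (inherits(x, "count_matrix")) x$counts else x
  condition <- as.factor(condition)
  if (nlevels(condition) != 2L)
    stop("condition must have exactly two levels", call. = FALSE)
  if (any(table(condition) < 2L))
    stop("need >= 2 replicates per condition", call. = FALSE)
  ctrl <- levels(condition)[1L]
  trt <- levels(condition)[2L]
  i_c <- condition == ctrl
  i_t <- condition == trt
  n <- nrow(m)
  out <- data.frame(barcode_id = rownames(m), base_mean = NA_real_,
                    log2fc = NA_real_, p_value = NA_real_, flagged = FALSE,
                    stringsAsFactors = FALSE)
  k <- sweep(m, 2L, size_factors, "/")
  out$base_mean <- rowMeans(k)
  q_c <- rowSums(m[, i_c, drop = FALSE]) / sum(size_factors[i_c])
  q_t <- rowSums(m[, i_t, drop = FALSE]) / sum(size_factors[i_t])
  zero <- q_c == 0 | q_t == 0
  out$log2fc <- ifelse(zero, log2((q_t + 0.5) / (q_c + 0.5)),
                       log2(q_t / q_c))
  for (i in seq_len(n)) {
    y <- m[i, ]
    if (all(y == 0)) {
      out$log2fc[i] <- 0; out$p_value[i] <- 1; out$flagged[i] <- TRUE
      next
    }
    theta <- min(1 / dispersions[i], 1e8)
    res <- .lrt_one(y, size_factors, theta, condition)
    if (is.na(res[["stat"]])) {
      out$p_value[i] <- 1; out$flagged[i] <- TRUE
    } else {
      out$p_value[i] <- stats::pchisq(res[["stat"]], df = 1,
                                      lower.tail = FALSE)
    }
  }
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of raw p values (validated to lie in \[0, 1\]).
#'
#' @param p Numeric vector of p values.
#' @return Adjusted p values, same length and order.
#' @export
adjust_bh <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Hit-calling thresholds
#'
#' The screen's significance rule: a strain is called only when the log2
#' fold change passes `lfc_threshold` in magnitude AND the raw p value and
#' the BH-adjusted p value both pass.
#'
#' @param lfc_threshold Minimum |log2FC| (default 0.5).
#' @param padj_max Maximum BH-adjusted p (default 0.1).
#' @param p_max Maximum raw p (default 0.001).
#' @return A `hit_criteria` list.
#' @export
hit_criteria <- function(lfc_threshold = 0.5, padj_max = 0.1, p_max = 0.001) {
  stopifnot(lfc_threshold > 0, padj_max > 0, padj_max <= 1, p_max > 0)
  structure(list(lfc_threshold = lfc_threshold, padj_max = padj_max,
                 p_max = p_max), class = "hit_criteria")
}

#' Call enriched (importer-candidate) and depleted (exporter-candidate) strains
#'
#' Adds `padj` (BH over the table's raw p values, unless already present)
#' and a `call` column: `enriched` when `log2fc >= lfc_threshold` with
#' `p <= p_max` and `padj <= padj_max`; `depleted` symmetrically at
#' `log2fc <= -lfc_threshold`; otherwise `ns`. In the pooled screen an
#' enriched deletion strain marks a candidate importer of the compound and a
#' depleted one a candidate exporter.
#'
#' @param rows Data frame with `log2fc`, `p_value` and optionally `padj`.
#' @param criteria A [hit_criteria()].
#' @return `rows` with `padj` and `call` columns, class `diffabund_table`.
#' @export
call_hits <- function(rows, criteria = hit_criteria()) {
  stopifnot(all(c("log2fc", "p_value") %in% names(rows)))
  if (!"padj" %in% names(rows)) rows$padj <- adjust_bh(rows$p_value)
  sig <- rows$p_value <= criteria$p_max & rows$padj <= criteria$padj_max
  rows$call <- ifelse(sig & rows$log2fc >= criteria$lfc_threshold, "enriched",
               ifelse(sig & rows$log2fc <= -criteria$lfc_threshold, "depleted",
                      "ns"))
  class(rows) <- c("diffabund_table", class(rows))
  attr(rows, "criteria") <- criteria
  rows
}

#' Differential abundance for one compound
#'
#' Convenience wrapper running the full treated-vs-control test for one
#' compound of a count matrix: selects the compound's treated samples and
#' the control samples, drops barcodes with zero counts across all selected
#' samples (reported in the `dropped` attribute), computes size factors and
#' dispersions, runs the NB LRT, adjusts by BH and calls hits.
#'
#' @param x A `count_matrix`.
#' @param compound Compound name to test (must appear in the sample sheet
#'   with condition "treated").
#' @param criteria A [hit_criteria()].
#' @param control_condition Sample-sheet condition labelling the untreated
#'   controls (default "control").
#' @return A `diffabund_table` (see [call_hits()]) with `gene` column and
#'   attributes `dropped`, `size_factors`, `compound`.
#' @export
diffabund <- function(x, compound, criteria = hit_criteria(),
                      control_condition = "control") {
  stopifnot(inherits(x, "count_matrix"))
  meta <- x$sample_meta
  sel_t <- meta$condition == "treated" & meta$compound == compound
  sel_c <- meta$condition == control_condition
  if (sum(sel_t) < 2L || sum(sel_c) < 2L)
    stop("need >= 2 treated and >= 2 control samples for ", compound,
         call. = FALSE)
  sel <- sel_t | sel_c
  m <- x$counts[, sel, drop = FALSE]
  condition <- factor(ifelse(sel_t[sel], "treated", "control"),
                      levels = c("control", "treated"))
  dropped <- rownames(m)[rowSums(m) == 0]
  m <- m[rowSums(m) > 0, , drop = FALSE]
  sf <- compute_size_factors(m)
  alpha <- estimate_dispersions(m, sf, condition)
  res <- lrt_test(m, sf, alpha, condition)
  res$padj <- adjust_bh(res$p_value)
  res <- call_hits(res, criteria)
  attr(res, "dropped") <- dropped
  attr(res, "size_factors") <- sf
  attr(res, "compound") <- compound
  res
}

#' Shifted-log transform of normalized counts
#'
#' `log2(count / size_factor + 1)`, a variance-taming transform used before
#' PCA; zero counts map to zero.
#'
#' @param x A `count_matrix` or counts matrix.
#' @param size_factors Size factors.
#' @return Numeric matrix, same dimensions.
#' @export
shifted_log_transform <- function(x, size_factors) {
  m <- if (inherits(x, "count_matrix")) x$counts else x
  log2(sweep(m, 2L, size_factors, "/") + 1)
}

#' PCA of transformed barcode profiles
#'
#' Samples are observations and barcodes features; features are centered
#' (not scaled). Components are ordered by decreasing variance.
#'
#' @param transformed Matrix of transformed counts (barcodes x samples),
#'   e.g. from [shifted_log_transform()].
#' @return List with `scores` (samples x components) and `var_explained`
#'   (fraction of total variance per component).
#' @export
run_pca <- function(transformed) {
  if (ncol(transformed) < 2L)
    stop("PCA needs at least two samples", call. = FALSE)
  pc <- stats::prcomp(t(transformed), center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  ve <- if (tot > 0) pc$sdev^2 / tot else rep(0, length(pc$sdev))
  list(scores = pc$x, var_explained = ve)
}

#' Correlation between two compound response profiles
#'
#' Pearson correlation of per-barcode log2 fold changes between two
#' differential-abundance tables, restricted to a barcode subset (default:
#' the intersection of the two tables).
#'
#' @param a,b Data frames with `barcode_id` and `log2fc`.
#' @param barcode_subset Optional character vector restricting the barcodes.
#' @return List of class `profile_correlation` with `r`, `r_squared` and
#'   `n_shared`.
#' @export
profile_correlation <- function(a, b, barcode_subset = NULL) {
  shared <- intersect(a$barcode_id, b$barcode_id)
  if (!is.null(barcode_subset)) shared <- intersect(shared, barcode_subset)
  if (length(shared) < 2L)
    stop("need at least two shared barcodes", call. = FALSE)
  la <- a$log2fc[match(shared, a$barcode_id)]
  lb <- b$log2fc[match(shared, b$barcode_id)]
  r <- stats::cor(la, lb)
  structure(list(r = r, r_squared = r^2, n_shared = length(shared)),
            class = "profile_correlation")
}

#' @export
print.profile_correlation <- function(x, ...) {
  cat(sprintf("profile correlation: r = %.4f, r^2 = %.4f over %d shared barcodes\n",
              x$r, x$r_squared, x$n_shared))
  invisible(x)
}
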
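## Run `fun()` under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is restored afterwards, so generators are pure in (params, seed).
.with_seed <- function(seed, fun) {
  if (is.null(seed)) return(fun())
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  fun()
}

#' Pooled-screen simulation design
#'
#' Parameters of the serial-transfer competition the generator emulates:
#' an equal-start pool grown under compound for about 15 generations
#' (three growth phases of ~5 generations separated by 20x dilutions),
#' sequenced to a fixed per-sample depth with per-base substitution error.
#' The transfer schedule is retained as metadata; planted effects are
#' endpoint log2 proportion effects (see [simulate_competition()]).
#'
#' @param n_barcodes Number of pooled strains (default 500).
#' @param generations Total generations of competition (default 15).
#' @param transfer_generations Generations per growth phase (default
#'   c(5, 5, 5), i.e. two 20x dilutions).
#' @param dilution Fold dilution at each transfer (default 20).
#' @param read_depth Reads per sample (default 1e6).
#' @param error_rate Per-base substitution probability in reads (default
#'   0.005).
#' @param n_replicates Replicates per condition (default 4, as cultures were
#'   grown in quadruplicate).
#' @param overdispersion Dirichlet-multinomial overdispersion layer giving
#'   the counts an NB-like dispersion of about this alpha (default 0.05;
#'   0 disables it).
#' @param seed Integer seed from which all randomness flows.
#' @return A `sim_design` list.
#' @export
sim_design <- function(n_barcodes = 500L, generations = 15,
                       transfer_generations = c(5, 5, 5), dilution = 20,
                       read_depth = 1e6, error_rate = 0.005,
                       n_replicates = 4L, overdispersion = 0.05, seed = 1L) {
  stopifnot(n_barcodes >= 1, read_depth >= 1, n_replicates >= 1,
            error_rate >= 0, error_rate < 1, overdispersion >= 0)
  structure(list(n_barcodes = as.integer(n_barcodes),
                 generations = generations,
                 transfer_generations = transfer_generations,
                 dilution = dilution,
                 read_depth = as.integer(read_depth),
                 error_rate = error_rate,
                 n_replicates = as.integer(n_replicates),
                 overdispersion = overdispersion,
                 seed = as.integer(seed)),
            class = "sim_design")
}

#' Generate a synthetic barcode reference
#'
#' Random ACGT barcodes with a guaranteed minimum pairwise Levenshtein
#' distance (so that single sequencing errors can never cross barcodes) and
#' distance > 4 from both flanks.
#'
#' @param n Number of barcodes.
#' @param length Barcode length in nt (default 20).
#' @param min_pairwise_distance Minimum Levenshtein distance between any two
#'   barcodes (default 5).
#' @param seed Integer seed (NULL = use the current RNG stream).
#' @param upstream_flank,downstream_flank Flank sequences (defaults: the
#'   deletion-collection U1/U2 priming sites).
#' @return A [barcode_reference()] with strain ids `strain_001`, ... and
#'   synthetic systematic gene names.
#' @export
generate_reference <- function(n, length = 20L, min_pairwise_distance = 5L,
                               seed = NULL,
                               upstream_flank = UPTAG_UPSTREAM_FLANK,
                               downstream_flank = UPTAG_DOWNSTREAM_FLANK) {
  stopifnot(n >= 1)
  .with_seed(seed, function() {
    accepted <- character(0)
    flanks <- toupper(c(upstream_flank, downstream_flank))
    attempts <- 0L
    max_attempts <- 2000L + 500L * n
    while (length(accepted) < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("could not place ", n, " barcodes at pairwise distance >= ",
             min_pairwise_distance, " after ", max_attempts, " attempts",
             call. = FALSE)
      cand <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                    collapse = "")
      if (any(utils::adist(cand, flanks) <= 4L)) next
      if (length(accepted) > 0L &&
          min(utils::adist(cand, accepted)) < min_pairwise_distance) next
      accepted <- c(accepted, cand)
    }
    ids <- sprintf("strain_%03d", seq_len(n))
    genes <- sprintf("YSY%03d%s", seq_len(n),
                     rep(c("W", "C"), length.out = n))
    barcode_reference(ids, genes, accepted,
                      upstream_flank = upstream_flank,
                      downstream_flank = downstream_flank)
  })
}

#' Expected pool proportions under planted fitness effects
#'
#' Formalizes the competition endpoint: the control pool stays uniform
#' (equal-start, no selection), while in the treated pool each strain's
#' proportion is tilted by its planted log2 effect delta and renormalized:
#' `p_i = 2^delta_i / sum_k 2^delta_k`. The realized expected log2 fold
#' change, `delta_i - log2(mean(2^delta))`, differs from delta by the
#' renormalization constant and is recorded as the recoverable truth.
#'
#' @param reference A `barcode_reference`.
#' @param delta Numeric vector of planted log2 proportion effects, one per
#'   barcode (0 = neutral).
#' @return List with `control_prop`, `treated_prop` (named, summing to 1)
#'   and `truth` (data frame `barcode_id`, `delta`, `expected_log2fc`).
#' @export
simulate_competition <- function(reference, delta) {
  ids <- reference$records$strain_id
  n <- length(ids)
  if (length(delta) == 1L) delta <- rep(delta, n)
  stopifnot(length(delta) == n, all(is.finite(delta)))
  control <- rep(1 / n, n)
  w <- 2^delta
  treated <- w / sum(w)
  names(control) <- names(treated) <- ids
  truth <- data.frame(barcode_id = ids, delta = delta,
                      expected_log2fc = delta - log2(mean(w)),
                      stringsAsFactors = FALSE)
  list(control_prop = control, treated_prop = treated, truth = truth)
}

## One replicate's read-count vector: multinomial at `depth`, with an
## optional gamma (Dirichlet-like) overdispersion layer targeting NB alpha.
.sample_replicate_counts <- function(prop, depth, overdispersion) {
  w <- prop
  if (overdispersion > 0) {
    g <- stats::rgamma(length(prop), shape = 1 / overdispersion,
                       rate = 1 / overdispersion)
    w <- prop * g
    w <- w / sum(w)
  }
  as.integer(stats::rmultinom(1L, size = depth, prob = w))
}

#' Simulate barcode counts for a treated-vs-control screen
#'
#' Counts-level generator (no reads): independent replicate count vectors
#' for the control and treated pools of [simulate_competition()], each an
#' (optionally overdispersed) multinomial draw at the design depth.
#'
#' @param reference A `barcode_reference`.
#' @param delta Planted log2 effects (see [simulate_competition()]).
#' @param design A [sim_design()]; `read_depth`, `n_replicates`,
#'   `overdispersion` and `seed` are used.
#' @param compound Compound label written into the sample sheet
#'   (default "drugX").
#' @return List with `matrix` (a `count_matrix` with control + treated
#'   samples) and `truth` (the competition truth table).
#' @export
simulate_screen_counts <- function(reference, delta, design,
                                   compound = "drugX") {
  comp <- simulate_competition(reference, delta)
  .with_seed(design$seed, function() {
    n_rep <- design$n_replicates
    ids <- reference$records$strain_id
    cols <- list()
    meta <- list()
    for (r in seq_len(n_rep)) {
      cols[[sprintf("ctrl_%d", r)]] <-
        .sample_replicate_counts(comp$control_prop, design$read_depth,
                                 design$overdispersion)
      meta[[length(meta) + 1L]] <- data.frame(
        sample_id = sprintf("ctrl_%d", r), compound = "DMSO",
        condition = "control", replicate = r, stringsAsFactors = FALSE)
    }
    for (r in seq_len(n_rep)) {
      cols[[sprintf("trt_%d", r)]] <-
        .sample_replicate_counts(comp$treated_prop, design$read_depth,
                                 design$overdispersion)
      meta[[length(meta) + 1L]] <- data.frame(
        sample_id = sprintf("trt_%d", r), compound = compound,
        condition = "treated", replicate = r, stringsAsFactors = FALSE)
    }
    m <- do.call(cbind, cols)
    rownames(m) <- ids
    list(matrix = count_matrix(m, do.call(rbind, meta)), truth = comp$truth)
  })
}

## Introduce i.i.d. per-base substitutions at rate `rate` into `seqs`.
.mutate_seqs <- function(seqs, rate) {
  if (rate == 0 || length(seqs) == 0L) return(seqs)
  bases <- c("A", "C", "G", "T")
  L <- nchar(seqs)
  k <- stats::rbinom(length(seqs), L, rate)
  for (i in which(k > 0L)) {
    pos <- sample.int(L[i], k[i])
    s <- strsplit(seqs[i], "")[[1L]]
    for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' Emit a FASTQ sample from pool proportions
#'
#' Draws a read-count vector (multinomial at the design depth, with the
#' design's overdispersion layer), builds each read as
#' `upstream_flank + barcode + downstream_flank` with i.i.d. per-base
#' substitutions at the design error rate, shuffles read order and writes a
#' FASTQ file with constant quality. The pre-error truth counts are
#' returned.
#'
#' @param proportions Named vector of pool proportions (must sum to 1).
#' @param reference A `barcode_reference`.
#' @param design A [sim_design()].
#' @param path Output FASTQ path.
#' @param seed Integer seed (NULL = current RNG stream).
#' @return Invisibly, a list with `path` and `truth_counts` (named integer
#'   vector summing to the design read depth).
#' @export
emit_reads <- function(proportions, reference, design, path, seed = NULL) {
  stopifnot(abs(sum(proportions) - 1) < 1e-8)
  ids <- reference$records$strain_id
  stopifnot(identical(sort(names(proportions)), sort(ids)))
  .with_seed(seed, function() {
    counts <- .sample_replicate_counts(proportions[ids], design$read_depth,
                                       design$overdispersion)
    names(counts) <- ids
    full <- paste0(reference$upstream_flank, reference$records$uptag,
                   reference$downstream_flank)
    reads <- rep(full, counts)
    reads <- .mutate_seqs(reads, design$error_rate)
    reads <- reads[sample.int(length(reads))]
    dss <- Biostrings::DNAStringSet(reads)
    names(dss) <- sprintf("read_%07d", seq_along(reads))
    quals <- Biostrings::BStringSet(strrep("I", nchar(reads)))
    Biostrings::writeXStringSet(dss, path, format = "fastq",
                                qualities = quals)
    invisible(list(path = path, truth_counts = counts))
  })
}

#' Simulate a full screen to FASTQ files
#'
#' Generates (or takes) a barcode reference, computes competition
#' proportions from planted effects and writes one FASTQ per replicate and
#' condition plus the reference TSV, sample sheet TSV and truth table TSV.
#'
#' @param design A [sim_design()].
#' @param delta Planted log2 effects, length `n_barcodes` (or scalar 0).
#' @param dir Output directory (created if needed).
#' @param reference Optional pre-built reference; by default generated from
#'   the design seed.
#' @param compound Compound label (default "drugX").
#' @return List with `reference`, `truth`, `sample_sheet`, `fastq` (named
#'   paths) and `truth_counts` (barcode x sample matrix of pre-error
#'   counts).
#' @export
simulate_screen <- function(design, delta = 0, dir, reference = NULL,
                            compound = "drugX") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(reference))
    reference <- generate_reference(design$n_barcodes, seed = design$seed)
  comp <- simulate_competition(reference, delta)
  n_rep <- design$n_replicates
  samples <- data.frame(
    sample_id = c(sprintf("ctrl_%d", seq_len(n_rep)),
                  sprintf("trt_%d", seq_len(n_rep))),
    compound = rep(c("DMSO", compound), each = n_rep),
    condition = rep(c("control", "treated"), each = n_rep),
    replicate = rep(seq_len(n_rep), 2L), stringsAsFactors = FALSE)
  fastq <- file.path(dir, paste0(samples$sample_id, ".fastq"))
  names(fastq) <- samples$sample_id
  truth_counts <- matrix(0L, nrow = design$n_barcodes, ncol = nrow(samples),
                         dimnames = list(reference$records$strain_id,
                                         samples$sample_id))
  .with_seed(design$seed, function() {
    for (j in seq_len(nrow(samples))) {
      prop <- if (samples$condition[j] == "control") comp$control_prop
      else comp$treated_prop
      res <- emit_reads(prop, reference, design, fastq[j], seed = NULL)
      truth_counts[, j] <<- res$truth_counts
    }
  })
  write_barcode_reference(reference, file.path(dir, "reference.tsv"))
  utils::write.table(samples, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(comp$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(reference = reference, truth = comp$truth, sample_sheet = samples,
       fastq = fastq, truth_counts = truth_counts)
}

#' Simulate a dose-inhibited growth curve
#'
#' A logistic OD trajectory sampled every `interval` minutes over
#' `duration` minutes, inhibited by a planted 4PL dose-response acting on
#' the growth-score scale: the relative score at dose d is
#' `rel(d) = f(d)/f(0)` for the planted 4PL f, and because the growth score
#' scales quadratically with OD amplitude the curve's amplitude is scaled by
#' `sqrt(rel(d))`. At dose 0 the curve reaches the stated carrying capacity;
#' at saturating dose the score plateaus near the 4PL bottom.
#'
#' @param dose Compound concentration (same units as `params$ec50`).
#' @param params Planted 4PL: list with `bottom`, `top`, `ec50`, `hill`.
#' @param od0 Inoculation OD (default 0.1).
#' @param capacity Carrying-capacity OD at dose 0 (default 1.2).
#' @param rate Logistic growth rate per minute (default 0.008).
#' @param interval Sampling interval in minutes (default 10).
#' @param duration Total time in minutes (default 1800, i.e. 30 h).
#' @param noise_sd Gaussian measurement noise SD in OD units (default
#'   0.005).
#' @param seed Integer seed (NULL = current RNG stream).
#' @return A [growth_curve()] with attribute `truth`: list with `rel`
#'   (planted relative score) and `generative_ic` function of the
#'   inhibition fraction.
#' @export
simulate_growth_curve <- function(dose,
                                  params = list(bottom = 0, top = 1,
                                                ec50 = 10, hill = 1),
                                  od0 = 0.1, capacity = 1.2, rate = 0.008,
                                  interval = 10, duration = 1800,
                                  noise_sd = 0.005, seed = NULL) {
  stopifnot(noise_sd >= 0, dose >= 0)
  f <- function(x) .four_pl(x, params$bottom, params$top, params$ec50,
                            params$hill)
  rel <- f(dose) / f(0)
  rel <- max(rel, 0)
  tt <- seq(0, duration, by = interval)
  logistic <- capacity / (1 + ((capacity - od0) / od0) * exp(-rate * tt))
  .with_seed(seed, function() {
    od <- od0 + sqrt(rel) * (logistic - od0)
    if (noise_sd > 0) od <- od + stats::rnorm(length(od), 0, noise_sd)
    od <- pmax(od, 0)
    cu <- growth_curve(tt, od)
    attr(cu, "truth") <- list(
      rel = rel,
      generative_ic = function(fraction)
        params$ec50 * (fraction / (1 - fraction))^(1 / params$hill))
    cu
  })
}

#' Simulate a colony-array plate image
#'
#' Renders the 32x48 quadruplicate spot grid of a validation layout into a
#' grayscale image: each spot is a `block x block` pixel patch at its
#' planted mean intensity plus Gaussian pixel noise, clipped to 0-255.
#' Baseline strain intensities vary uniformly (bounded colony-pinning
#' variation) with the stated SD; planted resistant strains sit
#' `effect_sd` between-strain SDs above baseline; corner voids render at
#' background level.
#'
#' @param layout A [build_validation_layout()] result.
#' @param resistant_strains Character vector (subset of the layout strains)
#'   planted as resistant.
#' @param baseline Baseline mean spot intensity (default 100).
#' @param strain_sd Between-strain SD of baseline intensity (default 5).
#' @param effect_sd Resistance effect in units of `strain_sd` (default 8).
#' @param void_level Background intensity of voids (default 20).
#' @param spot_jitter_sd Within-quadruplicate spot-to-spot SD (default 1).
#' @param noise_sd Pixel noise SD (default 2).
#' @param block Pixels per spot side (default 12; image is 384 x 576).
#' @param seed Integer seed.
#' @return List with `image` (matrix, 0-255), `role_map` (from
#'   [expand_quadruplicate()]) and `truth` (data frame `strain_id`,
#'   `planted_mean`, `resistant`).
#' @export
simulate_plate_image <- function(layout, resistant_strains = character(0),
                                 baseline = 100, strain_sd = 5,
                                 effect_sd = 8, void_level = 20,
                                 spot_jitter_sd = 1, noise_sd = 2,
                                 block = 12L, seed = 1L) {
  stopifnot(all(resistant_strains %in% layout$strain_id))
  rm_ <- expand_quadruplicate(layout)
  .with_seed(seed, function() {
    half_range <- strain_sd * sqrt(3)  # uniform with SD = strain_sd
    pos_mean <- numeric(nrow(layout))
    for (i in seq_len(nrow(layout))) {
      pos_mean[i] <- switch(layout$role[i],
        void = , void_extra = void_level,
        wildtype = baseline + stats::runif(1, -half_range, half_range),
        strain = if (layout$strain_id[i] %in% resistant_strains)
          baseline + effect_sd * strain_sd
        else baseline + stats::runif(1, -half_range, half_range))
    }
    key <- paste(layout$row, layout$col)
    spot_mean <- pos_mean[match(paste(rm_$row, rm_$col), key)] +
      stats::rnorm(nrow(rm_), 0, spot_jitter_sd)
    img <- matrix(0, 32L * block, 48L * block)
    for (k in seq_len(nrow(rm_))) {
      rs <- ((rm_$spot_row[k] - 1L) * block + 1L):(rm_$spot_row[k] * block)
      cs <- ((rm_$spot_col[k] - 1L) * block + 1L):(rm_$spot_col[k] * block)
      img[rs, cs] <- spot_mean[k]
    }
    if (noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, noise_sd)
    img <- pmin(pmax(img, 0), 255)
    is_strain <- layout$role == "strain"
    truth <- data.frame(strain_id = layout$strain_id[is_strain],
                        planted_mean = pos_mean[is_strain],
                        resistant = layout$strain_id[is_strain] %in%
                          resistant_strains,
                        stringsAsFactors = FALSE)
    list(image = img, role_map = rm_, truth = truth)
  })
}
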
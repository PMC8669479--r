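#' Barcode assignment configuration
#'
#' Controls how reads are matched to reference uptags: the maximum
#' Levenshtein edit distance at which a variant sequence is still rescued
#' onto its barcode, and how many substitutions are tolerated when locating
#' the constant flanks in a read.
#'
#' @param max_distance Maximum Levenshtein distance for barcode rescue
#'   (default 2: variants at distance 1-2 from a unique nearest uptag are
#'   counted as that barcode).
#' @param allowed_flank_mismatches Substitutions tolerated in each
#'   full-length flank match (default 1).
#' @param min_flank_match Minimum matched flank length. Flank matching is
#'   full-length; the field is retained for forward compatibility and must
#'   equal the flank length or `NA`.
#' @return An `assign_config` list.
#' @export
assign_config <- function(max_distance = 2L, allowed_flank_mismatches = 1L,
                          min_flank_match = NA_integer_) {
  max_distance <- as.integer(max_distance)
  if (is.na(max_distance) || max_distance < 0L)
    stop("max_distance must be a non-negative integer", call. = FALSE)
  allowed_flank_mismatches <- as.integer(allowed_flank_mismatches)
  if (is.na(allowed_flank_mismatches) || allowed_flank_mismatches < 0L)
    stop("allowed_flank_mismatches must be a non-negative integer", call. = FALSE)
  structure(list(max_distance = max_distance,
                 allowed_flank_mismatches = allowed_flank_mismatches,
                 min_flank_match = min_flank_match),
            class = "assign_config")
}

## Minimum-mismatch full-length occurrence of `pattern` in `subject`
## (substitutions only). Returns list(start, mismatches) or NULL; ties go
## to the leftmost position. `from` restricts the search start.
.best_flank_match <- function(subject_raw, pattern_raw, from = 1L) {
  np <- length(pattern_raw)
  ns <- length(subject_raw)
  last <- ns - np + 1L
  if (last < from) return(NULL)
  best_start <- NA_integer_
  best_mm <- Inf
  for (s in from:last) {
    mm <- sum(subject_raw[s:(s + np - 1L)] != pattern_raw)
    if (mm < best_mm) {
      best_mm <- mm
      best_start <- s
      if (mm == 0L) break
    }
  }
  list(start = best_start, mismatches = best_mm)
}

#' Extract the barcode region from a read
#'
#' Locates the upstream and downstream constant flanks in a read (full-length
#' match, up to `allowed_flank_mismatches` substitutions each, leftmost best
#' match; the downstream flank is searched only after the upstream one) and
#' returns the sequence between them. Reads in which either flank cannot be
#' located are discarded by the caller and tallied as `no_flank`.
#'
#' @param read A single read sequence (character scalar).
#' @param reference A `barcode_reference` (supplies the flanks).
#' @param config An `assign_config`.
#' @return The barcode substring (possibly empty), or `NA_character_` when a
#'   flank is not found.
#' @export
extract_barcode <- function(read, reference, config = assign_config()) {
  stopifnot(length(read) == 1L, nzchar(read))
  read <- toupper(read)
  sr <- charToRaw(read)
  up <- charToRaw(reference$upstream_flank)
  down <- charToRaw(reference$downstream_flank)
  hit_up <- .best_flank_match(sr, up)
  if (is.null(hit_up) || hit_up$mismatches > config$allowed_flank_mismatches)
    return(NA_character_)
  after_up <- hit_up$start + length(up)
  hit_down <- .best_flank_match(sr, down, from = after_up)
  if (is.null(hit_down) || hit_down$mismatches > config$allowed_flank_mismatches)
    return(NA_character_)
  if (hit_down$start == after_up) return("")
  substr(read, after_up, hit_down$start - 1L)
}

#' Dereplicate sequences
#'
#' Collapses a character vector of sequences to unique sequences with counts.
#'
#' @param sequences Character vector.
#' @return Named integer vector: unique sequence -> count. Counts sum to
#'   `length(sequences)`.
#' @export
dereplicate <- function(sequences) {
  if (length(sequences) == 0L) return(integer(0))
  tab <- table(sequences)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts
}

#' Assign a sequence to its nearest reference barcode
#'
#' Computes the Levenshtein distance from `seq` to every reference uptag and
#' applies the rescue rule: distance 0 is `exact`; a unique minimizer at
#' distance 1..`max_distance` is `corrected`; two or more uptags at the
#' minimal distance (<= `max_distance`) is `ambiguous`; a minimal distance
#' above `max_distance` is `unassigned`. Ties are never broken by reference
#' order. Non-ACGT characters participate in the distance as ordinary
#' mismatching symbols.
#'
#' @param seq Sequence to assign (character scalar, non-empty).
#' @param reference A `barcode_reference`.
#' @param config An `assign_config`.
#' @return A list of class `barcode_assignment` with fields `query`,
#'   `status` (one of exact/corrected/ambiguous/unassigned), `barcode_id`
#'   (strain id or `NA`), `distance` (`NA` when unassigned).
#' @export
assign_barcode <- function(seq, reference, config = assign_config()) {
  stopifnot(length(seq) == 1L, nzchar(seq))
  seq <- toupper(seq)
  d <- utils::adist(seq, reference$records$uptag)[1L, ]
  dmin <- min(d)
  hits <- which(d == dmin)
  if (dmin > config$max_distance) {
    status <- "unassigned"; id <- NA_character_; dist <- NA_integer_
  } else if (length(hits) > 1L) {
    status <- "ambiguous"; id <- NA_character_; dist <- as.integer(dmin)
  } else if (dmin == 0L) {
    status <- "exact"; id <- reference$records$strain_id[hits]; dist <- 0L
  } else {
    status <- "corrected"; id <- reference$records$strain_id[hits]
    dist <- as.integer(dmin)
  }
  structure(list(query = seq, status = status, barcode_id = id,
                 distance = dist),
            class = "barcode_assignment")
}

#' Count barcodes in one FASTQ sample
#'
#' Reads a FASTQ file, extracts the barcode region of every read, exactly
#' dereplicates the extracted sequences, assigns each unique sequence with
#' [assign_barcode()], and sums the dereplicated counts of all sequences
#' assigned (exactly or after correction) to the same barcode. Reads lacking
#' a flank, and reads whose barcode is ambiguous or unassignable, are
#' excluded from the counts but tallied, so the assignment statistics always
#' sum to the number of reads.
#'
#' @param fastq Path to a FASTQ file (optionally gzip-compressed).
#' @param reference A `barcode_reference`.
#' @param config An `assign_config`.
#' @return A list with `counts` (named integer vector over all reference
#'   strain ids, zeros included) and `stats` (integer vector with elements
#'   `exact`, `corrected`, `ambiguous`, `unassigned`, `no_flank`, `total`).
#' @export
count_sample <- function(fastq, reference, config = assign_config()) {
  reads <- tryCatch(
    as.character(Biostrings::readDNAStringSet(fastq, format = "fastq")),
    error = function(e)
      stop("malformed FASTQ '", fastq, "': ", conditionMessage(e),
           call. = FALSE))
  n_total <- length(reads)
  counts <- integer(nrow(reference$records))
  names(counts) <- reference$records$strain_id
  stats <- c(exact = 0L, corrected = 0L, ambiguous = 0L, unassigned = 0L,
             no_flank = 0L, total = n_total)
  if (n_total == 0L) return(list(counts = counts, stats = stats))

  ## flank extraction per unique read sequence (one scan per variant)
  derep_reads <- dereplicate(reads)
  extracted <- vapply(names(derep_reads), extract_barcode, "",
                      reference = reference, config = config)
  no_flank <- is.na(extracted) | !nzchar(extracted)
  stats[["no_flank"]] <- sum(derep_reads[no_flank])

  bc_counts <- derep_reads[!no_flank]
  if (length(bc_counts) > 0L) {
    derep_bc <- vapply(split(bc_counts, extracted[!no_flank]), sum, 0L)
    for (i in seq_along(derep_bc)) {
      a <- assign_barcode(names(derep_bc)[i], reference, config)
      stats[[a$status]] <- stats[[a$status]] + derep_bc[[i]]
      if (a$status %in% c("exact", "corrected"))
        counts[[a$barcode_id]] <- counts[[a$barcode_id]] + derep_bc[[i]]
    }
  }
  stopifnot(sum(stats[c("exact", "corrected", "ambiguous", "unassigned",
                        "no_flank")]) == n_total)
  list(counts = counts, stats = stats)
}

#' Assemble per-sample counts into a count matrix
#'
#' @param per_sample_counts Named list (sample id -> named count vector as
#'   produced by `count_sample()$counts`).
#' @param sample_meta Data frame with columns `sample_id`, `compound`,
#'   `condition` ("treated" or "control") and `replicate`. Column order of
#'   the matrix follows this sheet.
#' @param reference Optional `barcode_reference` fixing the row set; by
#'   default the union of barcode ids seen across samples. Barcodes absent
#'   from a sample get count 0.
#' @return A `count_matrix`: list with integer `counts`
#'   (barcode x sample) and the `sample_meta` data frame.
#' @export
build_count_matrix <- function(per_sample_counts, sample_meta,
                               reference = NULL) {
  if (length(per_sample_counts) == 0L)
    stop("no samples provided", call. = FALSE)
  needed <- c("sample_id", "compound", "condition", "replicate")
  missing <- setdiff(needed, names(sample_meta))
  if (length(missing) > 0L)
    stop("sample sheet is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  absent <- setdiff(names(per_sample_counts), sample_meta$sample_id)
  if (length(absent) > 0L)
    stop("sample(s) missing from the sample sheet: ",
         paste(absent, collapse = ", "), call. = FALSE)
  sample_meta <- sample_meta[sample_meta$sample_id %in%
                               names(per_sample_counts), , drop = FALSE]
  barcodes <- if (is.null(reference)) {
    sort(unique(unlist(lapply(per_sample_counts, names))))
  } else reference$records$strain_id
  m <- matrix(0L, nrow = length(barcodes), ncol = nrow(sample_meta),
              dimnames = list(barcodes, sample_meta$sample_id))
  for (s in sample_meta$sample_id) {
    v <- per_sample_counts[[s]]
    keep <- intersect(names(v), barcodes)
    m[keep, s] <- as.integer(v[keep])
  }
  count_matrix(m, sample_meta)
}

#' Count-matrix container
#'
#' @param counts Non-negative integer matrix, barcodes in rows (rownames),
#'   samples in columns (colnames).
#' @param sample_meta Data frame describing the columns (see
#'   [build_count_matrix()]).
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, sample_meta) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (!identical(colnames(counts), as.character(sample_meta$sample_id)))
    stop("sample_meta rows must match count columns in order", call. = FALSE)
  structure(list(counts = counts, sample_meta = sample_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d barcodes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$sample_meta$compound), collapse = ", ")))
  invisible(x)
}

#' Write / read a count matrix as TSV
#'
#' The matrix TSV has barcodes in rows (first column `barcode_id`) and
#' samples in columns; the sample sheet travels in a separate TSV.
#'
#' @param x A `count_matrix`.
#' @param counts_path,samples_path Output paths.
#' @return Invisibly, `counts_path`.
#' @export
write_count_matrix <- function(x, counts_path, samples_path) {
  stopifnot(inherits(x, "count_matrix"))
  tab <- data.frame(barcode_id = rownames(x$counts), x$counts,
                    check.names = FALSE)
  utils::write.table(tab, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$sample_meta, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(counts_path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(counts_path, samples_path) {
  tab <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  meta <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- tab$barcode_id
  meta <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
  count_matrix(m, meta)
}
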
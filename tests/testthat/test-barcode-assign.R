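test_that("barcode reference parsing validates, normalizes and round-trips", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("strain_id\tgene\tuptag",
               "sA\tYAL001C\tACGTACGTACGTACGTACGT",
               "sB\tYBL002W\tttttccccggggaaaatttt"), tsv)
  ref <- parse_barcode_reference(tsv)
  expect_equal(nrow(ref$records), 2L)
  # lowercase input stored uppercased, and stable under write/read
  expect_equal(ref$records$uptag[2], "TTTTCCCCGGGGAAAATTTT")
  out <- tempfile(fileext = ".tsv")
  write_barcode_reference(ref, out)
  expect_identical(parse_barcode_reference(out)$records, ref$records)

  # duplicate uptags rejected, naming the offending strains
  writeLines(c("strain_id\tgene\tuptag",
               "sA\tYAL001C\tACGTACGTACGTACGTACGT",
               "sB\tYBL002W\tACGTACGTACGTACGTACGT"), tsv)
  expect_error(parse_barcode_reference(tsv), "sA.*sB")

  writeLines("strain_id\tgene\tuptag", tsv)
  expect_error(parse_barcode_reference(tsv), "empty")
  writeLines(c("strain_id\tuptag", "sA\tACGT"), tsv)
  expect_error(parse_barcode_reference(tsv), "missing column")
})

test_that("extract_barcode locates flanks with bounded mismatches", {
  ref <- tiny_reference()
  b <- ref$records$uptag[1]
  read <- paste0(ref$upstream_flank, b, ref$downstream_flank)
  expect_identical(extract_barcode(read, ref), b)

  # no downstream flank at all
  expect_identical(extract_barcode(paste0(ref$upstream_flank, b), ref),
                   NA_character_)

  # one substitution inside the upstream flank still matches at <= 1
  # mismatch; position verified against a brute-force Hamming scan
  bad_up <- mutate_one_base(ref$upstream_flank, 7L, "A")  # C -> A
  read2 <- paste0("GG", bad_up, b, ref$downstream_flank, "TT")
  oracle <- hamming_scan_oracle(read2, ref$upstream_flank)
  expect_equal(oracle$mismatches, 1L)
  expect_identical(extract_barcode(read2, ref), b)
  # but not at 2 mismatches under the default config
  worse <- mutate_one_base(bad_up, 9L, "G")
  read3 <- paste0(worse, b, ref$downstream_flank)
  expect_identical(extract_barcode(read3, ref), NA_character_)
})

test_that("dereplication counts unique sequences and conserves totals", {
  expect_identical(dereplicate(c("AA", "AA", "AT")), c(AA = 2L, AT = 1L))
  expect_identical(dereplicate(character(0)), integer(0))
  many <- rep("ACGT", 1000)
  d <- dereplicate(many)
  expect_identical(d, c(ACGT = 1000L))
  x <- c("A", "B", "A", "C", "C", "C")
  expect_equal(sum(dereplicate(x)), length(x))
})

test_that("assign_barcode applies the distance-rescue rule", {
  ref <- tiny_reference()
  a <- assign_barcode(ref$records$uptag[2], ref)
  expect_identical(a$status, "exact")
  expect_identical(a$barcode_id, "sB")
  expect_identical(a$distance, 0L)

  # one substitution from sA, far from the others -> corrected at d = 1
  q <- mutate_one_base(ref$records$uptag[1], 3L, "T")
  a <- assign_barcode(q, ref)
  expect_identical(a$status, "corrected")
  expect_identical(a$barcode_id, "sA")
  expect_identical(a$distance, 1L)

  # three substitutions -> beyond max_distance 2 -> unassigned
  q3 <- mutate_one_base(mutate_one_base(q, 6L, "A"), 9L, "C")
  expect_true(min(utils::adist(q3, ref$records$uptag)) > 2)
  a <- assign_barcode(q3, ref)
  expect_identical(a$status, "unassigned")
  expect_true(is.na(a$barcode_id))
  expect_true(is.na(a$distance))
})

test_that("ties resolve to ambiguous, independent of reference order", {
  # two uptags at equal distance 1 from the query
  ref <- barcode_reference(c("s1", "s2"), c("YA", "YB"),
                           c("AAAAAAAAAACCCCCCCCCC",
                             "AAAAAAAAAACCCCCCCCCG"))
  q <- "AAAAAAAAAACCCCCCCCCT"  # distance 1 from both
  a <- assign_barcode(q, ref)
  expect_identical(a$status, "ambiguous")
  expect_true(is.na(a$barcode_id))
  rev_ref <- barcode_reference(c("s2", "s1"), c("YB", "YA"),
                               c("AAAAAAAAAACCCCCCCCCG",
                                 "AAAAAAAAAACCCCCCCCCC"))
  b <- assign_barcode(q, rev_ref)
  expect_identical(b$status, a$status)
  expect_identical(b$distance, a$distance)
})

test_that("assignment distance matches the DP Levenshtein oracle", {
  ref <- generate_reference(25, seed = 91)
  set.seed(92)
  bases <- c("A", "C", "G", "T")
  for (k in 1:40) {
    q <- paste(sample(bases, sample(15:25, 1), replace = TRUE),
               collapse = "")
    d_oracle <- min(vapply(ref$records$uptag, lev_oracle, 0L, a = q))
    a <- assign_barcode(q, ref, assign_config(max_distance = 100L))
    expect_identical(as.integer(a$distance), as.integer(d_oracle))
  }
})

test_that("count_sample counts, merges variants and conserves reads", {
  ref <- tiny_reference()
  mk <- function(b) paste0(ref$upstream_flank, b, ref$downstream_flank)
  A <- ref$records$uptag[1]; B <- ref$records$uptag[2]
  Avar1 <- mutate_one_base(A, 2L, "A")   # C -> A, distance 1 from A
  Avar2 <- mutate_one_base(A, 11L, "A")  # G -> A, distance 1 from A
  reads <- c(rep(mk(A), 10), rep(mk(B), 5),
             rep(mk(Avar1), 5), rep(mk(Avar2), 3),   # rescued variants of A
             rep(substr(mk(A), 1, 25), 2),           # flank lost
             rep(mk("GGGGGGGGGGGGGGGGGGGG"), 4))     # unassignable
  fq <- write_fastq(reads, tempfile(fileext = ".fastq"))
  res <- count_sample(fq, ref)
  expect_equal(unname(res$counts[c("sA", "sB", "sC")]), c(18L, 5L, 0L))
  expect_equal(unname(res$stats[["exact"]]), 15L)
  expect_equal(unname(res$stats[["corrected"]]), 8L)
  expect_equal(unname(res$stats[["no_flank"]]), 2L)
  expect_equal(unname(res$stats[["unassigned"]]), 4L)
  expect_equal(sum(res$stats[c("exact", "corrected", "ambiguous",
                               "unassigned", "no_flank")]),
               unname(res$stats[["total"]]))
})

test_that("count_sample reports malformed FASTQ", {
  bad <- tempfile(fileext = ".fastq")
  writeLines(c("read_1", "ACGT", "+", "IIII"), bad)  # header lost its "@"
  expect_error(count_sample(bad, tiny_reference()), "malformed FASTQ")
})

test_that("error-free simulated reads are recovered exactly", {
  design <- sim_design(n_barcodes = 15, read_depth = 1500, error_rate = 0,
                       n_replicates = 1, overdispersion = 0, seed = 21)
  ref <- generate_reference(15, seed = 22)
  comp <- simulate_competition(ref, 0)
  fq <- tempfile(fileext = ".fastq")
  truth <- emit_reads(comp$control_prop, ref, design, fq, seed = 23)
  res <- count_sample(fq, ref)
  expect_identical(unname(res$counts[names(truth$truth_counts)]),
                   unname(truth$truth_counts))
  expect_equal(unname(res$stats[["corrected"]]), 0L)
  expect_equal(unname(res$stats[["ambiguous"]]), 0L)
})

test_that("build_count_matrix fills zeros and validates the sheet", {
  meta <- data.frame(sample_id = c("s1", "s2"), compound = "X",
                     condition = c("control", "treated"), replicate = 1L)
  cm <- build_count_matrix(list(s1 = c(a = 3L), s2 = c(b = 5L)), meta)
  expect_equal(dim(cm$counts), c(2L, 2L))
  expect_equal(cm$counts["a", "s2"], 0L)
  expect_equal(cm$counts["b", "s1"], 0L)
  expect_error(build_count_matrix(list(), meta), "no samples")
  expect_error(build_count_matrix(list(s3 = c(a = 1L)), meta),
               "missing from the sample sheet")
})

test_that("matrix columns from the simulator sum to the sequencing depth", {
  design <- sim_design(n_barcodes = 10, read_depth = 800, error_rate = 0,
                       n_replicates = 4, overdispersion = 0, seed = 31)
  sim <- simulate_screen(design, delta = 0, dir = tempfile("sim"))
  per_sample <- lapply(sim$fastq, function(f)
    count_sample(f, sim$reference)$counts)
  cm <- build_count_matrix(per_sample, sim$sample_sheet,
                           reference = sim$reference)
  expect_equal(ncol(cm$counts), 8L)
  expect_true(all(colSums(cm$counts) == design$read_depth))
})
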
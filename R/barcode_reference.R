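#' Default uptag priming sequences
#'
#' Constant regions flanking the 20-nt uptag barcode in the yeast deletion
#' collection (the U1/U2 priming sites used to amplify upstream barcodes).
#' Reads are expected to contain `upstream_flank + uptag + downstream_flank`.
#'
#' @format Character scalars, 18 nt each.
#' @export
UPTAG_UPSTREAM_FLANK <- "GATGTCCACGAGGTCTCT"

#' @rdname UPTAG_UPSTREAM_FLANK
#' @export
UPTAG_DOWNSTREAM_FLANK <- "CGTACGCTGCAGGTCGAC"

#' Construct a barcode reference
#'
#' A barcode reference maps deletion strains to their unique 20-nt uptag
#' barcodes, together with the constant priming regions that flank the
#' barcode in each sequencing read.
#'
#' @param strain_id Character vector of unique strain identifiers.
#' @param gene Character vector of systematic gene names (e.g. "YER056C").
#' @param uptag Character vector of barcode sequences (alphabet ACGT;
#'   canonically 20 nt). Stored uppercased.
#' @param upstream_flank,downstream_flank Constant priming sequences
#'   surrounding the barcode. Defaults are the deletion-collection U1/U2
#'   sites.
#' @return An object of class `barcode_reference`: a list with a `records`
#'   data frame (`strain_id`, `gene`, `uptag`) and the two flanks.
#' @export
barcode_reference <- function(strain_id, gene, uptag,
                              upstream_flank = UPTAG_UPSTREAM_FLANK,
                              downstream_flank = UPTAG_DOWNSTREAM_FLANK) {
  strain_id <- as.character(strain_id)
  gene <- as.character(gene)
  uptag <- toupper(as.character(uptag))
  if (length(strain_id) < 1L)
    stop("barcode reference must contain at least one record", call. = FALSE)
  if (length(gene) != length(strain_id) || length(uptag) != length(strain_id))
    stop("strain_id, gene and uptag must have equal length", call. = FALSE)
  if (any(!nzchar(uptag)) || anyNA(uptag))
    stop("uptags must be non-empty", call. = FALSE)
  if (anyDuplicated(strain_id))
    stop("duplicate strain_id: ",
         paste(unique(strain_id[duplicated(strain_id)]), collapse = ", "),
         call. = FALSE)
  dup <- duplicated(uptag) | duplicated(uptag, fromLast = TRUE)
  if (any(dup)) {
    pairs <- split(strain_id[dup], uptag[dup])
    stop("duplicate uptag(s): ",
         paste(vapply(names(pairs), function(u)
           sprintf("%s shared by {%s}", u,
                   paste(pairs[[u]], collapse = ", ")), ""), collapse = "; "),
         call. = FALSE)
  }
  if (any(grepl("[^ACGT]", uptag)))
    warning("uptag(s) contain non-ACGT characters")
  structure(list(
    records = data.frame(strain_id = strain_id, gene = gene, uptag = uptag,
                         stringsAsFactors = FALSE),
    upstream_flank = toupper(upstream_flank),
    downstream_flank = toupper(downstream_flank)
  ), class = "barcode_reference")
}

#' @export
print.barcode_reference <- function(x, ...) {
  cat(sprintf("barcode_reference: %d strains, uptag length %s, flanks %d/%d nt\n",
              nrow(x$records),
              paste(range(nchar(x$records$uptag)), collapse = "-"),
              nchar(x$upstream_flank), nchar(x$downstream_flank)))
  invisible(x)
}

#' Read a barcode reference from a TSV file
#'
#' Expects a tab-separated file with header columns `strain_id`, `gene`
#' and `uptag` (additional columns are ignored). Sequences are uppercased
#' on input; duplicate uptags or strain ids are rejected.
#'
#' @param path Path to the TSV file.
#' @inheritParams barcode_reference
#' @return A `barcode_reference`.
#' @export
parse_barcode_reference <- function(path,
                                    upstream_flank = UPTAG_UPSTREAM_FLANK,
                                    downstream_flank = UPTAG_DOWNSTREAM_FLANK) {
  if (!file.exists(path))
    stop("barcode reference file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  needed <- c("strain_id", "gene", "uptag")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0L)
    stop("barcode reference is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(tab) == 0L)
    stop("barcode reference file is empty: ", path, call. = FALSE)
  barcode_reference(tab$strain_id, tab$gene, tab$uptag,
                    upstream_flank = upstream_flank,
                    downstream_flank = downstream_flank)
}

#' Write a barcode reference to TSV
#'
#' @param reference A `barcode_reference`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_barcode_reference <- function(reference, path) {
  stopifnot(inherits(reference, "barcode_reference"))
  utils::write.table(reference$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
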
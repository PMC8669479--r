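#' Build a 16x24 validation plate layout
#'
#' The validation arrays place up to 308 test strains on a 384-position
#' (16 rows x 24 columns) grid: the four corners are voids (no inoculation),
#' the remaining 72 border positions carry wild type (BY4741), and the
#' 14 x 22 = 308 interior positions are filled with test strains in
#' row-major order; unfilled interior positions are marked `void_extra`.
#'
#' @param strains Character vector of unique strain ids, length <= 308.
#' @return A `plate_layout`: data frame with `row` (1-16), `col` (1-24),
#'   `role` (void / void_extra / wildtype / strain) and `strain_id`.
#' @export
build_validation_layout <- function(strains = character(0)) {
  strains <- as.character(strains)
  if (length(strains) > 308L)
    stop("layout capacity is 308 interior positions; got ",
         length(strains), " strains", call. = FALSE)
  if (anyDuplicated(strains))
    stop("duplicate strain ids in layout", call. = FALSE)
  grid <- expand.grid(col = 1:24, row = 1:16)[, c("row", "col")]
  corner <- (grid$row %in% c(1L, 16L)) & (grid$col %in% c(1L, 24L))
  border <- (grid$row %in% c(1L, 16L) | grid$col %in% c(1L, 24L)) & !corner
  interior <- !corner & !border
  role <- rep("void_extra", nrow(grid))
  role[corner] <- "void"
  role[border] <- "wildtype"
  strain_id <- rep(NA_character_, nrow(grid))
  ii <- which(interior)  # already row-major: grid varies col fastest
  fill <- seq_along(strains)
  role[ii[fill]] <- "strain"
  strain_id[ii[fill]] <- strains
  structure(data.frame(row = grid$row, col = grid$col, role = role,
                       strain_id = strain_id, stringsAsFactors = FALSE),
            class = c("plate_layout", "data.frame"))
}

#' Expand a 384-position layout to the 1,536-spot quadruplicate map
#'
#' Each 16x24 position is stamped as a 2x2 block of spots on the 32x48
#' array, so spot (R, C) maps back to position (ceiling(R/2), ceiling(C/2)).
#' A full plate has 1,536 spots: 16 corner-void spots and 288 wild-type
#' border spots.
#'
#' @param layout A [build_validation_layout()] result.
#' @return Data frame with `spot_row` (1-32), `spot_col` (1-48), `row`,
#'   `col`, `role`, `strain_id`; 1,536 rows.
#' @export
expand_quadruplicate <- function(layout) {
  stopifnot(inherits(layout, "plate_layout"))
  spots <- expand.grid(spot_col = 1:48, spot_row = 1:32)[, c("spot_row",
                                                             "spot_col")]
  spots$row <- ceiling(spots$spot_row / 2)
  spots$col <- ceiling(spots$spot_col / 2)
  key_l <- paste(layout$row, layout$col)
  idx <- match(paste(spots$row, spots$col), key_l)
  spots$role <- layout$role[idx]
  spots$strain_id <- layout$strain_id[idx]
  spots
}

#' Quantify colony-array spots from a grayscale image
#'
#' Averages the pixel values of a fixed square cut-out centered on each of
#' the 32x48 spots, on a 0-255 grayscale. Spot centers default to a regular
#' grid (image dimensions must then be multiples of 32 and 48); explicit
#' centers may be supplied, e.g. from an affine fit to corner fiducials.
#'
#' @param image Numeric matrix (single channel) with values on a 0-255
#'   scale (use [read_plate_image()] for PNG files).
#' @param centers Optional 1536 x 2 matrix of (row, col) pixel centers in
#'   spot order (row-major over the 32x48 grid).
#' @param halfwidth Half-width of the square cut-out in pixels (default 3,
#'   i.e. a 7x7 cut-out).
#' @param invert If TRUE, report `255 - value` so that larger always means
#'   more growth on dark-colony imagery.
#' @return A 32x48 numeric matrix of spot intensities (`spot_grid`).
#' @export
quantify_spots <- function(image, centers = NULL, halfwidth = 3L,
                           invert = FALSE) {
  stopifnot(is.matrix(image))
  if (is.null(centers)) {
    if (nrow(image) %% 32L != 0L || ncol(image) %% 48L != 0L)
      stop("image dimensions must be multiples of 32 x 48 for the regular ",
           "grid; supply centers otherwise", call. = FALSE)
    bh <- nrow(image) / 32L; bw <- ncol(image) / 48L
    centers <- as.matrix(expand.grid(
      c = (seq_len(48) - 0.5) * bw, r = (seq_len(32) - 0.5) * bh))[, c("r", "c")]
  }
  stopifnot(nrow(centers) == 1536L)
  g <- matrix(NA_real_, 32L, 48L)
  for (k in seq_len(1536L)) {
    r0 <- round(centers[k, 1L]); c0 <- round(centers[k, 2L])
    rs <- (r0 - halfwidth):(r0 + halfwidth)
    cs <- (c0 - halfwidth):(c0 + halfwidth)
    if (min(rs) < 1L || max(rs) > nrow(image) ||
        min(cs) < 1L || max(cs) > ncol(image))
      stop("cut-out for spot ", k, " falls outside the image", call. = FALSE)
    sr <- ((k - 1L) %/% 48L) + 1L
    sc <- ((k - 1L) %% 48L) + 1L
    g[sr, sc] <- mean(image[rs, cs])
  }
  if (invert) g <- 255 - g
  structure(g, class = c("spot_grid", "matrix"))
}

#' Read a grayscale plate image from PNG
#'
#' @param path PNG file; multi-channel images are averaged to one channel.
#' @return Numeric matrix on the 0-255 scale.
#' @export
read_plate_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3, dim(img)[3]),
                                               drop = FALSE], c(1, 2), mean)
  img * 255
}

#' Median spot intensity per strain
#'
#' Collapses the quadruplicate spots of every plate position to their median
#' intensity, per the plate map; voids are excluded. Wild-type border
#' positions are reported alongside strains (one median per position) for
#' visual-control inspection.
#'
#' @param spot_grid 32x48 intensity matrix from [quantify_spots()].
#' @param role_map Spot-level map from [expand_quadruplicate()].
#' @return Data frame `row`, `col`, `role`, `strain_id`,
#'   `median_intensity`; one row per non-void position.
#' @export
summarize_strains <- function(spot_grid, role_map) {
  vals <- spot_grid[cbind(role_map$spot_row, role_map$spot_col)]
  keep <- role_map$role %in% c("strain", "wildtype")
  key <- paste(role_map$row, role_map$col)
  med <- tapply(vals[keep], key[keep], stats::median)
  first <- !duplicated(key) & keep
  out <- data.frame(row = role_map$row[first], col = role_map$col[first],
                    role = role_map$role[first],
                    strain_id = role_map$strain_id[first],
                    stringsAsFactors = FALSE)
  out$median_intensity <- as.numeric(med[paste(out$row, out$col)])
  out[order(out$row, out$col), , drop = FALSE]
}

#' Call resistant strains by plate-wide z score
#'
#' Standardizes each test strain's median intensity against the mean and
#' sample standard deviation of all test-strain medians (wild-type border
#' positions and voids are excluded from the statistics by default) and
#' calls `resistant` at z > 3, `candidate` at 2 < z <= 3, otherwise `ns`.
#' Strains that failed to grow on the control plate (control median below
#' the 5th percentile of control medians, when a control summary is given)
#' are flagged `no_growth_control` and excluded from statistics and calls.
#'
#' @param summary Data frame from [summarize_strains()] for the treatment
#'   plate (or any data frame with `strain_id`, `role`, `median_intensity`).
#' @param control_summary Optional [summarize_strains()] result for the
#'   solvent-control plate, used for the no-growth gate.
#' @param include_wildtype If TRUE, wild-type positions also enter the mean
#'   and SD (off by default).
#' @param z_resistant,z_candidate Call thresholds in SD units (3 and 2).
#' @return Data frame `strain_id`, `median_intensity`, `z`, `call`.
#' @export
call_resistant <- function(summary, control_summary = NULL,
                           include_wildtype = FALSE,
                           z_resistant = 3, z_candidate = 2) {
  test <- summary[summary$role == "strain", , drop = FALSE]
  if (nrow(test) < 3L)
    stop("need at least three strain medians", call. = FALSE)
  no_growth <- rep(FALSE, nrow(test))
  if (!is.null(control_summary)) {
    ctrl <- control_summary[control_summary$role == "strain", , drop = FALSE]
    cm <- ctrl$median_intensity[match(test$strain_id, ctrl$strain_id)]
    thr <- stats::quantile(ctrl$median_intensity, 0.05, na.rm = TRUE)
    no_growth <- !is.na(cm) & cm < thr
  }
  pool <- test$median_intensity[!no_growth]
  if (include_wildtype)
    pool <- c(pool, summary$median_intensity[summary$role == "wildtype"])
  mu <- mean(pool)
  sdev <- stats::sd(pool)
  if (!is.finite(sdev) || sdev == 0) {
    warning("degenerate spread: all medians equal; z set to 0")
    z <- rep(0, nrow(test))
  } else {
    z <- (test$median_intensity - mu) / sdev
  }
  call <- ifelse(no_growth, "no_growth_control",
          ifelse(z > z_resistant, "resistant",
          ifelse(z > z_candidate, "candidate", "ns")))
  data.frame(strain_id = test$strain_id,
             median_intensity = test$median_intensity,
             z = z, call = call, stringsAsFactors = FALSE)
}
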
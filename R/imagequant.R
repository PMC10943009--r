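#' Multi-round image stack
#'
#' Named list of 2-D non-negative images of identical shape: one round per
#' imaged module, a nuclear-stain round, and optionally a background
#' (autofluorescence) round.
#'
#' @param rounds Named list of numeric matrices.
#' @param nuclear Name of the nuclear round.
#' @param background Optional name of the background round.
#' @param pixel_size Physical pixel size (micron/px), > 0.
#' @param fov Field-of-view identifier.
#' @return An `image_stack` object.
#' @export
image_stack <- function(rounds, nuclear = "DAPI", background = NULL,
                        pixel_size = 1, fov = "fov1") {
  abort_if(is.null(names(rounds)) || any(names(rounds) == ""),
           "rounds must be a named list")
  dims <- vapply(rounds, dim, integer(2))
  abort_if(any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]),
           "all rounds must share the same shape")
  abort_if(!nuclear %in% names(rounds), "nuclear round not found")
  abort_if(!is.null(background) && !background %in% names(rounds),
           "background round not found")
  abort_if(pixel_size <= 0, "pixel_size must be positive")
  structure(list(rounds = rounds, nuclear = nuclear, background = background,
                 pixel_size = pixel_size, fov = fov),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$rounds[[1]])
  cat(sprintf("<image_stack> %d rounds of %dx%d px (nuclear: %s%s)\n",
              length(x$rounds), d[1], d[2], x$nuclear,
              if (is.null(x$background)) "" else
                sprintf(", background: %s", x$background)))
  invisible(x)
}

module_rounds <- function(stack) {
  setdiff(names(stack$rounds), c(stack$nuclear, stack$background))
}

#' Read / write an image stack as multi-page TIFF plus a round manifest
#'
#' `write_image_stack()` writes `rounds.tif` (32-bit float, one page per
#' round) and `manifest.csv` (`round_id`, `is_nuclear`, `is_background`,
#' `pixel_size`) into `dir`; `read_image_stack()` reverses it.
#'
#' @param stack An [image_stack()].
#' @param dir Directory.
#' @return The stack (read) or `dir` invisibly (write).
#' @export
write_image_stack <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  # TIFF pages are stored in [0, 1]; per-round scales live in the manifest
  scales <- vapply(stack$rounds, function(r) max(max(r), 1), numeric(1))
  pages <- Map(function(r, s) r / s, stack$rounds, scales)
  tiff::writeTIFF(unname(pages), file.path(dir, "rounds.tif"),
                  bits.per.sample = 32L, reduce = FALSE)
  utils::write.csv(
    data.frame(round_id = names(stack$rounds),
               is_nuclear = names(stack$rounds) == stack$nuclear,
               is_background = names(stack$rounds) %in% stack$background,
               scale = unname(scales),
               pixel_size = stack$pixel_size),
    file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(dir) {
  pages <- tiff::readTIFF(file.path(dir, "rounds.tif"), all = TRUE)
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  pages <- Map(function(p, s) p * s, pages, man$scale)
  names(pages) <- man$round_id
  image_stack(pages, nuclear = man$round_id[man$is_nuclear][1],
              background = if (any(man$is_background))
                man$round_id[man$is_background][1],
              pixel_size = man$pixel_size[1])
}

#' Write / read a segmentation label map as TIFF
#'
#' Labels are stored as 32-bit float pages scaled by 1/65535 (the TIFF
#' writer expects values in `[0, 1]`), exact for up to 65535 labels.
#'
#' @param labels Integer label matrix (0 = background).
#' @param path TIFF path.
#' @return `path` invisibly (write) or the integer matrix (read).
#' @export
write_label_map <- function(labels, path) {
  abort_if(max(labels) > 65535, "label map supports at most 65535 labels")
  tiff::writeTIFF(matrix(as.numeric(labels) / 65535,
                         nrow(labels), ncol(labels)),
                  path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Watershed segmentation of a nuclear-stain image
#'
#' Gaussian smoothing, global threshold (Otsu by default), Euclidean distance
#' transform, watershed. Labels with fewer than `min_area_px` pixels are
#' discarded and the rest relabelled contiguously. This is the basic
#' segmentation fallback; externally produced label maps (e.g. from deep
#' learning segmenters) can be supplied to the pipeline directly.
#'
#' @param nuclear_image Non-negative matrix.
#' @param smoothing_sigma Gaussian sigma in pixels (0 = no smoothing).
#' @param threshold `"otsu"` or a numeric intensity threshold.
#' @param min_area_px Minimum nucleus area in pixels.
#' @return Integer label matrix.
#' @export
segment_nuclei_watershed <- function(nuclear_image, smoothing_sigma = 2,
                                     threshold = "otsu",
                                     min_area_px = 3000) {
  abort_if(length(nuclear_image) == 0, "empty image")
  img <- as_dense_matrix(nuclear_image)
  if (smoothing_sigma > 0) {
    img <- as.matrix(EBImage::gblur(EBImage::Image(img),
                                    sigma = smoothing_sigma))
  }
  thr <- if (identical(threshold, "otsu")) {
    rng <- range(img)
    if (rng[2] > rng[1]) {
      scaled <- (img - rng[1]) / (rng[2] - rng[1])
      rng[1] + EBImage::otsu(EBImage::Image(scaled)) * (rng[2] - rng[1])
    } else {
      rng[2]  # flat image: nothing above threshold
    }
  } else {
    threshold
  }
  fg <- img > thr
  if (!any(fg)) {
    rlang::warn("no foreground above threshold; returning empty label map")
    return(matrix(0L, nrow(img), ncol(img)))
  }
  dm <- EBImage::distmap(EBImage::Image(fg * 1))
  ws <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  labels <- matrix(as.integer(EBImage::imageData(ws)), nrow(img), ncol(img))
  areas <- tabulate(labels)
  keep <- which(areas >= min_area_px)
  relabel <- integer(max(labels, 1L))
  relabel[keep] <- seq_along(keep)
  labels[labels > 0] <- relabel[labels[labels > 0]]
  labels
}

fft_freq <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= floor((n - 1) / 2), k, k - n)
}

#' Subpixel image registration by phase correlation
#'
#' Estimates the translation `(dy, dx)` such that
#' `moving(y, x) ~ fixed(y - dy, x - dx)`: the argmax of the inverse FFT of
#' the normalized cross-power spectrum, refined to subpixel precision by
#' evaluating an upsampled discrete Fourier transform in a +/-1 px
#' neighbourhood of the integer peak. Applying the negated shift (see
#' [align_image()]) aligns `moving` onto `fixed`.
#'
#' @param moving,fixed Equal-shape numeric matrices.
#' @param upsample Upsampling factor of the refinement (50 gives 0.02 px
#'   steps).
#' @param fmax Low-pass cut-off of the spectral mask in cycles/pixel per
#'   axis. Phase-correlation whitening weights all frequencies equally, so
#'   the aliased, noise-dominated band near Nyquist would otherwise bias the
#'   subpixel estimate; 0.35 keeps the well-measured low band. Set to 0.5 to
#'   disable.
#' @return Named numeric `c(dy, dx)`.
#' @export
register_image <- function(moving, fixed, upsample = 50, fmax = 0.35) {
  abort_if(!all(dim(moving) == dim(fixed)), "images must share shape")
  abort_if(all(moving == 0) || all(fixed == 0),
           "shift undefined for an all-zero image",
           class = "modulefish_undefined_error")
  nr <- nrow(fixed); nc <- ncol(fixed)
  cross <- stats::fft(moving) * Conj(stats::fft(fixed))
  mod <- Mod(cross)
  cpn <- cross / ifelse(mod > 0, mod, 1)
  if (fmax < 0.5) {
    cpn <- cpn * outer(abs(fft_freq(nr) / nr) <= fmax,
                       abs(fft_freq(nc) / nc) <= fmax)
  }
  cc <- Re(stats::fft(cpn, inverse = TRUE)) / length(cpn)
  peak <- arrayInd(which.max(cc), dim(cc)) - 1L
  d0 <- ifelse(peak > c(nr, nc) / 2, peak - c(nr, nc), peak)
  if (upsample > 1) {
    ky <- fft_freq(nr); kx <- fft_freq(nc)
    ys <- d0[1] + seq(-1, 1, by = 1 / upsample)
    xs <- d0[2] + seq(-1, 1, by = 1 / upsample)
    er <- exp(2i * pi * outer(ys, ky) / nr)
    ec <- exp(2i * pi * outer(kx, xs) / nc)
    up <- Re(er %*% cpn %*% ec)
    best <- arrayInd(which.max(up), dim(up))
    d <- c(ys[best[1]], xs[best[2]])
  } else {
    d <- as.numeric(d0)
  }
  c(dy = d[1], dx = d[2])
}

#' Translate an image by a (possibly fractional) shift
#'
#' Returns the image resampled so that a round registered at shift
#' `(dy, dx)` (see [register_image()]) lands on the fixed frame:
#' `out(y, x) = img(y + dy, x + dx)` with bilinear interpolation. Pixels
#' whose source falls outside the image become `NA` and are excluded from
#' per-cell means rather than zero-filled.
#'
#' @param img Numeric matrix.
#' @param shift Numeric `(dy, dx)`.
#' @return Matrix with `NA` at out-of-bounds pixels.
#' @export
align_image <- function(img, shift) {
  nr <- nrow(img); nc <- ncol(img)
  sy <- seq_len(nr) + shift[1]
  sx <- seq_len(nc) + shift[2]
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  grab <- function(yy, xx) {
    m <- matrix(NA_real_, nr, nc)
    oky <- yy >= 1 & yy <= nr
    okx <- xx >= 1 & xx <= nc
    m[oky, okx] <- img[yy[oky], xx[okx], drop = FALSE]
    m
  }
  term <- function(m, w) {
    r <- m * w
    r[w == 0] <- 0
    r
  }
  out <- term(grab(y0, x0), outer(1 - fy, 1 - fx)) +
    term(grab(y0 + 1L, x0), outer(fy, 1 - fx)) +
    term(grab(y0, x0 + 1L), outer(1 - fy, fx)) +
    term(grab(y0 + 1L, x0 + 1L), outer(fy, fx))
  out
}

#' Apply the shift-acceptance policy across rounds
#'
#' `per_image` applies every registered shift as measured. `fov_average`
#' first discards shifts whose `|dy|` or `|dx|` exceeds `max_abs_px`
#' (registration failures), then applies the arithmetic mean of the survivors
#' to every round — appropriate when the stage reproducibly mis-positions all
#' rounds of a field of view by the same amount.
#'
#' @param shifts Rounds x 2 matrix (or tibble with `dy`, `dx`), one row per
#'   round.
#' @param max_abs_px Discard threshold in pixels (strict `>`).
#' @param mode `"per_image"` or `"fov_average"`.
#' @return Matrix of applied shifts (same rows as input) with attribute
#'   `discarded` (row indices dropped by the filter).
#' @export
shift_policy <- function(shifts, max_abs_px = 50,
                         mode = c("per_image", "fov_average")) {
  mode <- match.arg(mode)
  if (is.data.frame(shifts)) shifts <- cbind(shifts$dy, shifts$dx)
  shifts <- matrix(as.numeric(shifts), ncol = 2,
                   dimnames = list(rownames(shifts), c("dy", "dx")))
  abort_if(nrow(shifts) == 0, "at least one shift is required")
  if (mode == "per_image") {
    attr(shifts, "discarded") <- integer(0)
    return(shifts)
  }
  bad <- abs(shifts[, 1]) > max_abs_px | abs(shifts[, 2]) > max_abs_px
  abort_if(all(bad), "all shifts exceed max_abs_px",
           class = "modulefish_empty_error")
  avg <- colMeans(shifts[!bad, , drop = FALSE])
  out <- matrix(avg, nrow(shifts), 2, byrow = TRUE,
                dimnames = dimnames(shifts))
  attr(out, "discarded") <- which(bad)
  out
}

#' Subtract an aligned background image
#'
#' Pixel-wise difference, clamped at zero (camera intensities are
#' non-negative).
#'
#' @param image,background_image Equal-shape matrices (background already
#'   aligned with the same shift as `image`).
#' @return Matrix.
#' @export
subtract_background <- function(image, background_image) {
  abort_if(!all(dim(image) == dim(background_image)),
           "image and background must share shape")
  pmax(image - background_image, 0)
}

#' Percentile-based illumination / background-level correction
#'
#' Subtracts a scalar — the given percentile of the pixels outside the cell
#' masks — from the whole image (clamped at zero). Removes field-of-view-level
#' offset differences using only pixels that carry no cell signal.
#'
#' @param image Numeric matrix.
#' @param cell_masks Equal-shape label matrix (0 = outside cells).
#' @param percentile Percentile (linear interpolation between order
#'   statistics).
#' @return Corrected matrix.
#' @export
illumination_correct <- function(image, cell_masks, percentile = 60) {
  abort_if(!all(dim(image) == dim(cell_masks)),
           "masks must share the image shape")
  off <- image[cell_masks == 0]
  off <- off[!is.na(off)]
  abort_if(length(off) == 0, "no off-mask pixels",
           class = "modulefish_empty_error")
  pmax(image - pctl(off, percentile), 0)
}

#' Grow nucleus masks into cell masks
#'
#' Each label grows to all background pixels within Euclidean distance
#' `dilation_px` of the label's pixels; a pixel reachable from several nuclei
#' is assigned to the nearest one, so labels never merge and the boundary
#' between two close nuclei is equidistant.
#'
#' @param nuclei Integer label matrix.
#' @param dilation_px Dilation radius in pixels (>= 0; 0 is the identity).
#' @return Integer label matrix with the same label identities.
#' @export
dilate_masks <- function(nuclei, dilation_px) {
  abort_if(dilation_px < 0, "dilation_px must be >= 0")
  nuclei <- matrix(as.integer(nuclei), nrow(nuclei), ncol(nuclei))
  if (dilation_px == 0 || !any(nuclei > 0)) return(nuclei)
  d <- EBImage::distmap(EBImage::Image((nuclei == 0) * 1))
  mask <- nuclei > 0 | as.matrix(d) <= dilation_px + 1e-9
  out <- EBImage::propagate(EBImage::Image(matrix(0, nrow(nuclei), ncol(nuclei))),
                            seeds = EBImage::Image(nuclei),
                            mask = EBImage::Image(mask), lambda = 1e8)
  matrix(as.integer(EBImage::imageData(out)), nrow(nuclei), ncol(nuclei))
}

#' Normalize an image to a high percentile
#'
#' Divides by the given percentile of pixel intensities (99th by default);
#' output values can exceed 1.
#'
#' @param image Numeric matrix.
#' @param percentile Percentile used as the divisor.
#' @return Normalized matrix.
#' @export
normalize_image <- function(image, percentile = 99) {
  abort_if(length(image) == 0, "empty image")
  v <- pctl(image[!is.na(image)], percentile)
  abort_if(v == 0, "normalization percentile is zero",
           class = "modulefish_undefined_error")
  image / v
}

masked_means <- function(img, masks, n_labels) {
  ok <- !is.na(img) & masks > 0
  sums <- rep(0, n_labels)
  npx <- rep(0L, n_labels)
  t1 <- tapply(img[ok], masks[ok], sum)
  t2 <- tapply(rep(1L, sum(ok)), masks[ok], sum)
  idx <- as.integer(names(t1))
  sums[idx] <- t1
  npx[idx] <- t2
  list(mean = ifelse(npx > 0, sums / pmax(npx, 1L), NA_real_), n_px = npx)
}

#' Cell-by-module intensity matrix
#'
#' Entry `(cell, module)` is the mean intensity of the module's (aligned)
#' image over the cell's mask pixels. Out-of-bounds pixels created by
#' alignment are excluded from the means; a cell whose mask retains no valid
#' pixel in some round is flagged (`qc_reason = "empty_mask"`), not silently
#' dropped.
#'
#' @param stack An [image_stack()]; only module rounds are quantified.
#' @param cell_masks Integer label matrix (e.g. from [dilate_masks()]).
#' @param shifts Optional rounds x 2 matrix of `(dy, dx)` per module round
#'   (row order matching the stack's module rounds); images are aligned
#'   by [align_image()] with the negated sampling convention described there.
#' @return A `cell_by_module` object: list with `values` (cells x modules
#'   matrix) and `cells` (tibble `cell`, `y_px`, `x_px`, `y_um`, `x_um`,
#'   `area_px`, `qc_flag`, `qc_reason`, `fov`).
#' @export
intensity_matrix <- function(stack, cell_masks, shifts = NULL) {
  abort_if(!inherits(stack, "image_stack"), "stack must be an image_stack")
  abort_if(!all(dim(cell_masks) == dim(stack$rounds[[1]])),
           "masks must share the image shape")
  mods <- module_rounds(stack)
  n_labels <- max(cell_masks)
  abort_if(n_labels == 0, "no cells in the label map",
           class = "modulefish_empty_error")
  if (is.null(shifts)) shifts <- matrix(0, length(mods), 2)
  if (is.data.frame(shifts)) shifts <- cbind(shifts$dy, shifts$dx)
  shifts <- matrix(as.numeric(shifts), ncol = 2)
  abort_if(nrow(shifts) != length(mods), "one shift per module round required")

  values <- matrix(NA_real_, n_labels, length(mods),
                   dimnames = list(NULL, mods))
  empty <- rep(FALSE, n_labels)
  for (m in seq_along(mods)) {
    img <- stack$rounds[[mods[m]]]
    if (any(shifts[m, ] != 0)) img <- align_image(img, shifts[m, ])
    mm <- masked_means(img, cell_masks, n_labels)
    values[, m] <- mm$mean
    empty <- empty | mm$n_px == 0
  }
  cy <- tapply(row(cell_masks)[cell_masks > 0], cell_masks[cell_masks > 0], mean)
  cx <- tapply(col(cell_masks)[cell_masks > 0], cell_masks[cell_masks > 0], mean)
  area <- tabulate(cell_masks, nbins = n_labels)
  ypx <- rep(NA_real_, n_labels); xpx <- rep(NA_real_, n_labels)
  ypx[as.integer(names(cy))] <- cy
  xpx[as.integer(names(cx))] <- cx
  cells <- tibble::tibble(
    cell = seq_len(n_labels),
    y_px = ypx, x_px = xpx,
    y_um = ypx * stack$pixel_size, x_um = xpx * stack$pixel_size,
    area_px = area,
    qc_flag = empty | area == 0,
    qc_reason = ifelse(empty | area == 0, "empty_mask", NA_character_),
    fov = stack$fov)
  structure(list(values = values, cells = cells,
                 pixel_size = stack$pixel_size),
            class = "cell_by_module")
}

#' @export
print.cell_by_module <- function(x, ...) {
  cat(sprintf("<cell_by_module> %d cells x %d modules (%d flagged by QC)\n",
              nrow(x$values), ncol(x$values), sum(x$cells$qc_flag)))
  invisible(x)
}

#' Flag low-quality cells in a cell-by-module matrix
#'
#' `total_percentile` mode flags cells whose summed intensity across modules
#' is below the given percentile of all totals. `band` mode flags cells that
#' are below the per-module `low_percentile` in every module ("dark" cells)
#' or above the per-module `high_percentile` in more than `max_high_modules`
#' modules (saturated debris). Flags carry reasons; when the relevant
#' distribution is degenerate (all equal) nothing is flagged and a warning is
#' raised.
#'
#' @param cbm A [intensity_matrix()] result.
#' @param mode `"total_percentile"` or `"band"`.
#' @param percentile Percentile of totals (total mode).
#' @param low_percentile,high_percentile Per-module band percentiles.
#' @param max_high_modules Band mode: flag when bright in strictly more than
#'   this many modules.
#' @return The `cell_by_module` with updated `qc_flag` / `qc_reason`.
#' @export
qc_cells <- function(cbm, mode = c("total_percentile", "band"),
                     percentile = 15, low_percentile = 0.2,
                     high_percentile = 98, max_high_modules = 30) {
  mode <- match.arg(mode)
  v <- cbm$values
  abort_if(nrow(v) == 0, "empty matrix", class = "modulefish_empty_error")
  flag <- rep(FALSE, nrow(v))
  reason <- rep(NA_character_, nrow(v))
  if (mode == "total_percentile") {
    totals <- rowSums(v, na.rm = TRUE)
    if (max(totals) == min(totals)) {
      rlang::warn("degenerate totals; no cells flagged")
    } else {
      thr <- pctl(totals, percentile)
      flag <- totals < thr
      reason[flag] <- "low_total"
    }
  } else {
    low_thr <- apply(v, 2, pctl, p = low_percentile)
    high_thr <- apply(v, 2, pctl, p = high_percentile)
    if (all(apply(v, 2, function(col) max(col) == min(col)))) {
      rlang::warn("degenerate module distributions; no cells flagged")
    } else {
      low <- rowSums(sweep(v, 2, low_thr, `<`), na.rm = TRUE) == ncol(v)
      high <- rowSums(sweep(v, 2, high_thr, `>`), na.rm = TRUE) >
        max_high_modules
      flag <- low | high
      reason[low] <- "low_all_modules"
      reason[high] <- "high_many_modules"
    }
  }
  cbm$cells$qc_flag <- cbm$cells$qc_flag | flag
  cbm$cells$qc_reason <- dplyr::coalesce(cbm$cells$qc_reason, reason)
  cbm
}

#' Drop QC-flagged cells
#'
#' @param cbm A `cell_by_module`.
#' @return The same object restricted to QC-passing cells.
#' @export
qc_pass <- function(cbm) {
  keep <- !cbm$cells$qc_flag
  cbm$values <- cbm$values[keep, , drop = FALSE]
  cbm$cells <- cbm$cells[keep, ]
  cbm
}

#' Named quantification presets
#'
#' Parameter bundles mirroring the per-experiment processing choices:
#' `fig2` (5 px dilation, 99th-percentile normalization, no matrix QC —
#' downstream max-channel assignment does the filtering), `fig3` (15 px,
#' normalization, cells below the 15th percentile of total intensity
#' removed), `fig4` (10 px, normalization, 20th percentile), `fig5` (10 px,
#' 60th-percentile off-mask illumination correction, band QC at the
#' 0.2/98 percentiles with a 30-module limit, field-of-view-averaged shifts).
#'
#' @param name One of `"fig2"`, `"fig3"`, `"fig4"`, `"fig5"`.
#' @return List of parameters for [quantify_stack()].
#' @export
quantify_preset <- function(name = c("fig3", "fig2", "fig4", "fig5")) {
  name <- match.arg(name)
  switch(name,
    fig2 = list(dilation_px = 5, normalize_percentile = 99,
                illumination_percentile = NULL, qc_mode = "none",
                shift_mode = "per_image"),
    fig3 = list(dilation_px = 15, normalize_percentile = 99,
                illumination_percentile = NULL, qc_mode = "total_percentile",
                qc_percentile = 15, shift_mode = "per_image"),
    fig4 = list(dilation_px = 10, normalize_percentile = 99,
                illumination_percentile = NULL, qc_mode = "total_percentile",
                qc_percentile = 20, shift_mode = "per_image"),
    fig5 = list(dilation_px = 10, normalize_percentile = NULL,
                illumination_percentile = 60, qc_mode = "band",
                qc_low = 0.2, qc_high = 98, qc_max_high_modules = 30,
                shift_mode = "fov_average"))
}

#' Quantify an image stack into a QC'd cell-by-module matrix
#'
#' The full chain: register every module round to the nuclear round, apply
#' the shift policy, align, subtract the background round (if present, with
#' the same shifts), dilate the nucleus masks into cell masks, optionally
#' subtract the off-mask illumination percentile, optionally normalize each
#' round to its 99th percentile, average per cell mask, and QC-flag cells.
#'
#' @param stack An [image_stack()].
#' @param nuclei Integer nucleus label matrix; if `NULL`, segmented from the
#'   nuclear round with [segment_nuclei_watershed()] (`min_area_px` then
#'   matters).
#' @param preset Preset name passed to [quantify_preset()].
#' @param max_shift_px Shift-policy discard threshold.
#' @param min_area_px Only used when segmenting internally.
#' @param ... Overrides for individual preset entries.
#' @return A `cell_by_module` with QC flags applied, plus attributes
#'   `shifts` (applied) and `raw_shifts` (as registered).
#' @export
quantify_stack <- function(stack, nuclei = NULL, preset = "fig3",
                           max_shift_px = 50, min_area_px = 3000, ...) {
  p <- utils::modifyList(quantify_preset(preset), list(...))
  if (is.null(nuclei)) {
    nuclei <- segment_nuclei_watershed(stack$rounds[[stack$nuclear]],
                                       min_area_px = min_area_px)
  }
  mods <- module_rounds(stack)
  raw <- t(vapply(mods, function(m) {
    register_image(stack$rounds[[m]], stack$rounds[[stack$nuclear]])
  }, numeric(2)))
  applied <- shift_policy(raw, max_abs_px = max_shift_px,
                          mode = p$shift_mode)

  masks <- dilate_masks(nuclei, p$dilation_px)
  rounds <- stack$rounds
  bg <- if (!is.null(stack$background)) rounds[[stack$background]]
  for (m in seq_along(mods)) {
    img <- rounds[[mods[m]]]
    if (any(applied[m, ] != 0)) img <- align_image(img, applied[m, ])
    if (!is.null(bg)) {
      bg_aligned <- if (any(applied[m, ] != 0)) {
        align_image(bg, applied[m, ])
      } else {
        bg
      }
      img <- subtract_background(img, bg_aligned)
    }
    if (!is.null(p$illumination_percentile)) {
      img <- illumination_correct(img, masks, p$illumination_percentile)
    }
    if (!is.null(p$normalize_percentile)) {
      img <- normalize_image(img, p$normalize_percentile)
    }
    rounds[[mods[m]]] <- img
  }
  aligned_stack <- stack
  aligned_stack$rounds <- rounds
  cbm <- intensity_matrix(aligned_stack, masks, shifts = NULL)
  cbm <- switch(p$qc_mode,
    none = cbm,
    total_percentile = qc_cells(cbm, "total_percentile",
                                percentile = p$qc_percentile),
    band = qc_cells(cbm, "band", low_percentile = p$qc_low,
                    high_percentile = p$qc_high,
                    max_high_modules = p$qc_max_high_modules))
  attr(cbm, "shifts") <- applied
  attr(cbm, "raw_shifts") <- raw
  cbm
}
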
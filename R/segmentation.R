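#' Linear contrast enhancement to the full display range
#'
#' Remaps intensities so the minimum maps to the low end and the maximum to
#' the high end of the display range, monotonically and linearly in between.
#' This sharpens the difference between stained cells and background before
#' thresholding.
#'
#' @param pixels numeric matrix of grayscale values.
#' @param display_range two-element range to map onto (default 8-bit).
#' @return remapped matrix of the same shape.
#' @export
enhance_contrast <- function(pixels, display_range = c(0, 255)) {
  r <- range(pixels, finite = TRUE)
  if (r[1] == r[2])
    stop("constant image: contrast enhancement is degenerate")
  display_range[1] +
    (pixels - r[1]) / (r[2] - r[1]) * (display_range[2] - display_range[1])
}

#' Otsu threshold of an 8-bit image
#'
#' Exhaustive scan of the 255 candidate cuts maximizing the between-class
#' variance `w0 * w1 * (mu0 - mu1)^2` of the 256-bin intensity histogram.
#' Ties resolve to the smallest maximizing threshold. Pixels with intensity
#' less than or equal to the threshold form the dark class.
#'
#' @param pixels numeric vector or matrix; values are clamped to 0..255 and
#'   binned at integer resolution.
#' @return integer threshold in 0..254, or `NA` for a constant image.
#' @export
otsu_threshold <- function(pixels) {
  v <- pmin(pmax(as.vector(pixels), 0), 255)
  h <- tabulate(as.integer(round(v)) + 1L, nbins = 256L)
  n <- sum(h)
  levels <- 0:255
  w0 <- cumsum(h)[1:255]
  w1 <- n - w0
  s0 <- cumsum(h * levels)[1:255]
  mu0 <- ifelse(w0 > 0, s0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (sum(h * levels) - s0) / w1, 0)
  bcv <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
  bcv[w0 == 0 | w1 == 0] <- 0
  if (max(bcv) == 0) return(NA_integer_)
  as.integer(which.max(bcv) - 1L)
}

#' Dynamic Otsu binarization of a section image
#'
#' Computes a per-image Otsu threshold inside the region of interest and
#' returns the binary mask of stained (dark) pixels. When a reference mask
#' for the sparsely populated SLM layer is supplied, the threshold is
#' clamped downward so that no more than `max_slm_foreground` of the SLM
#' reference pixels would be classified as foreground: the SLM is known to
#' contain almost no somas, so a threshold flooding it is rejected.
#'
#' @param pixels grayscale matrix (one coronal section).
#' @param roi optional region of interest as `c(row_min, row_max, col_min,
#'   col_max)` (1-based, inclusive); pixels outside the ROI are never
#'   foreground and do not enter the threshold computation.
#' @param slm_mask optional logical matrix (same shape) marking the SLM
#'   reference region.
#' @param max_slm_foreground maximum tolerated foreground fraction inside
#'   the SLM reference (default 1%).
#' @param enhance apply [enhance_contrast()] before thresholding (default);
#'   the mask geometry is unaffected for already full-range images.
#' @return logical matrix of foreground (stained) pixels, with the chosen
#'   threshold in attribute `"threshold"`.
#' @export
binarize_dynamic_otsu <- function(pixels, roi = NULL, slm_mask = NULL,
                                  max_slm_foreground = 0.01,
                                  enhance = TRUE) {
  if (!is.null(roi)) {
    if (roi[1] < 1 || roi[3] < 1 || roi[2] > nrow(pixels) ||
        roi[4] > ncol(pixels) || roi[1] > roi[2] || roi[3] > roi[4])
      stop("empty or out-of-bounds roi")
    work <- pixels[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
  } else {
    work <- pixels
  }
  if (enhance && length(unique(as.vector(work))) > 1)
    work <- enhance_contrast(work)
  thr <- otsu_threshold(work)
  if (is.na(thr)) {
    warning("no bimodality: constant region, returning empty mask")
    mask <- matrix(FALSE, nrow(pixels), ncol(pixels))
    attr(mask, "threshold") <- NA_integer_
    return(mask)
  }
  if (!is.null(slm_mask)) {
    if (!any(slm_mask)) stop("slm reference mask is empty")
    if (!is.null(roi)) {
      ref <- slm_mask[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
    } else ref <- slm_mask
    refv <- as.integer(round(pmin(pmax(work[ref], 0), 255)))
    if (length(refv)) {
      # largest threshold keeping the SLM foreground fraction below the cap
      frac <- cumsum(tabulate(refv + 1L, nbins = 256L)) / length(refv)
      ok <- which(frac[1:255] <= max_slm_foreground) - 1L
      clamp <- if (length(ok)) max(ok) else -1L
      thr <- min(thr, clamp)
    }
  }
  sub <- work <= thr
  mask <- matrix(FALSE, nrow(pixels), ncol(pixels))
  if (!is.null(roi)) {
    mask[roi[1]:roi[2], roi[3]:roi[4]] <- sub
  } else {
    mask[] <- sub
  }
  attr(mask, "threshold") <- as.integer(thr)
  mask
}

#' Convert a binary mask to soma coordinates
#'
#' Every foreground pixel is one soma: at soma-sized pixel resolution
#' (about 20 um, comparable to a pyramidal soma diameter) each stained
#' pixel is associated to one cell body. Coordinates follow the fixed
#' convention `x = column * xy_resolution`, `y = row * xy_resolution`,
#' `z = slice_index * z_resolution`, all indices 0-based.
#'
#' @param mask logical matrix of foreground pixels.
#' @param slice_index 0-based index of the section in the stack.
#' @param xy_resolution,z_resolution um per pixel / per slice.
#' @param mode `"pixel"` (one soma per foreground pixel, the default rule)
#'   or `"component"` (one soma at the centroid of each 4-connected
#'   component, a denoising alternative).
#' @return data frame `gid, x, y, z` (gids local to this call).
#' @export
mask_to_somas <- function(mask, slice_index, xy_resolution = 20,
                          z_resolution = 20,
                          mode = c("pixel", "component")) {
  stopifnot_scalar_pos(xy_resolution, "xy_resolution")
  stopifnot_scalar_pos(z_resolution, "z_resolution")
  mode <- match.arg(mode)
  if (mode == "pixel") {
    idx <- which(mask, arr.ind = TRUE)
    col0 <- idx[, 2] - 1
    row0 <- idx[, 1] - 1
  } else {
    lab <- .label_components_cpp(mask)
    ids <- sort(unique(lab[lab > 0]))
    if (length(ids)) {
      idx <- which(mask, arr.ind = TRUE)
      l <- lab[idx]
      col0 <- tapply(idx[, 2] - 1, l, mean)
      row0 <- tapply(idx[, 1] - 1, l, mean)
    } else {
      col0 <- row0 <- numeric(0)
    }
  }
  data.frame(gid = seq_along(col0),
             x = as.numeric(col0) * xy_resolution,
             y = as.numeric(row0) * xy_resolution,
             z = rep(slice_index * z_resolution, length(col0)))
}

#' Segment a whole stack into soma coordinates
#'
#' Applies [binarize_dynamic_otsu()] and [mask_to_somas()] to every section
#' of the stack and concatenates the results with globally unique GIDs.
#'
#' @param stack rows x cols x slices grayscale array.
#' @param imaging an [make_imaging_params()] (resolutions are taken from it).
#' @param roi,slm_mask,max_slm_foreground,enhance,mode
#'   passed to the per-slice operations.
#' @return data frame `gid, x, y, z` over all sections.
#' @export
segment_stack <- function(stack, imaging = make_imaging_params(),
                          roi = NULL, slm_mask = NULL,
                          max_slm_foreground = 0.01, enhance = TRUE,
                          mode = "pixel") {
  out <- vector("list", dim(stack)[3])
  for (s in seq_len(dim(stack)[3])) {
    mask <- binarize_dynamic_otsu(stack[, , s], roi = roi,
                                  slm_mask = slm_mask,
                                  max_slm_foreground = max_slm_foreground,
                                  enhance = enhance)
    out[[s]] <- mask_to_somas(mask, s - 1L, imaging$xy_resolution,
                              imaging$z_resolution, mode = mode)
  }
  somas <- do.call(rbind, out)
  somas$gid <- seq_len(nrow(somas))
  somas
}

#' Extract a landmark surface cloud from a labelled stack
#'
#' For every section, the boundary pixels of the requested region label
#' (foreground pixels with at least one 4-neighbour outside the region,
#' image borders included) are extracted, tagged by 4-connected component,
#' scaled to micrometres and stacked into a 3D surface point cloud.
#'
#' @param label_stack integer rows x cols x slices array of region labels.
#' @param region_id the label to extract.
#' @param xy_resolution,z_resolution um per pixel / per slice.
#' @return data frame `x, y, z, slice, component`; if the region occurs in
#'   a single slice the result carries attribute `degenerate = TRUE` and a
#'   warning is raised (no usable 3D mesh).
#' @export
build_landmark_mesh <- function(label_stack, region_id, xy_resolution = 20,
                                z_resolution = 20) {
  present <- vapply(seq_len(dim(label_stack)[3]),
                    function(s) any(label_stack[, , s] == region_id),
                    logical(1))
  if (!any(present))
    stop("region ", region_id, " absent from the label stack")
  out <- list()
  for (s in which(present)) {
    m <- label_stack[, , s] == region_id
    pad <- matrix(FALSE, nrow(m) + 2, ncol(m) + 2)
    pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
    core <- pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)] &
      pad[1:nrow(m), 2:(ncol(m) + 1)] & pad[3:(nrow(m) + 2), 2:(ncol(m) + 1)] &
      pad[2:(nrow(m) + 1), 1:ncol(m)] & pad[2:(nrow(m) + 1), 3:(ncol(m) + 2)]
    boundary <- m & !core
    lab <- .label_components_cpp(m)
    idx <- which(boundary, arr.ind = TRUE)
    out[[length(out) + 1]] <- data.frame(
      x = (idx[, 2] - 1) * xy_resolution,
      y = (idx[, 1] - 1) * xy_resolution,
      z = (s - 1) * z_resolution,
      slice = s - 1L,
      component = lab[idx])
  }
  mesh <- do.call(rbind, out)
  if (sum(present) < 2) {
    warning("region ", region_id, " present in a single slice: ",
            "degenerate mesh")
    attr(mesh, "degenerate") <- TRUE
  }
  mesh
}
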
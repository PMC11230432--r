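# Bright-field colony-area measurement: focal-slab detection from the
# per-slice coefficient-of-variation profile, then a classical segmentation
# of the standard-deviation z-projection (Sobel edges, threshold,
# small-object removal, hole filling, Gaussian smoothing).

#' Colony-mask parameters
#'
#' @param pixel_size_um Pixel size (default 0.271 um/pixel).
#' @param sobel_kernel Sobel kernel size (default 5).
#' @param threshold Binarisation threshold on the Sobel response of the
#'   mean-normalized projection (default 0.025).
#' @param min_object_area_um2 Minimum object area kept (default 734 um^2).
#' @param gaussian_sigma_px Smoothing SD in pixels (default 3).
#' @return List of class `ng_mask_params`.
#' @export
mask_params <- function(pixel_size_um = 0.271, sobel_kernel = 5,
                        threshold = 0.025, min_object_area_um2 = 734,
                        gaussian_sigma_px = 3) {
  stopifnot(pixel_size_um > 0, sobel_kernel == 5 || sobel_kernel == 3,
            threshold > 0, min_object_area_um2 > 0, gaussian_sigma_px > 0)
  structure(list(pixel_size_um = pixel_size_um, sobel_kernel = sobel_kernel,
                 threshold = threshold,
                 min_object_area_um2 = min_object_area_um2,
                 gaussian_sigma_px = gaussian_sigma_px),
            class = "ng_mask_params")
}

#' Find the in-focus colony slab of a bright-field z-stack
#'
#' Computes the per-slice coefficient of variation (SD/mean). A bright-field
#' phase object has minimal contrast in focus, so the CV minimum is the
#' middle slice; the CV maxima below and above it approximate the bottom
#' and top of the colony.
#'
#' @param stack 3D array (z, y, x).
#' @return Integer vector `c(z_bottom, z_mid, z_top)`.
#' @export
find_colony_slab <- function(stack) {
  nz <- dim(stack)[1]
  if (is.na(nz) || nz < 5) stop("stack must have at least 5 slices")
  cv_prof <- vapply(seq_len(nz), function(z) {
    sl <- stack[z, , ]
    sd(sl) / mean(sl)
  }, numeric(1))
  z_mid <- which.min(cv_prof)
  if (z_mid == 1 || z_mid == nz)
    stop("no interior CV minimum: cannot locate the in-focus slice")
  z_bottom <- which.max(cv_prof[seq_len(z_mid - 1)])
  z_top <- z_mid + which.max(cv_prof[(z_mid + 1):nz])
  c(z_bottom = z_bottom, z_mid = z_mid, z_top = z_top)
}

# normalized Sobel kernels (unit-gradient response): smoothing cross
# derivative, 5-tap by default
sobel_kernels <- function(size = 5) {
  if (size == 5) list(smooth = c(1, 4, 6, 4, 1) / 16,
                      deriv = c(-1, -2, 0, 2, 1) / 8)
  else list(smooth = c(1, 2, 1) / 4, deriv = c(-1, 0, 1) / 2)
}

# fill interior holes: background components not connected to the image
# border become foreground (4-connectivity for background)
fill_holes <- function(mask) {
  bg <- label_components_cpp(!mask, 4L)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_labels <- border_labels[border_labels > 0]
  mask | (bg > 0 & !(bg %in% border_labels))
}

# drop connected components smaller than min_px (8-connectivity)
remove_small_objects <- function(mask, min_px) {
  lab <- label_components_cpp(mask, 8L)
  if (max(lab) == 0) return(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), 0, sigma)
  k / sum(k)
}

#' Segment the colony in a bright-field z-stack and measure its area
#'
#' Crops the stack to the colony slab, makes a standard-deviation
#' z-projection normalized by the mean intensity of the cropped stack,
#' applies a first-order Sobel filter (gradient magnitude), thresholds,
#' removes objects smaller than `min_object_area_um2`, fills holes,
#' Gaussian-smooths and re-binarises at 0.5, and fills holes again. When
#' several objects survive, the largest connected component is reported as
#' the colony.
#'
#' @param stack 3D array (z, y, x).
#' @param params [mask_params()].
#' @return List with `mask` (logical matrix), `area_um2` (0 when no colony
#'   is found), `slab` (the [find_colony_slab()] result).
#' @export
segment_colony <- function(stack, params = mask_params()) {
  # a stack with no focal structure (monotone or flat CV profile) has no
  # detectable colony
  slab <- tryCatch(find_colony_slab(stack), error = function(e) NULL)
  if (is.null(slab)) {
    return(list(mask = matrix(FALSE, dim(stack)[2], dim(stack)[3]),
                area_um2 = 0, slab = NULL))
  }
  sub <- stack[slab["z_bottom"]:slab["z_top"], , , drop = FALSE]
  nz <- dim(sub)[1]
  proj <- apply(sub, c(2, 3), sd)
  proj <- proj / mean(sub)
  kk <- sobel_kernels(params$sobel_kernel)
  gx <- conv2_sep_cpp(proj, kk$smooth, kk$deriv)
  gy <- conv2_sep_cpp(proj, kk$deriv, kk$smooth)
  mag <- sqrt(gx^2 + gy^2)
  mask <- mag > params$threshold
  min_px <- ceiling(params$min_object_area_um2 / params$pixel_size_um^2)
  mask <- remove_small_objects(mask, min_px)
  no_colony <- list(mask = matrix(FALSE, nrow(proj), ncol(proj)),
                    area_um2 = 0, slab = slab)
  if (!any(mask)) return(no_colony)
  mask <- fill_holes(mask)
  gk <- gaussian_kernel_1d(params$gaussian_sigma_px)
  sm <- conv2_sep_cpp(mask + 0, gk, gk)
  mask <- sm >= 0.5
  if (!any(mask)) return(no_colony)
  mask <- fill_holes(mask)
  lab <- label_components_cpp(mask, 8L)
  sizes <- tabulate(lab[lab > 0])
  if (!length(sizes) || max(sizes) < min_px) return(no_colony)
  mask <- lab == which.max(sizes)
  list(mask = mask, area_um2 = sum(mask) * params$pixel_size_um^2,
       slab = slab)
}
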
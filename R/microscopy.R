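#' Imaging model parameters
#'
#' Camera/optics constants for synthetic fluorescence images of bacteria.
#' The defaults describe an EM-CCD-like setup at 100 nm/pixel with a
#' diffraction-limited PSF of sigma 1.3 px on a 512 x 512 frame. Intensities
#' are calibrated so one AU corresponds to one detected photon per pixel:
#' with `shot_noise = TRUE` each pixel's photon signal is Poisson
#' distributed around its expectation, then camera offset and Gaussian read
#' noise are added.
#'
#' @param nrow,ncol Frame size in pixels.
#' @param psf_sigma PSF standard deviation in pixels.
#' @param camera_offset Camera baseline added to every pixel (AU).
#' @param read_noise_sd Gaussian read noise SD (AU); 0 disables it.
#' @param photon_scale Photons detected per fluorophore in a spot (AU).
#' @param unbound_bg Diffuse unbound-protein fluorescence inside cells
#'   (AU/pixel), e.g. free RNA-binding fusion protein.
#' @param shot_noise Apply Poisson noise to the photon signal?
#' @param pixel_nm Physical pixel size (nm), metadata only.
#' @param cell_halflength_px,cell_halfwidth_px Ellipse semi-axes of a cell
#'   of size 1, in pixels; linear dimensions scale with sqrt(cell size).
#' @param conc_scale AU/pixel of in-cell fluorescence per unit reporter
#'   concentration.
#' @return An object of class `imaging_params`.
#' @export
imaging_params <- function(nrow = 512L, ncol = 512L, psf_sigma = 1.3,
                           camera_offset = 100, read_noise_sd = 2,
                           photon_scale = 200, unbound_bg = 0,
                           shot_noise = TRUE, pixel_nm = 100,
                           cell_halflength_px = 11, cell_halfwidth_px = 4,
                           conc_scale = 1) {
  p <- list(nrow = as.integer(nrow), ncol = as.integer(ncol),
            psf_sigma = psf_sigma, camera_offset = camera_offset,
            read_noise_sd = read_noise_sd, photon_scale = photon_scale,
            unbound_bg = unbound_bg, shot_noise = isTRUE(shot_noise),
            pixel_nm = pixel_nm, cell_halflength_px = cell_halflength_px,
            cell_halfwidth_px = cell_halfwidth_px, conc_scale = conc_scale)
  stopifnot(p$nrow > 0, p$ncol > 0, p$psf_sigma > 0, p$camera_offset >= 0,
            p$read_noise_sd >= 0, p$photon_scale > 0, p$unbound_bg >= 0,
            p$cell_halflength_px > 0, p$cell_halfwidth_px > 0,
            p$conc_scale > 0)
  class(p) <- "imaging_params"
  p
}

#' Synthesize a fluorescence image of cells with optional mRNA spots
#'
#' Renders a subset of a simulated population as an image: each cell is an
#' ellipse (rod-like bacterium) at a random position and orientation,
#' filled with its reporter *concentration* (`conc_scale * G / s`, so
#' integrated intensity tracks total protein while mean intensity tracks
#' concentration) plus the diffuse unbound-protein background. Optional
#' diffraction-limited spots model single mRNAs decorated by fluorescent
#' RNA-binding protein: each spot adds a 2D Gaussian of SD `psf_sigma`
#' integrating to `fluorophores * photon_scale`. A 24-tandem-site mRNA
#' bound by dimeric coat protein carries up to 48 fluorophores. Poisson
#' shot noise (if enabled), camera offset and read noise are applied last.
#'
#' Cells are placed by rejection sampling; overlapping placements are
#' retried up to `max_retries` times, then an error is raised.
#'
#' @param pop A [simulate_population()] result.
#' @param img A [imaging_params()] object.
#' @param n_cells Number of cells to render (first `n_cells` of `pop`).
#' @param spots_per_cell Expected number of spots per cell (Poisson), or an
#'   integer vector of exact per-cell counts.
#' @param fluorophores_per_spot Fluorophore count per spot: a scalar, or a
#'   function(n) returning n counts (e.g. partial site occupancy).
#' @param seed Integer seed.
#' @param max_retries Placement retries per cell before giving up.
#' @return An object of class `image_sample`: `image` (matrix, AU), `masks`
#'   (label matrix, 0 = background, labels 1..n contiguous), `concentration`
#'   (per-cell AU/px), `size` (per-cell size factors), `spots` (data.frame
#'   `spot`, `cell`, `row`, `col`, `fluorophores`; 1-based pixel-center
#'   coordinates), `params`.
#' @export
simulate_image <- function(pop, img = imaging_params(), n_cells = 20L,
                           spots_per_cell = 0, fluorophores_per_spot = 48L,
                           seed = 1L, max_retries = 200L) {
  stopifnot(inherits(pop, "cell_population"), inherits(img, "imaging_params"))
  n_cells <- as.integer(n_cells)
  stopifnot(n_cells >= 0, n_cells <= length(pop$reporter))
  set.seed(as.integer(seed))

  image <- matrix(0, img$nrow, img$ncol)
  masks <- matrix(0L, img$nrow, img$ncol)
  conc <- numeric(0)
  sizes <- numeric(0)
  spots <- data.frame(spot = integer(0), cell = integer(0), row = integer(0),
                      col = integer(0), fluorophores = numeric(0))

  if (n_cells > 0) {
    G <- pop$reporter[seq_len(n_cells)]
    s <- pop$size[seq_len(n_cells)]
    conc <- img$conc_scale * G / s
    sizes <- s
    a <- img$cell_halflength_px * sqrt(s)
    b <- img$cell_halfwidth_px * sqrt(s)

    centers <- matrix(NA_real_, n_cells, 2)
    radius <- a + 1
    for (i in seq_len(n_cells)) {
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        margin <- radius[i] + 1
        cy <- stats::runif(1, margin, img$nrow - margin)
        cx <- stats::runif(1, margin, img$ncol - margin)
        if (i == 1L) ok <- TRUE else {
          prev <- seq_len(i - 1L)
          ok <- all((centers[prev, 1] - cy)^2 + (centers[prev, 2] - cx)^2 >
                      (radius[prev] + radius[i] + 1)^2)
        }
        if (ok) {
          centers[i, ] <- c(cy, cx)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place cell ", i, " without overlap after ",
             max_retries, " retries; reduce n_cells or cell size",
             call. = FALSE)
      }
    }
    theta <- stats::runif(n_cells, 0, pi)

    for (i in seq_len(n_cells)) {
      cy <- centers[i, 1]; cx <- centers[i, 2]
      r0 <- max(1L, floor(cy - radius[i])); r1 <- min(img$nrow, ceiling(cy + radius[i]))
      c0 <- max(1L, floor(cx - radius[i])); c1 <- min(img$ncol, ceiling(cx + radius[i]))
      rr <- r0:r1; cc <- c0:c1
      dy <- outer(rr - cy, rep(1, length(cc)))
      dx <- outer(rep(1, length(rr)), cc - cx)
      u <- (dy * cos(theta[i]) + dx * sin(theta[i])) / a[i]
      v <- (-dy * sin(theta[i]) + dx * cos(theta[i])) / b[i]
      inside <- u^2 + v^2 <= 1
      sub_m <- masks[rr, cc]
      sub_m[inside] <- i
      masks[rr, cc] <- sub_m
      sub_i <- image[rr, cc]
      sub_i[inside] <- sub_i[inside] + conc[i] + img$unbound_bg
      image[rr, cc] <- sub_i
    }

    # spots: drawn per cell at uniformly chosen in-mask pixels
    n_spots <- if (length(spots_per_cell) == n_cells) {
      as.integer(spots_per_cell)
    } else if (length(spots_per_cell) == 1L) {
      if (spots_per_cell == as.integer(spots_per_cell)) {
        rep.int(as.integer(spots_per_cell), n_cells)
      } else stats::rpois(n_cells, spots_per_cell)
    } else stop("spots_per_cell must be scalar or length n_cells",
                call. = FALSE)
    sp_list <- list()
    for (i in which(n_spots > 0)) {
      px <- which(masks == i, arr.ind = TRUE)
      pick <- px[sample.int(nrow(px), n_spots[i], replace = TRUE), ,
                 drop = FALSE]
      nf <- if (is.function(fluorophores_per_spot)) {
        fluorophores_per_spot(n_spots[i])
      } else rep.int(fluorophores_per_spot, n_spots[i])
      for (j in seq_len(n_spots[i])) {
        image <- add_gaussian_spot(image, pick[j, 1], pick[j, 2],
                                   total = nf[j] * img$photon_scale,
                                   sigma = img$psf_sigma)
      }
      sp_list[[length(sp_list) + 1L]] <-
        data.frame(cell = i, row = as.integer(pick[, 1]),
                   col = as.integer(pick[, 2]), fluorophores = nf)
    }
    if (length(sp_list)) {
      spots <- do.call(rbind, sp_list)
      spots <- cbind(spot = seq_len(nrow(spots)), spots)
    }
  }

  if (img$shot_noise) {
    image[] <- stats::rpois(length(image), lambda = pmax(image, 0))
  }
  image <- image + img$camera_offset
  if (img$read_noise_sd > 0) {
    image <- image + stats::rnorm(length(image), sd = img$read_noise_sd)
  }
  structure(list(image = image, masks = masks, concentration = conc,
                 size = sizes, spots = spots, params = img,
                 seed = as.integer(seed)),
            class = "image_sample")
}

# Adds a 2D Gaussian of the given continuous integral, truncated at 5 sigma.
add_gaussian_spot <- function(image, row, col, total, sigma) {
  r <- ceiling(5 * sigma)
  rr <- max(1L, row - r):min(nrow(image), row + r)
  cc <- max(1L, col - r):min(ncol(image), col + r)
  amp <- total / (2 * pi * sigma^2)
  g <- amp * exp(-(outer((rr - row)^2, (cc - col)^2, "+")) / (2 * sigma^2))
  image[rr, cc] <- image[rr, cc] + g
  image
}

#' @export
print.image_sample <- function(x, ...) {
  cat("<image_sample>", nrow(x$image), "x", ncol(x$image), "px,",
      length(x$concentration), "cells,", nrow(x$spots), "spots\n")
  invisible(x)
}

#' Per-cell mean intensities with image background subtraction
#'
#' Implements the mask-based quantification protocol: for every labelled
#' cell the mean pixel intensity inside its mask is extracted, and the mean
#' intensity of a large cell-free region is subtracted. The background
#' region is the largest connected component of unmasked pixels if it holds
#' at least 1,000 px, otherwise all unmasked pixels.
#'
#' @param img An [simulate_image()] result, or a numeric matrix.
#' @param masks Label matrix (0 = background); defaults to `img$masks`.
#' @return A `data.frame` with one row per nonempty label: `cell_id`,
#'   `mean`, `npix`, `integrated`, `background`, `bgsub_mean`,
#'   `bgsub_integrated`.
#' @export
quantify_cells <- function(img, masks = NULL) {
  if (inherits(img, "image_sample")) {
    if (is.null(masks)) masks <- img$masks
    img <- img$image
  }
  stopifnot(is.matrix(img), is.matrix(masks),
            all(dim(img) == dim(masks)))
  labels <- seq_len(max(masks))
  bg_mask <- masks == 0
  comp <- EBImage::bwlabel(bg_mask)
  comp_sizes <- tabulate(comp[comp > 0])
  bg_px <- if (length(comp_sizes) && max(comp_sizes) >= 1000L) {
    comp == which.max(comp_sizes)
  } else bg_mask
  background <- mean(img[bg_px])
  rows <- lapply(labels, function(l) {
    px <- img[masks == l]
    if (!length(px)) {
      warning("mask label ", l, " is empty; skipped")
      return(NULL)
    }
    data.frame(cell_id = l, mean = mean(px), npix = length(px),
               integrated = sum(px), background = background,
               bgsub_mean = mean(px) - background,
               bgsub_integrated = sum(px) - background * length(px))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cell_id = integer(0), mean = numeric(0),
                      npix = integer(0), integrated = numeric(0),
                      background = numeric(0), bgsub_mean = numeric(0),
                      bgsub_integrated = numeric(0))
  }
  out
}

#' Signal-to-noise ratio of mRNA spots over in-cell background
#'
#' Scores each known spot of an [simulate_image()] sample as
#' `SNR = (peak - local background mean) / SD(local background)`, where the
#' local background is taken from in-cell pixels in an annulus around the
#' spot (inner radius 4 sigma, outer 7 sigma of the PSF, keeping the
#' Gaussian tail below 0.04% of the peak), excluding pixels within 4 sigma
#' of any spot. If fewer than `min_annulus` such pixels
#' exist, the annulus is widened to all eligible in-cell pixels and the row
#' is flagged. This is the detectability proxy for single mRNAs against
#' unbound fluorescent protein.
#'
#' @param img An [simulate_image()] result.
#' @param spots Spot table; defaults to `img$spots` (ground truth).
#' @param min_annulus Minimum number of annulus pixels before widening.
#' @return A `data.frame` with `spot`, `cell`, `row`, `col`, `snr`,
#'   `n_annulus`, `widened`.
#' @export
spot_snr <- function(img, spots = NULL, min_annulus = 30L) {
  stopifnot(inherits(img, "image_sample"))
  if (is.null(spots)) spots <- img$spots
  if (nrow(spots) == 0L) {
    return(data.frame(spot = integer(0), cell = integer(0), row = integer(0),
                      col = integer(0), snr = numeric(0),
                      n_annulus = integer(0), widened = logical(0)))
  }
  sigma <- img$params$psf_sigma
  im <- img$image
  masks <- img$masks
  all_sp <- img$spots
  out <- lapply(seq_len(nrow(spots)), function(i) {
    r0 <- spots$row[i]; c0 <- spots$col[i]
    cell <- masks[r0, c0]
    px <- which(masks == cell, arr.ind = TRUE)
    d2 <- (px[, 1] - r0)^2 + (px[, 2] - c0)^2
    # distance to any spot in this cell (exclude all spot cores)
    sp_cell <- all_sp[all_sp$cell == cell, , drop = FALSE]
    near_spot <- rep.int(FALSE, nrow(px))
    for (j in seq_len(nrow(sp_cell))) {
      near_spot <- near_spot |
        ((px[, 1] - sp_cell$row[j])^2 + (px[, 2] - sp_cell$col[j])^2 <
           (4 * sigma)^2)
    }
    ann <- !near_spot & d2 >= (4 * sigma)^2 & d2 <= (7 * sigma)^2
    widened <- FALSE
    if (sum(ann) < min_annulus) {
      ann <- !near_spot
      widened <- TRUE
    }
    vals <- im[px[ann, , drop = FALSE]]
    if (length(vals) < 2L) {
      return(data.frame(spot = i, cell = cell, row = r0, col = c0,
                        snr = NA_real_, n_annulus = length(vals),
                        widened = widened))
    }
    snr <- (im[r0, c0] - mean(vals)) / stats::sd(vals)
    data.frame(spot = i, cell = cell, row = r0, col = c0, snr = snr,
               n_annulus = sum(ann), widened = widened)
  })
  do.call(rbind, out)
}

#' Write / read an image sample as TIFF plus JSON sidecar
#'
#' Images are stored as 16-bit grayscale TIFF. Arbitrary-unit intensities
#' are scaled into the 16-bit range; the scale factor is recorded in a JSON
#' sidecar so [read_image_sample()] restores the original values (to 16-bit
#' quantization). Masks are stored as a label TIFF with unit scale.
#'
#' @param img An [simulate_image()] result.
#' @param path Base path; writes `<path>_image.tif`, `<path>_masks.tif`,
#'   `<path>_meta.json`, and `<path>_cells.csv` (quantification).
#' @return Invisibly, the written file paths.
#' @export
write_image_sample <- function(img, path) {
  stopifnot(inherits(img, "image_sample"))
  scale <- max(img$image, 1e-12)
  tiff::writeTIFF(img$image / scale, paste0(path, "_image.tif"),
                  bits.per.sample = 16L)
  tiff::writeTIFF(img$masks / 65535, paste0(path, "_masks.tif"),
                  bits.per.sample = 16L)
  meta <- list(intensity_scale = scale, mask_scale = 65535,
               n_cells = length(img$concentration),
               spots = img$spots, params = unclass(img$params),
               seed = img$seed)
  jsonlite::write_json(meta, paste0(path, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(quantify_cells(img), paste0(path, "_cells.csv"),
                   row.names = FALSE)
  invisible(paste0(path, c("_image.tif", "_masks.tif", "_meta.json",
                           "_cells.csv")))
}

#' @rdname write_image_sample
#' @return `read_image_sample()`: a list with `image`, `masks`, `spots`,
#'   `params`.
#' @export
read_image_sample <- function(path) {
  meta <- jsonlite::read_json(paste0(path, "_meta.json"),
                              simplifyVector = TRUE)
  image <- tiff::readTIFF(paste0(path, "_image.tif")) * meta$intensity_scale
  masks <- round(tiff::readTIFF(paste0(path, "_masks.tif")) *
                   meta$mask_scale)
  list(image = image, masks = matrix(as.integer(masks), nrow(masks)),
       spots = as.data.frame(meta$spots), params = meta$params)
}
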
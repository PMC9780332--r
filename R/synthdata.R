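# Synthetic micrograph generator: fields of spherocylindrical (rod-shaped)
# cells with uniform cytoplasmic fluorescence, optional bright foci of known
# partition ratio rho, Gaussian PSF blur, background, and camera noise --
# with full per-cell ground truth so the whole downstream pipeline can be
# benchmarked without real data.
#
# Rendering is binary-membership (a pixel belongs to a shape iff its centre
# does), so noiseless, blur-free scenes obey exact intensity arithmetic:
# interior = background + cytoplasm, focus = background + rho * cytoplasm.

#' Scene parameters for the synthetic micrograph generator
#'
#' Defaults emulate wide-field fluorescence imaging of *E. coli* at 100x/1.4
#' NA: 0.065 um/px, cells 2-4 um long and ~1 um wide, a diffraction-limited
#' PSF (sigma 1.2 px), Poisson shot noise plus Gaussian read noise.
#'
#' @param image_shape Image size in pixels (rows, cols).
#' @param pixel_size Pixel size, um/px.
#' @param n_cells Number of cells to place.
#' @param cell_length_range,cell_width_range Tip-to-tip length and width
#'   ranges, um.
#' @param cytoplasm_intensity,background_intensity Arbitrary intensity units
#'   (added: a cell pixel reads background + cytoplasm).
#' @param condensate_fraction Probability that a cell carries condensates.
#' @param partition_ratio Condensed/dilute intensity ratio rho >= 1 applied
#'   to focus pixels of condensate-bearing cells. A vector gives a
#'   deterministic per-cell mixture (cycled over cells in order).
#' @param condensate_radius_range Focus radius range, um.
#' @param foci_per_cell Foci per condensate-bearing cell (>= 1).
#' @param placement `"polar"` (focus at a randomly chosen pole, the typical
#'   appearance in micrographs, and it keeps the midpoint cytoplasm
#'   reference clean) or `"axis"` (uniform along the medial axis).
#' @param psf_sigma Gaussian PSF sigma in px; 0 disables blur.
#' @param noise `NULL` for none, or a list
#'   `list(type = "poisson_gaussian", gain = 1, read_sd = 2)`; Poisson shot
#'   noise is applied as `rpois(img/gain)*gain`.
#' @param bit_depth 8 or 16; intensities are clipped to the representable
#'   range.
#' @param gap_px Minimum spacing kept between a cell and its placement-slot
#'   border (cells never overlap).
#' @param seed Integer RNG seed; scenes are bit-reproducible given the seed.
#' @return A validated `scene_params` list.
#' @export
scene_params <- function(image_shape = c(600L, 600L),
                         pixel_size = 0.065,
                         n_cells = 40L,
                         cell_length_range = c(2, 4),
                         cell_width_range = c(0.9, 1.1),
                         cytoplasm_intensity = 120,
                         background_intensity = 10,
                         condensate_fraction = 0.8,
                         partition_ratio = 1.6,
                         condensate_radius_range = c(0.25, 0.35),
                         foci_per_cell = 1L,
                         placement = c("polar", "axis"),
                         psf_sigma = 1.2,
                         noise = list(type = "poisson_gaussian",
                                      gain = 1, read_sd = 2),
                         bit_depth = 16L,
                         gap_px = 4L,
                         seed = 1L) {
  placement <- match.arg(placement)
  p <- list(image_shape = as.integer(image_shape), pixel_size = pixel_size,
            n_cells = as.integer(n_cells),
            cell_length_range = cell_length_range,
            cell_width_range = cell_width_range,
            cytoplasm_intensity = cytoplasm_intensity,
            background_intensity = background_intensity,
            condensate_fraction = condensate_fraction,
            partition_ratio = partition_ratio,
            condensate_radius_range = condensate_radius_range,
            foci_per_cell = as.integer(foci_per_cell),
            placement = placement, psf_sigma = psf_sigma, noise = noise,
            bit_depth = as.integer(bit_depth), gap_px = as.integer(gap_px),
            seed = as.integer(seed))
  validate_scene_params(p)
  structure(p, class = "scene_params")
}

validate_scene_params <- function(p) {
  if (any(p$image_shape < 16)) ct_stop("image_shape must be >= 16x16",
                                       "invalid_argument")
  if (any(p$partition_ratio < 1)) ct_stop("partition_ratio must be >= 1",
                                          "invalid_argument")
  if (p$condensate_fraction < 0 || p$condensate_fraction > 1)
    ct_stop("condensate_fraction must be in [0,1]", "invalid_argument")
  if (p$cytoplasm_intensity < 0 || p$background_intensity < 0)
    ct_stop("intensities must be >= 0", "invalid_argument")
  if (p$n_cells < 0) ct_stop("n_cells must be >= 0", "invalid_argument")
  if (p$foci_per_cell < 1) ct_stop("foci_per_cell must be >= 1",
                                   "invalid_argument")
  if (!p$bit_depth %in% c(8L, 16L)) ct_stop("bit_depth must be 8 or 16",
                                            "invalid_argument")
  invisible(p)
}

#' Construct a micrograph object
#'
#' @param pixels Non-negative numeric intensity matrix.
#' @param pixel_size Pixel size, um/px.
#' @param bit_depth 8 or 16.
#' @return A `micrograph`.
#' @export
micrograph <- function(pixels, pixel_size = 0.065, bit_depth = 16L) {
  pixels <- as.matrix(pixels)
  if (!all(is.finite(pixels)) || any(pixels < 0))
    ct_stop("pixels must be finite and non-negative", "invalid_argument")
  if (any(dim(pixels) < 16))
    ct_stop("micrograph must be at least 16x16", "invalid_argument")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 bit_depth = as.integer(bit_depth)),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph> %dx%d px, %g um/px, %d-bit, range [%.1f, %.1f]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size, x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

as_pixels <- function(img) {
  if (inherits(img, "micrograph")) img$pixels else as.matrix(img)
}

px_size <- function(img, default = 0.065) {
  if (inherits(img, "micrograph")) img$pixel_size else default
}

# distance from pixel centres (r, c grids) to segment a-b
dist_to_segment <- function(rr, cc, a, b) {
  vx <- b[1] - a[1]; vy <- b[2] - a[2]
  L2 <- vx * vx + vy * vy
  if (L2 == 0) return(sqrt((rr - a[1])^2 + (cc - a[2])^2))
  t <- ((rr - a[1]) * vx + (cc - a[2]) * vy) / L2
  t <- pmin(1, pmax(0, t))
  sqrt((rr - (a[1] + t * vx))^2 + (cc - (a[2] + t * vy))^2)
}

#' Render a synthetic micrograph with ground truth
#'
#' Cells are spherocylinders (rectangles capped by half-disks) placed on a
#' jittered grid of disjoint slots, so they can never overlap; each carries
#' uniform cytoplasmic intensity on top of a uniform background. Cells
#' selected to carry condensates get `foci_per_cell` disk foci on the medial
#' axis whose pixels are brightened to `partition_ratio` times the
#' cytoplasm. The field is then blurred with a Gaussian PSF, noise is added,
#' and intensities are clipped to the bit depth.
#'
#' @param params A [scene_params()] list.
#' @return A list with elements `image` (a [micrograph()]) and `truth`
#'   (class `scene_truth`): per-cell centroid, orientation, length, width,
#'   mask (linear pixel indices), `has_condensate`, `true_rho` and focus
#'   centres/radii, plus a per-cell summary data.frame.
#' @export
#' @examples
#' sc <- generate_scene(scene_params(n_cells = 6, image_shape = c(256, 256)))
#' sc$truth$cells[[1]]$has_condensate
generate_scene <- function(params = scene_params()) {
  p <- validate_scene_params(params)
  with_seed(p$seed, {
    nr <- p$image_shape[1]; nc <- p$image_shape[2]
    img <- matrix(p$background_intensity, nr, nc)

    # slot grid sized to the longest possible cell
    Lmax_px <- p$cell_length_range[2] / p$pixel_size
    slot <- ceiling(Lmax_px) + 2L * p$gap_px
    sr <- floor(nr / slot); sc <- floor(nc / slot)
    if (p$n_cells > 0 && p$n_cells > sr * sc) {
      ct_stop(sprintf(
        "cannot place %d non-overlapping cells in a %dx%d image (max %d); use fewer or smaller cells or a larger image",
        p$n_cells, nr, nc, sr * sc), "placement_error")
    }
    slots <- if (p$n_cells > 0) sample.int(sr * sc, p$n_cells) else integer(0)

    cells <- vector("list", p$n_cells)
    for (k in seq_len(p$n_cells)) {
      si <- (slots[k] - 1) %% sr; sj <- (slots[k] - 1) %/% sr
      L_um <- runif(1, p$cell_length_range[1], p$cell_length_range[2])
      W_um <- runif(1, p$cell_width_range[1], p$cell_width_range[2])
      L <- L_um / p$pixel_size; W <- W_um / p$pixel_size
      theta <- runif(1, 0, pi)
      jit <- (slot - L) / 2 - 1
      ctr <- c(si * slot + slot / 2 + runif(1, -jit, jit),
               sj * slot + slot / 2 + runif(1, -jit, jit))
      half <- (L - W) / 2  # cap-centre half-length
      a <- ctr + half * c(cos(theta), sin(theta))
      b <- ctr - half * c(cos(theta), sin(theta))

      lo_r <- max(1, floor(min(a[1], b[1]) - W)); hi_r <- min(nr, ceiling(max(a[1], b[1]) + W))
      lo_c <- max(1, floor(min(a[2], b[2]) - W)); hi_c <- min(nc, ceiling(max(a[2], b[2]) + W))
      rr <- matrix(lo_r:hi_r, hi_r - lo_r + 1, hi_c - lo_c + 1)
      cc <- matrix(lo_c:hi_c, hi_r - lo_r + 1, hi_c - lo_c + 1, byrow = TRUE)
      inside <- dist_to_segment(rr, cc, a, b) <= W / 2
      idx <- (cc[inside] - 1L) * nr + rr[inside]  # linear indices
      img[idx] <- img[idx] + p$cytoplasm_intensity

      has <- rbinom(1, 1, p$condensate_fraction) == 1
      rho_k <- p$partition_ratio[(k - 1) %% length(p$partition_ratio) + 1]
      rho <- if (has) rho_k else 1
      foci <- list()
      if (has && rho > 1) {
        for (f in seq_len(p$foci_per_cell)) {
          rf_um <- runif(1, p$condensate_radius_range[1],
                         p$condensate_radius_range[2])
          rf <- min(rf_um / p$pixel_size, W / 2 - 0.5)
          fc <- if (p$placement == "polar") {
            if (runif(1) < 0.5) a else b
          } else {
            t <- runif(1)
            a + t * (b - a)
          }
          fin <- inside & (sqrt((rr - fc[1])^2 + (cc - fc[2])^2) <= rf)
          fidx <- (cc[fin] - 1L) * nr + rr[fin]
          img[fidx] <- img[fidx] + (rho - 1) * p$cytoplasm_intensity
          foci[[f]] <- list(center = fc, radius_px = rf)
        }
      }
      cells[[k]] <- list(
        label = k, centroid = c(mean(rr[inside]), mean(cc[inside])),
        orientation = theta, length_um = L_um, width_um = W_um,
        mask_idx = idx, has_condensate = has && rho > 1, true_rho = rho,
        foci = foci)
    }

    if (p$psf_sigma > 0) {
      img <- as.matrix(EBImage::gblur(img, sigma = p$psf_sigma,
                                      radius = 2 * ceiling(3 * p$psf_sigma) + 1))
    }
    if (!is.null(p$noise)) {
      g <- if (is.null(p$noise$gain)) 1 else p$noise$gain
      img[] <- rpois(length(img), pmax(img, 0) / g) * g
      rsd <- if (is.null(p$noise$read_sd)) 0 else p$noise$read_sd
      if (rsd > 0) img[] <- img + rnorm(length(img), 0, rsd)
    }
    img[img < 0] <- 0
    img[img > 2^p$bit_depth - 1] <- 2^p$bit_depth - 1

    summary <- if (p$n_cells > 0) data.frame(
      label = vapply(cells, `[[`, 0, "label"),
      centroid_row = vapply(cells, function(x) x$centroid[1], 0),
      centroid_col = vapply(cells, function(x) x$centroid[2], 0),
      length_um = vapply(cells, `[[`, 0, "length_um"),
      width_um = vapply(cells, `[[`, 0, "width_um"),
      has_condensate = vapply(cells, `[[`, TRUE, "has_condensate"),
      true_rho = vapply(cells, `[[`, 0, "true_rho")
    ) else data.frame()

    list(
      image = micrograph(img, p$pixel_size, p$bit_depth),
      truth = structure(list(cells = cells, summary = summary,
                             params = p), class = "scene_truth")
    )
  })
}

#' Write a scene to disk (TIFF + ground-truth CSV + params JSON)
#'
#' @param scene Result of [generate_scene()].
#' @param prefix Output path prefix; writes `<prefix>.tif`,
#'   `<prefix>_truth.csv`, `<prefix>_params.json`.
#' @return Paths, invisibly.
#' @export
write_scene <- function(scene, prefix) {
  img <- scene$image
  maxv <- 2^img$bit_depth - 1
  tiff::writeTIFF(img$pixels / maxv, paste0(prefix, ".tif"),
                  bits.per.sample = img$bit_depth)
  write.csv(scene$truth$summary, paste0(prefix, "_truth.csv"),
            row.names = FALSE)
  jsonlite::write_json(scene$truth$params, paste0(prefix, "_params.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(paste0(prefix, c(".tif", "_truth.csv", "_params.json")))
}

#' Read a single-channel TIFF as a micrograph
#'
#' @param path TIFF path (first page of a stack).
#' @param pixel_size Pixel size, um/px.
#' @param bit_depth Bit depth used to rescale the [0,1] TIFF samples back to
#'   intensity counts.
#' @return A [micrograph()].
#' @export
read_micrograph <- function(path, pixel_size = 0.065, bit_depth = 16L) {
  if (!file.exists(path)) ct_stop(paste0("no such file: ", path),
                                  "missing_input")
  x <- tiff::readTIFF(path, all = FALSE)
  if (length(dim(x)) == 3) x <- x[, , 1]
  micrograph(x * (2^bit_depth - 1), pixel_size, bit_depth)
}

#' Synthetic growth and expression table
#'
#' Optical density follows a logistic growth curve; fluorescence accumulates
#' at `dF/dt = rate * OD(t) * a(t)` where the expression activity `a(t)`
#' optionally decays exponentially (stationary-phase shutdown), making the
#' fluorescence/OD proxy rise over the first hours and then plateau.
#'
#' @param duration Duration in hours (> 0).
#' @param timestep Sampling interval, h.
#' @param od_params `list(od0, K, r)`: initial OD, carrying capacity and
#'   growth rate (1/h). `od0 = K` gives constant OD.
#' @param expression_rate Fluorescence production rate (a.u. per OD h).
#' @param expression_decay_h Time constant of expression shutdown in hours;
#'   `Inf` disables the decay (constant rate).
#' @param noise_sd SD of multiplicative log-normal noise on both channels;
#'   0 disables.
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @return data.frame with columns time, od, fluorescence.
#' @export
generate_growth_table <- function(duration = 24, timestep = 0.25,
                                  od_params = list(od0 = 0.1, K = 2, r = 0.6),
                                  expression_rate = 50,
                                  expression_decay_h = 5,
                                  noise_sd = 0, seed = 1L) {
  if (duration <= 0) ct_stop("duration must be positive", "invalid_argument")
  if (expression_rate < 0 || od_params$r < 0 || od_params$K <= 0 ||
      od_params$od0 <= 0)
    ct_stop("rates and ODs must be positive", "invalid_argument")
  t <- seq(0, duration, by = timestep)
  K <- od_params$K; od0 <- od_params$od0; r <- od_params$r
  od <- K / (1 + (K - od0) / od0 * exp(-r * t))
  act <- if (is.finite(expression_decay_h)) exp(-t / expression_decay_h) else 1
  integrand <- expression_rate * od * act
  # cumulative trapezoid
  fl <- c(0, cumsum((integrand[-1] + integrand[-length(t)]) / 2 * diff(t)))
  if (noise_sd > 0) {
    with_seed(seed, {
      od <- od * exp(rnorm(length(t), 0, noise_sd))
      fl <- fl * exp(rnorm(length(t), 0, noise_sd))
    })
  }
  data.frame(time = t, od = od, fluorescence = fl)
}
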
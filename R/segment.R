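# Cell detection pre-processing: rolling-ball background subtraction, Li
# minimum-cross-entropy thresholding, 8-connected labeling, and
# shape-constraint filtering into cell regions with medial axes.

ball_element <- function(radius, shape = c("ball", "paraboloid")) {
  shape <- match.arg(shape)
  r <- radius
  off <- expand.grid(di = -r:r, dj = -r:r)
  d2 <- off$di^2 + off$dj^2
  keep <- d2 <= r^2
  h <- if (shape == "ball") sqrt(r^2 - d2[keep]) else -d2[keep] / (2 * r)
  list(di = as.integer(off$di[keep]), dj = as.integer(off$dj[keep]), h = h)
}

#' Rolling-ball background subtraction
#'
#' Estimates the background as the grayscale opening of the image with a
#' ball-shaped (or paraboloid) structuring element of the given radius --
#' the surface traced by rolling a ball under the intensity landscape --
#' and subtracts it. Output is clipped at zero; a flat image maps to zero.
#' For large radii the image is first shrunk by block-minimum, the ball is
#' rolled on the shrunk image with a proportionally smaller radius, and the
#' background is bilinearly re-expanded (the classical speed-up); radii up
#' to 16 px always use the exact full-resolution opening.
#'
#' @param img A [micrograph()] or intensity matrix.
#' @param radius_px Ball radius in pixels (default 100).
#' @param element `"ball"` or `"paraboloid"`.
#' @param shrink Integer shrink factor; `NULL` picks 1/2/4/8 by radius.
#' @return Background-subtracted image, same class as the input.
#' @export
rolling_ball_subtract <- function(img, radius_px = 100,
                                  element = c("ball", "paraboloid"),
                                  shrink = NULL) {
  element <- match.arg(element)
  px <- as_pixels(img)
  if (radius_px < 1 || radius_px != round(radius_px))
    ct_stop("radius_px must be a positive integer", "invalid_argument")
  if (radius_px >= min(dim(px)))
    ct_stop(sprintf("radius (%d) must be smaller than the image (%dx%d)",
                    radius_px, nrow(px), ncol(px)), "invalid_argument")
  if (is.null(shrink)) {
    shrink <- if (radius_px <= 16) 1L else if (radius_px <= 48) 2L
              else if (radius_px <= 128) 4L else 8L
  }
  if (shrink > 1) {
    small <- .block_min_cpp(px, as.integer(shrink))
    r2 <- max(1L, as.integer(round(radius_px / shrink)))
    el <- ball_element(r2, element)
    bg_small <- .gray_dilate_cpp(.gray_erode_cpp(small, el$di, el$dj, el$h),
                                 el$di, el$dj, el$h)
    bg <- .bilinear_expand_cpp(bg_small, nrow(px), ncol(px),
                               as.integer(shrink))
    bg <- pmin(bg, px)
  } else {
    el <- ball_element(as.integer(radius_px), element)
    bg <- .gray_dilate_cpp(.gray_erode_cpp(px, el$di, el$dj, el$h),
                           el$di, el$dj, el$h)
  }
  out <- px - bg
  out[out < 0] <- 0
  if (inherits(img, "micrograph")) micrograph(out, img$pixel_size,
                                              img$bit_depth) else out
}

#' Li minimum-cross-entropy threshold
#'
#' Iterative fixed-point estimate of the threshold minimising the Li & Lee
#' cross entropy between the image and its binarised means, started from
#' the image mean: given a current threshold t, the below/above-t means
#' m0, m1 are computed and t is updated to (m1 - m0)/(log m1 - log m0)
#' until convergence.
#'
#' @param img A [micrograph()] or intensity matrix with at least two
#'   distinct values.
#' @param tol Convergence tolerance on the threshold (default: 1e-7 of the
#'   intensity range).
#' @param max_iter Iteration cap.
#' @return The threshold intensity (scalar).
#' @export
li_threshold <- function(img, tol = NULL, max_iter = 200L) {
  v <- as.numeric(as_pixels(img))
  v <- v[is.finite(v)]
  rng <- diff(range(v))
  if (rng == 0) ct_stop("degenerate image: all pixels equal",
                        "degenerate_image")
  if (is.null(tol)) tol <- rng * 1e-7
  # shift to strictly positive values so partition means admit logs
  eps <- rng * 1e-6
  x <- v - min(v) + eps
  t <- mean(x)
  for (i in seq_len(max_iter)) {
    lo <- x[x <= t]; hi <- x[x > t]
    if (!length(lo) || !length(hi)) break
    m0 <- mean(lo); m1 <- mean(hi)
    if (m1 <= m0) break
    t_new <- (m1 - m0) / (log(m1) - log(m0))
    if (abs(t_new - t) < tol) { t <- t_new; break }
    t <- t_new
  }
  t + min(v) - eps
}

#' Shape constraints for cell filtering
#'
#' Ranges a connected component must satisfy to be kept as a cell: area
#' (px^2), length and width (um), circularity (4*pi*A/P^2) and maximum
#' angularity (mean absolute turning angle of the smoothed medial axis,
#' radians). Defaults suit rod-shaped bacteria imaged at 0.065 um/px.
#'
#' @param area_px Area range, px^2.
#' @param length_um,width_um Length/width ranges, um.
#' @param circularity Circularity range (dimensionless).
#' @param max_angularity Maximum angularity, radians.
#' @return A `shape_constraints` list.
#' @export
shape_constraints <- function(area_px = c(150, 2500),
                              length_um = c(1.0, 6.0),
                              width_um = c(0.5, 1.6),
                              circularity = c(0.2, 0.9),
                              max_angularity = 0.35) {
  for (rg in list(area_px, length_um, width_um, circularity)) {
    if (length(rg) != 2 || rg[1] >= rg[2])
      ct_stop("constraint ranges must be (lower, upper) with lower < upper",
              "invalid_argument")
  }
  structure(list(area_px = area_px, length_um = length_um,
                 width_um = width_um, circularity = circularity,
                 max_angularity = max_angularity),
            class = "shape_constraints")
}

# ordered longest path through a skeleton: Euclidean-weighted geodesic to
# the farthest pixel, then back (the weighted skeleton diameter), so spurs
# reaching into the poles are retained and diagonal steps count sqrt(2)
skeleton_path <- function(skel) {
  pts <- which(skel, arr.ind = TRUE)
  n <- nrow(pts)
  if (n == 0) return(NULL)
  if (n == 1) return(pts)
  key <- paste(pts[, 1], pts[, 2])
  idx <- seq_len(n); names(idx) <- key
  neigh <- function(k) {
    i <- pts[k, 1]; j <- pts[k, 2]
    cand <- paste(rep(i + c(-1, 0, 1), 3), rep(j + c(-1, 0, 1), each = 3))
    hits <- idx[cand]
    hits <- hits[!is.na(hits)]
    hits[hits != k]
  }
  wdist <- function(u, v) {
    sqrt(sum((pts[u, ] - pts[v, ])^2))
  }
  dijkstra <- function(start) {
    dist <- rep(Inf, n); par <- rep(NA_integer_, n)
    dist[start] <- 0
    done <- rep(FALSE, n)
    repeat {
      u <- which.min(ifelse(done, Inf, dist))
      if (done[u] || !is.finite(dist[u])) break
      done[u] <- TRUE
      for (v in neigh(u)) {
        alt <- dist[u] + wdist(u, v)
        if (alt < dist[v]) {
          dist[v] <- alt; par[v] <- u
        }
      }
      if (all(done | !is.finite(dist))) break
    }
    list(dist = dist, par = par)
  }
  b1 <- dijkstra(1L)
  a <- which.max(ifelse(is.finite(b1$dist), b1$dist, -1))
  b2 <- dijkstra(a)
  b <- which.max(ifelse(is.finite(b2$dist), b2$dist, -1))
  path <- c(b)
  while (!is.na(b2$par[path[1]])) path <- c(b2$par[path[1]], path)
  pts[path, , drop = FALSE]
}

# geodesic length of an ordered pixel polyline
polyline_length <- function(path) {
  if (is.null(path) || nrow(path) < 2) return(0)
  sum(sqrt(rowSums((path[-1, , drop = FALSE] -
                    path[-nrow(path), , drop = FALSE])^2)))
}

smooth_path <- function(path, k = 5) {
  if (nrow(path) < k) return(path)
  sm <- apply(path, 2, function(v) stats::filter(v, rep(1 / k, k),
                                                 sides = 2))
  ok <- stats::complete.cases(sm)
  sm[ok, , drop = FALSE]
}

# mean absolute turning angle along the smoothed, resampled medial axis
path_angularity <- function(path, stride = 3) {
  sm <- smooth_path(path)
  if (is.null(sm) || nrow(sm) < 2 * stride + 1) return(0)
  pick <- seq(1, nrow(sm), by = stride)
  if (length(pick) < 3) return(0)
  seg <- diff(sm[pick, , drop = FALSE])
  ang <- atan2(seg[, 2], seg[, 1])
  d <- diff(ang)
  d <- atan2(sin(d), cos(d))  # wrap to (-pi, pi]
  mean(abs(d))
}

# axis polyline from principal-component slicing: project mask pixels onto
# the principal axis, take the per-bin mean perpendicular position.
# Fallback used when thinning degenerates (it assumes a straight-ish rod).
pca_axis <- function(padmask) {
  pts <- which(padmask, arr.ind = TRUE)
  if (nrow(pts) < 3) return(pts)
  ctr <- colMeans(pts)
  cen <- sweep(pts, 2, ctr)
  ev <- eigen(crossprod(cen) / nrow(cen), symmetric = TRUE)$vectors[, 1]
  proj <- cen %*% ev
  perp <- cen %*% c(-ev[2], ev[1])
  bin <- round(proj)
  mperp <- tapply(perp, bin, mean)
  b <- as.numeric(names(mperp))
  ord <- order(b)
  axis <- outer(b[ord], ev) + outer(as.numeric(mperp[ord]), c(-ev[2], ev[1]))
  axis <- sweep(axis, 2, ctr, "+")
  round(axis)
}

# measure one labeled component; sub-mask cropped with a 1-px zero pad
measure_region <- function(submask, offset, pixel_size, perimeter) {
  pad <- matrix(FALSE, nrow(submask) + 2, ncol(submask) + 2)
  pad[2:(nrow(submask) + 1), 2:(ncol(submask) + 1)] <- submask
  dt <- as.matrix(EBImage::distmap(pad))
  skel <- .thin_cpp(pad)
  path <- skeleton_path(skel)
  if (is.null(path)) return(NULL)
  # a valid rod skeleton spans at least its own width; otherwise thinning
  # degenerated and the principal-axis slice is used instead
  if (polyline_length(path) + 2 * max(dt) < 2 * (2 * mean(dt[path]))) {
    path <- pca_axis(pad)
    path <- path[pad[path] & dt[path] > 1, , drop = FALSE]
    if (nrow(path) < 2) return(NULL)
  }
  # smoothing removes the zigzag of the discrete skeleton, which would
  # inflate the geodesic length by a few percent
  spath <- smooth_path(path)
  if (nrow(spath) < 2) spath <- path
  geo <- polyline_length(spath)
  # extend each skeleton end along its local outward direction to the mask
  # boundary: recovers the pole caps (and any over-erosion of the ends)
  ray_extend <- function(end, inner) {
    d <- end - inner
    nrm <- sqrt(sum(d^2))
    if (nrm == 0) return(0)
    d <- d / nrm
    t <- 0
    repeat {
      t2 <- t + 0.25
      p <- round(end + t2 * d)
      if (p[1] < 1 || p[2] < 1 || p[1] > nrow(pad) || p[2] > ncol(pad) ||
          !pad[p[1], p[2]]) break
      t <- t2
    }
    t
  }
  np <- nrow(spath)
  k <- min(np, 4)
  e1 <- ray_extend(spath[1, ], spath[k, ])
  e2 <- ray_extend(spath[np, ], spath[np - k + 1, ])
  length_px <- geo + e1 + e2
  # width from the distance transform over the central half of the axis
  # (the caps taper and would bias the mean down)
  mid <- seq(max(1, floor(nrow(path) / 4)),
             min(nrow(path), ceiling(3 * nrow(path) / 4)))
  width_px <- 2 * mean(dt[path[mid, , drop = FALSE]])
  area <- sum(submask)
  circ <- 4 * pi * area / perimeter^2
  axis_global <- cbind(path[, 1] - 1 + offset[1] - 1,
                       path[, 2] - 1 + offset[2] - 1)
  list(area_px = area,
       length_um = unname(length_px * pixel_size),
       width_um = unname(width_px * pixel_size),
       circularity = unname(circ),
       angularity = path_angularity(path),
       medial_axis = axis_global)
}

#' Segment cells from a background-subtracted micrograph
#'
#' Thresholds with [li_threshold()], fills holes, labels 8-connected
#' components, measures per-component shape descriptors (length and width
#' from the medial axis and the distance transform, circularity
#' 4*pi*A/P^2, angularity as the mean absolute turning angle along the
#' smoothed medial axis) and keeps components that satisfy the
#' [shape_constraints()] and do not touch the image border.
#'
#' @param img A background-subtracted [micrograph()] or matrix.
#' @param constraints A [shape_constraints()] object.
#' @param pixel_size Pixel size in um/px (taken from the micrograph when
#'   available).
#' @param threshold Optional fixed threshold; default is Li's.
#' @return A list of `cell_region` objects (possibly empty), each with
#'   label, pixel indices, centroid, medial axis, length, width,
#'   circularity and angularity. The attribute `"rejects"` counts the
#'   components discarded per criterion.
#' @export
segment_cells <- function(img, constraints = shape_constraints(),
                          pixel_size = NULL, threshold = NULL) {
  px <- as_pixels(img)
  psz <- if (is.null(pixel_size)) px_size(img) else pixel_size
  if (length(unique(as.numeric(px))) < 2) {
    out <- list()
    attr(out, "rejects") <- c(blank = 1L)
    return(out)
  }
  thr <- if (is.null(threshold)) li_threshold(px) else threshold
  mask <- px > thr
  mask <- as.matrix(EBImage::fillHull(mask)) > 0
  lab <- .label8_cpp(mask)
  nlab <- max(lab)
  if (nlab == 0) {
    out <- list()
    attr(out, "rejects") <- c(none = 0L)
    return(out)
  }
  # Freeman 8-chain perimeter from the ordered contour (diagonal steps
  # count sqrt(2)); EBImage's pixel-count perimeter underestimates and
  # inflates circularity
  contours <- EBImage::ocontour(lab)
  chain_perimeter <- function(oc) {
    if (is.null(oc) || nrow(oc) < 2) return(1)
    d <- rbind(diff(oc), oc[1, ] - oc[nrow(oc), ])
    sum(sqrt(rowSums(d^2)))
  }
  rejects <- c(border = 0L, area = 0L, length = 0L, width = 0L,
               circularity = 0L, angularity = 0L, degenerate = 0L)
  nr <- nrow(px); nc <- ncol(px)
  regions <- list()
  for (l in seq_len(nlab)) {
    idx <- which(lab == l)
    rows <- (idx - 1L) %% nr + 1L
    cols <- (idx - 1L) %/% nr + 1L
    if (any(rows == 1 | rows == nr | cols == 1 | cols == nc)) {
      rejects["border"] <- rejects["border"] + 1L
      next
    }
    area <- length(idx)
    if (area < constraints$area_px[1] || area > constraints$area_px[2]) {
      rejects["area"] <- rejects["area"] + 1L
      next
    }
    r0 <- min(rows); c0 <- min(cols)
    sub <- matrix(FALSE, max(rows) - r0 + 1, max(cols) - c0 + 1)
    sub[cbind(rows - r0 + 1, cols - c0 + 1)] <- TRUE
    m <- measure_region(sub, c(r0, c0), psz, chain_perimeter(contours[[l]]))
    if (is.null(m)) {
      rejects["degenerate"] <- rejects["degenerate"] + 1L
      next
    }
    if (m$length_um < constraints$length_um[1] ||
        m$length_um > constraints$length_um[2]) {
      rejects["length"] <- rejects["length"] + 1L
      next
    }
    if (m$width_um < constraints$width_um[1] ||
        m$width_um > constraints$width_um[2]) {
      rejects["width"] <- rejects["width"] + 1L
      next
    }
    if (m$circularity < constraints$circularity[1] ||
        m$circularity > constraints$circularity[2]) {
      rejects["circularity"] <- rejects["circularity"] + 1L
      next
    }
    if (m$angularity > constraints$max_angularity) {
      rejects["angularity"] <- rejects["angularity"] + 1L
      next
    }
    regions[[length(regions) + 1]] <- structure(list(
      label = length(regions) + 1L,
      mask_idx = idx,
      centroid = c(mean(rows), mean(cols)),
      medial_axis = m$medial_axis,  # 0-based (row, col)
      area_px = area,
      length_um = m$length_um,
      width_um = m$width_um,
      circularity = m$circularity,
      angularity = m$angularity,
      image_dim = c(nr, nc),
      pixel_size = psz
    ), class = "cell_region")
  }
  attr(regions, "rejects") <- rejects
  attr(regions, "threshold") <- thr
  regions
}

#' @export
print.cell_region <- function(x, ...) {
  cat(sprintf(
    "<cell_region> #%d at (%.1f, %.1f): %d px, %.2f x %.2f um, circ %.2f, ang %.2f\n",
    x$label, x$centroid[1], x$centroid[2], x$area_px, x$length_um,
    x$width_um, x$circularity, x$angularity))
  invisible(x)
}

#' Per-cell shape table
#'
#' @param regions List of `cell_region`s from [segment_cells()].
#' @return data.frame with one row per cell.
#' @export
cells_to_table <- function(regions) {
  if (!length(regions)) {
    return(data.frame(label = integer(), centroid_row = double(),
                      centroid_col = double(), area_px = integer(),
                      length_um = double(), width_um = double(),
                      circularity = double(), angularity = double()))
  }
  data.frame(
    label = vapply(regions, `[[`, 0L, "label"),
    centroid_row = vapply(regions, function(x) x$centroid[1], 0),
    centroid_col = vapply(regions, function(x) x$centroid[2], 0),
    area_px = vapply(regions, `[[`, 0L, "area_px"),
    length_um = vapply(regions, `[[`, 0, "length_um"),
    width_um = vapply(regions, `[[`, 0, "width_um"),
    circularity = vapply(regions, `[[`, 0, "circularity"),
    angularity = vapply(regions, `[[`, 0, "angularity")
  )
}
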
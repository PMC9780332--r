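# Independent oracles and small fixture builders used across the suite.

# brute-force net charge: letter counting, independent of residue_charge()
oracle_net_charge <- function(s) {
  ch <- strsplit(s, "")[[1]]
  sum(ch %in% c("K", "R")) - sum(ch %in% c("D", "E"))
}

random_aa_seq <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

# brute-force Li cross-entropy objective and its minimisation over the
# observed gray levels (same positivity shift convention as li_threshold)
oracle_li_objective <- function(v, t) {
  rng <- diff(range(v))
  eps <- rng * 1e-6
  x <- v - min(v) + eps
  tt <- t - min(v) + eps
  lo <- x[x <= tt]
  hi <- x[x > tt]
  if (!length(lo) || !length(hi)) return(Inf)
  -sum(lo) * log(mean(lo)) - sum(hi) * log(mean(hi))
}

oracle_li_minima <- function(v, rel_tol = 1e-6) {
  cand <- sort(unique(v))
  cand <- cand[-length(cand)]
  obj <- vapply(cand, function(t) oracle_li_objective(v, t), 0.0)
  best <- min(obj)
  cand[obj <= best + abs(best) * rel_tol]
}

# brute-force non-flat grayscale opening with a ball element (double loop,
# replicate-extended borders)
oracle_ball_opening_subtract <- function(img, r) {
  nr <- nrow(img); nc <- ncol(img)
  off <- expand.grid(di = -r:r, dj = -r:r)
  keep <- off$di^2 + off$dj^2 <= r^2
  off <- off[keep, ]
  h <- sqrt(r^2 - off$di^2 - off$dj^2)
  clamp <- function(v, hi) pmin(pmax(v, 1), hi)
  er <- matrix(NA_real_, nr, nc)
  dl <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- clamp(i + off$di, nr); jj <- clamp(j + off$dj, nc)
    er[i, j] <- min(img[cbind(ii, jj)] - h)
  }
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- clamp(i - off$di, nr); jj <- clamp(j - off$dj, nc)
    dl[i, j] <- max(er[cbind(ii, jj)] + h)
  }
  out <- img - dl
  out[out < 0] <- 0
  out
}

# random bimodal 8-bit test image (background + foreground Gaussian modes,
# the histogram regime automatic thresholding is designed for)
random_bimodal_image <- function(n = 32) {
  w <- runif(1, 0.3, 0.9)
  m1 <- runif(1, 20, 80); m2 <- runif(1, 120, 220)
  s1 <- runif(1, 5, 20); s2 <- runif(1, 5, 30)
  v <- c(rnorm(round(n * n * w), m1, s1),
         rnorm(n * n - round(n * n * w), m2, s2))
  matrix(round(pmin(255, pmax(0, v))), n, n)
}

# clean-scene parameters: blur and noise off, zero background, so rendered
# intensities obey exact arithmetic
clean_scene_params <- function(...) {
  args <- list(...)
  defaults <- list(psf_sigma = 0, noise = NULL, background_intensity = 0,
                   image_shape = c(400L, 400L), n_cells = 12L, seed = 1L)
  do.call(scene_params, utils::modifyList(defaults, args))
}

# run simulate -> subtract -> segment -> call on one scene
run_scene_pipeline <- function(params, threshold = 1.20, radius = 100) {
  sc <- generate_scene(params)
  bg <- rolling_ball_subtract(sc$image, radius)
  cells <- segment_cells(bg)
  calls <- if (length(cells)) call_cells(cells, bg, threshold = threshold)
           else list()
  list(scene = sc, bg = bg, cells = cells, calls = calls)
}
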
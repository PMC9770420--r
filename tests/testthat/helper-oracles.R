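# Independent oracles and fixture builders shared across tests.

# Exhaustive 256-level Otsu: scan every candidate threshold and maximize the
# between-class variance directly from the pixel values (first maximum wins,
# i.e. the lowest threshold).
brute_force_otsu <- function(img) {
  v <- as.vector(img)
  best <- -Inf
  best_t <- NA_integer_
  for (t in 0:254) {
    g0 <- v[v <= t]
    g1 <- v[v > t]
    if (!length(g0) || !length(g1)) next
    bcv <- length(g0) * length(g1) * (mean(g0) - mean(g1))^2
    if (bcv > best) {
      best <- bcv
      best_t <- t
    }
  }
  best_t
}

# random 8-bit test images drawn from a few distribution shapes
random_8bit <- function(n = 64, kind = c("uniform", "bimodal", "skewed")) {
  kind <- match.arg(kind)
  n1 <- floor(n * n * 0.7)
  v <- switch(kind,
    uniform = sample(0:255, n * n, replace = TRUE),
    bimodal = pmin(pmax(round(c(rnorm(n1, 60, 20),
                                rnorm(n * n - n1, 190, 25))), 0), 255),
    skewed = pmin(round(rexp(n * n, 1 / 40)), 255))
  matrix(as.integer(v), n, n)
}

# axis-aligned rectangle mask (rows x cols pixels) centered in a field
rect_mask <- function(h, w, field = max(h, w) + 20) {
  m <- matrix(FALSE, field, field)
  r0 <- floor((field - h) / 2) + 1
  c0 <- floor((field - w) / 2) + 1
  m[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- TRUE
  m
}

# digitized disc mask of radius r pixels
disc_mask <- function(r, field = 2 * ceiling(r) + 21) {
  ctr <- (field + 1) / 2
  d <- outer(seq_len(field) - ctr, seq_len(field) - ctr,
             function(y, x) sqrt(y^2 + x^2))
  d <= r
}

# a small blur-free, noise-free scene whose rendering is its own footprint
# oracle
noiseless_scene <- function(..., seed) {
  scene_spec(..., background_level = 0, noise_sd = 0, psf_sigma_um = 0,
             seed = seed)
}

# count objects in a noiseless rendering by labeling pixels above background
oracle_count <- function(stack, connectivity = 8) {
  proj <- project_stack(stack, "max")
  n_particles(label_particles(proj > 0, connectivity = connectivity))
}
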
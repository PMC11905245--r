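# Independent oracles and small fixture builders shared across tests.
# Each oracle recomputes a quantity by a different route than the
# implementation (rasterization, enumeration, voxel sorting, literal
# formula transcription) so agreement is meaningful.

# --- fixture builders -------------------------------------------------

# arc from a list of (left, right) bank pairs + cumulative weights
toy_arc <- function(banks, weights = NULL, arc_mu = 100, gantry = NULL,
                    leaf_width = 5, increment = 30) {
  n <- length(banks)
  if (is.null(weights)) weights <- seq(0, 1, length.out = n)
  if (is.null(gantry)) gantry <- seq(0, 360, length.out = n)
  cps <- lapply(seq_len(n), function(i)
    control_point(gantry[i] %% 360,
                  mlc_positions(banks[[i]][[1]], banks[[i]][[2]],
                                leaf_width = leaf_width),
                  weights[i]))
  vmat_arc(cps, arc_mu = arc_mu, increment_deg = increment)
}

# seeded random 5-CP toy arc (open apertures, mild jaggedness)
random_toy_arc <- function(seed, n_cp = 5, n_pairs = 6) {
  set.seed(seed)
  banks <- lapply(seq_len(n_cp), function(i) {
    l <- runif(n_pairs, -40, -5)
    r <- runif(n_pairs, 5, 40)
    list(l, r)
  })
  w <- sort(runif(n_cp - 2))
  toy_arc(banks, weights = c(0, w, 1), arc_mu = runif(1, 100, 500))
}

# uniform-dose cube grid
uniform_grid <- function(dose = 70, n = 10, spacing = 2) {
  dose_grid(array(dose, c(n, n, n)), spacing = spacing)
}

# --- geometry oracles -------------------------------------------------

# pixel-marching perimeter/area of the union of open leaf-pair
# rectangles, on a res-mm raster: perimeter counts exposed pixel edges
raster_aperture <- function(mlc, closed_gap = 0.5, res = 0.1) {
  op <- which((mlc$right - mlc$left) > closed_gap)
  if (length(op) == 0) return(list(area = 0, perimeter = 0))
  t <- mlc$leaf_width
  x0 <- min(mlc$left[op]) - res
  x1 <- max(mlc$right[op]) + res
  nx <- round((x1 - x0) / res)
  ny <- length(mlc$left) # one band of t/res rows per leaf pair
  rows_per <- round(t / res)
  img <- matrix(FALSE, nrow = ny * rows_per, ncol = nx)
  for (p in op) {
    cols <- which((x0 + (seq_len(nx) - 0.5) * res) > mlc$left[p] &
                    (x0 + (seq_len(nx) - 0.5) * res) < mlc$right[p])
    rows <- ((p - 1) * rows_per + 1):(p * rows_per)
    img[rows, cols] <- TRUE
  }
  area <- sum(img) * res^2
  # exposed edges: 4 per pixel minus 2 per interior adjacency
  horiz <- sum(img[-1, ] & img[-nrow(img), ])
  vert <- sum(img[, -1] & img[, -ncol(img)])
  per <- (4 * sum(img) - 2 * (horiz + vert)) * res
  list(area = area, perimeter = per)
}

# --- complexity oracles: literal transcriptions of the metric table ---

oracle_lsv <- function(left, right) {
  factor_for <- function(pos) {
    n <- length(pos)
    if (n < 2) return(1)
    pos_max <- max(pos) - min(pos)
    if (pos_max == 0) return(1)
    s <- 0
    for (k in seq_len(n - 1)) s <- s + (pos_max - abs(pos[k] - pos[k + 1]))
    s / ((n - 1) * pos_max)
  }
  factor_for(left) * factor_for(right)
}

oracle_arc_mcs <- function(arc, closed_gap = 0.5) {
  cps <- arc$control_points
  n_pairs <- length(cps[[1]]$mlc$left)
  maxop <- rep(0, n_pairs)
  for (cp in cps) maxop <- pmax(maxop, cp$mlc$right - cp$mlc$left)
  inf <- maxop > closed_gap
  lsv <- aav <- numeric(length(cps))
  for (i in seq_along(cps)) {
    m <- cps[[i]]$mlc
    lsv[i] <- oracle_lsv(m$left[inf], m$right[inf])
    aav[i] <- sum((m$right - m$left)[inf]) / sum(maxop[inf])
  }
  w <- vapply(cps, function(cp) cp$cum_weight, numeric(1))
  mu <- diff(w) * arc$arc_mu
  total <- 0
  for (i in seq_along(mu)) {
    total <- total + (aav[i] + aav[i + 1]) / 2 * (lsv[i] + lsv[i + 1]) / 2 *
      mu[i] / arc$arc_mu
  }
  list(mcs = total, lsv = lsv, aav = aav)
}

oracle_beam_area <- function(arc, closed_gap = 0.5) {
  cps <- arc$control_points
  aa <- vapply(cps, function(cp) {
    op <- (cp$mlc$right - cp$mlc$left) > closed_gap
    sum(cp$mlc$leaf_width * (cp$mlc$right - cp$mlc$left)[op])
  }, numeric(1))
  w <- vapply(cps, function(cp) cp$cum_weight, numeric(1))
  mu <- diff(w) * arc$arc_mu
  s <- 0
  for (j in seq_along(mu)) s <- s + mu[j] * (aa[j] + aa[j + 1]) / 2
  s / arc$arc_mu
}

# --- statistics oracles -----------------------------------------------

# exact two-sided signed-rank p by explicit enumeration of all 2^n sign
# patterns (n <= 14 or so)
oracle_wilcoxon <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  lower <- mean(w_all <= w_obs + 1e-9)
  upper <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}

# --- DVH oracle -------------------------------------------------------

# dose covering a given volume, from the sorted raw voxel doses
oracle_d_at_volume <- function(doses, vv_cc, volume_cc) {
  k <- ceiling(volume_cc / vv_cc - 1e-9)
  sort(doses, decreasing = TRUE)[max(k, 1)]
}

oracle_v_at_dose <- function(doses, vv_cc, dose) sum(doses >= dose) * vv_cc
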
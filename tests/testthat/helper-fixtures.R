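# Shared fixtures: built in code at test time, no stored data.

# exact linear "toy" calibration curve HU = -773 + 100 x, constructed through
# the public fitting interface from noiseless points
toy_curve <- function() {
  pts <- tibble::tibble(rho_zeff = c(2, 5, 8, 12, 20, 27),
                        hu = -773 + 100 * c(2, 5, 8, 12, 20, 27))
  fit_hu_curve(pts)
}

# the 11-tissue simulated insert battery used in calibration tests
insert_battery <- function() {
  t <- icru_tissues()
  t[match(c("lung_inflated", "adipose", "water", "muscle", "liver", "cartilage",
            "thyroid", "spongiosa", "femur", "humerus", "cortical_bone"),
          t$name), ]
}

# smooth random dose plane: constant floor plus a few Gaussian bumps
smooth_plane <- function(seed, n = 20, sp = 0.2) {
  set.seed(seed)
  x <- (0:(n - 1)) * sp
  g <- expand.grid(x = x, y = x)
  v <- rep(0.15, nrow(g))
  for (k in 1:3) {
    cx <- runif(1, 1, 3); cy <- runif(1, 1, 3)
    a <- runif(1, 0.4, 0.8); s <- runif(1, 1.2, 2.0)
    v <- v + a * exp(-((g$x - cx)^2 + (g$y - cy)^2) / (2 * s^2))
  }
  dose_plane(matrix(v, n, n), c(sp, sp))
}

# a target plane close to `ref`: smooth multiplicative perturbation + shift
perturbed_target <- function(ref, seed, amp = 0.03, shift = c(0.1, -0.05)) {
  set.seed(seed)
  n <- nrow(ref$values); m <- ncol(ref$values)
  pert <- outer(seq(0, 1, length.out = n), seq(0, 1, length.out = m),
                function(a, b) amp * sin(2 * pi * (a * runif(1, 0.5, 1.5) +
                                                   b * runif(1, 0.5, 1.5) + runif(1))))
  dose_plane(ref$values * (1 + pert), ref$spacing, ref$origin + shift)
}

# independent brute-force gamma oracle: exhaustive search on a fine offset
# grid (default dta/100), one pixel at a time; shares no code with the
# implementation's coarse-search + refinement path
gamma_oracle <- function(ref, tgt, dd = 4, dta = 0.3, thr = 10,
                         radius = 3 * dta, step = dta / 100) {
  norm <- max(ref$values)
  dd_abs <- dd / 100 * norm
  mask <- ref$values >= thr / 100 * norm
  ij <- which(mask, arr.ind = TRUE)
  offs <- expand.grid(dx = seq(-radius, radius, by = step),
                      dy = seq(-radius, radius, by = step))
  offs <- offs[offs$dx^2 + offs$dy^2 <= radius^2 + 1e-12, ]
  g <- rep(NA_real_, nrow(ij))
  for (p in seq_len(nrow(ij))) {
    x <- ref$origin[1] + (ij[p, 1] - 1) * ref$spacing[1]
    y <- ref$origin[2] + (ij[p, 2] - 1) * ref$spacing[2]
    dr <- ref$values[ij[p, 1], ij[p, 2]]
    gx <- (x + offs$dx - tgt$origin[1]) / tgt$spacing[1]
    gy <- (y + offs$dy - tgt$origin[2]) / tgt$spacing[2]
    ok <- gx >= 0 & gx <= nrow(tgt$values) - 1 & gy >= 0 & gy <= ncol(tgt$values) - 1
    if (!any(ok)) next
    i0 <- pmin(floor(gx[ok]), nrow(tgt$values) - 2)
    j0 <- pmin(floor(gy[ok]), ncol(tgt$values) - 2)
    fx <- gx[ok] - i0; fy <- gy[ok] - j0
    v <- tgt$values
    dt <- v[cbind(i0 + 1, j0 + 1)] * (1 - fx) * (1 - fy) +
      v[cbind(i0 + 2, j0 + 1)] * fx * (1 - fy) +
      v[cbind(i0 + 1, j0 + 2)] * (1 - fx) * fy +
      v[cbind(i0 + 2, j0 + 2)] * fx * fy
    g[p] <- sqrt(min(((dt - dr) / dd_abs)^2 +
                       (offs$dx[ok]^2 + offs$dy[ok]^2) / dta^2))
  }
  out <- matrix(NA_real_, nrow(ref$values), ncol(ref$values))
  out[mask] <- g
  out
}

# expected database label for each ground-truth phantom label (0 stays air)
expected_labels <- function(truth, db) {
  rz <- icru_rho_zeff()
  hu <- predict_hu(db$curve, rz$rho_zeff[match(truth$legend$name, rz$name)])
  c(0L, findInterval(hu, db$tissues$hu_lo))[as.vector(truth$labels) + 1L]
}
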
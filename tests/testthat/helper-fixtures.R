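# Shared fixture builders; everything is generated in code at test time.

small_ellipsoid_spec <- function(spacing = 1, ...) {
  shape_spec(semi_axes = c(8, 6, 5), spacing = spacing, ...)
}

# Digitized ellipsoid as a plain array, independent of make_segmentation()
# (used to cross-check the generator itself).
brute_ellipsoid_mask <- function(ax, n, ctr, sp = 1) {
  idx <- expand.grid(i = 0:(n[1] - 1), j = 0:(n[2] - 1), k = 0:(n[3] - 1))
  r <- ((idx$i * sp - ctr[1]) / ax[1])^2 + ((idx$j * sp - ctr[2]) / ax[2])^2 +
       ((idx$k * sp - ctr[3]) / ax[3])^2
  array(as.integer(r <= 1), n)
}

# One-way ANOVA by explicit sums of squares (independent oracle).
brute_force_anova <- function(values, groups) {
  groups <- as.character(groups)
  grand <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(unlist(lapply(split(values, groups), function(v) (v - mean(v))^2)))
  k <- length(unique(groups)); n <- length(values)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = f, df_between = k - 1, df_error = n - k,
       p = pf(f, k - 1, n - k, lower.tail = FALSE))
}

# Total volume of the foreground voxels that touch background (6-adjacency):
# the discretization band within which mesh and voxel-count volumes may differ.
surface_voxel_layer <- function(seg) {
  a <- seg$data; d <- dim(a)
  sh <- function(by) {
    out <- array(0L, d)
    src <- dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    for (ax in 1:3) if (by[ax] > 0) {
      dst[[ax]] <- (1 + by[ax]):d[ax]; src[[ax]] <- 1:(d[ax] - by[ax])
    } else if (by[ax] < 0) {
      dst[[ax]] <- 1:(d[ax] + by[ax]); src[[ax]] <- (1 - by[ax]):d[ax]
    }
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  nmin <- a
  for (v in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1)))
    nmin <- pmin(nmin, sh(v))
  sum(a == 1L & nmin == 0L) * voxel_volume(seg)
}

random_invertible_affine <- function() {
  repeat {
    m <- diag(4)
    m[1:3, 1:3] <- matrix(rnorm(9, sd = 0.6), 3) + diag(3)
    m[1:3, 4] <- rnorm(3, sd = 10)
    if (abs(det(m[1:3, 1:3])) > 0.1) return(m)
  }
}

rigid_affine <- function(angles = c(0.3, -0.2, 0.5), shift = c(10, -5, 3)) {
  rx <- rbind(c(1, 0, 0), c(0, cos(angles[1]), -sin(angles[1])),
              c(0, sin(angles[1]), cos(angles[1])))
  ry <- rbind(c(cos(angles[2]), 0, sin(angles[2])), c(0, 1, 0),
              c(-sin(angles[2]), 0, cos(angles[2])))
  rz <- rbind(c(cos(angles[3]), -sin(angles[3]), 0),
              c(sin(angles[3]), cos(angles[3]), 0), c(0, 0, 1))
  m <- diag(4)
  m[1:3, 1:3] <- rx %*% ry %*% rz
  m[1:3, 4] <- shift
  m
}

# Minimal hand-built cohort records
toy_records <- function(pvcs, subjects, groups, scans, sides,
                        method = "toy", v_bl = 3000) {
  data.frame(subject_id = subjects, group = groups, scan = scans,
             side = sides, method = method, v_bl = v_bl,
             v_fu = v_bl * (1 + pvcs / 100), stringsAsFactors = FALSE)
}
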
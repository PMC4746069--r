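# Independent oracles and fixture builders used across the suite. The
# oracles deliberately avoid the package's SVD/vectorised code paths:
# rotations are found by 1-D numerical optimisation over the angle, and
# ANOVA sums of squares by explicit loops.

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

center_mat <- function(X) sweep(X, 2L, colMeans(X))

# Brute-force full Procrustes fit of a 2D configuration onto a target:
# optimise the residual over the rotation angle, with the least-squares
# scale computed analytically for each candidate angle.
brute_opa_distance <- function(moving, target) {
  X <- center_mat(as.matrix(moving))
  Y <- center_mat(as.matrix(target))
  obj <- function(theta) {
    XR <- X %*% rot2(theta)
    s <- sum(XR * Y) / sum(X^2)
    sum((s * XR - Y)^2)
  }
  vals <- vapply(seq(-pi, pi, length.out = 721L), obj, 0)
  t0 <- seq(-pi, pi, length.out = 721L)[which.min(vals)]
  opt <- stats::optimize(obj, c(t0 - 0.02, t0 + 0.02), tol = 1e-14)
  sqrt(max(opt$objective, 0))
}

# Rotation-only brute-force alignment (for the GPA oracle).
brute_rotate_onto <- function(X, C) {
  obj <- function(theta) sum((X %*% rot2(theta) - C)^2)
  vals <- vapply(seq(-pi, pi, length.out = 721L), obj, 0)
  t0 <- seq(-pi, pi, length.out = 721L)[which.min(vals)]
  opt <- stats::optimize(obj, c(t0 - 0.02, t0 + 0.02), tol = 1e-15)
  X %*% rot2(opt$minimum)
}

# Independent GPA: unit-size scaling, then repeated pairwise-average
# consensus updates with brute-force rotations.
brute_gpa_consensus <- function(configs, iters = 200L) {
  mats <- lapply(configs, function(m) {
    X <- center_mat(as.matrix(m))
    X / sqrt(sum(X^2))
  })
  C <- mats[[1L]]
  for (k in seq_len(iters)) {
    rotated <- lapply(mats, brute_rotate_onto, C = C)
    Cnew <- Reduce(`+`, rotated) / length(rotated)
    Cnew <- center_mat(Cnew)
    Cnew <- Cnew / sqrt(sum(Cnew^2))
    if (sqrt(mean((Cnew - C)^2)) < 1e-12) { C <- Cnew; break }
    C <- Cnew
  }
  C
}

# Explicit-loop two-way (individual x side, replicates within cells) ANOVA
# sums of squares over aligned original + mirrored observations, summing
# over every coordinate one at a time.
brute_anova_ss <- function(dec) {
  n_obs <- dim(dec$aligned)[3L]
  specimen <- dec$index$specimen
  ids <- unique(specimen)
  L <- dim(dec$aligned)[1L]; D <- dim(dec$aligned)[2L]
  ss <- c(ind = 0, side = 0, ixs = 0, err = 0)
  for (l in seq_len(L)) for (d in seq_len(D)) {
    y <- array(NA_real_, dim = c(length(ids), 2L,
                                 sum(specimen == ids[1L])))
    for (ii in seq_along(ids)) {
      reps <- which(specimen == ids[ii])
      for (jj in seq_along(reps)) {
        y[ii, 1L, jj] <- dec$aligned[l, d, reps[jj]]
        y[ii, 2L, jj] <- dec$mirrored[l, d, reps[jj]]
      }
    }
    grand <- mean(y)
    for (ii in seq_along(ids)) {
      mi <- mean(y[ii, , ])
      ss["ind"] <- ss["ind"] + dim(y)[2L] * dim(y)[3L] * (mi - grand)^2
    }
    for (ss_lvl in 1:2) {
      ms <- mean(y[, ss_lvl, ])
      ss["side"] <- ss["side"] + dim(y)[1L] * dim(y)[3L] * (ms - grand)^2
    }
    for (ii in seq_along(ids)) for (ss_lvl in 1:2) {
      cell <- mean(y[ii, ss_lvl, ])
      mi <- mean(y[ii, , ]); ms <- mean(y[, ss_lvl, ])
      ss["ixs"] <- ss["ixs"] +
        dim(y)[3L] * (cell - mi - ms + grand)^2
      ss["err"] <- ss["err"] + sum((y[ii, ss_lvl, ] - cell)^2)
    }
  }
  ss
}

# Tiny fixture: symmetric 2D template with k pairs and u medians.
tiny_template <- function(k = 2L, u = 1L) {
  px <- seq(0.5, 1, length.out = k)
  py <- seq(-0.5, 0.5, length.out = k)
  coords <- matrix(NA_real_, 2L * k + u, 2L)
  left <- seq(1L, by = 2L, length.out = k); right <- left + 1L
  coords[left, ] <- cbind(-px, py)
  coords[right, ] <- cbind(px, py)
  coords[2L * k + seq_len(u), ] <- cbind(rep(0, u),
                                         seq(0.9, 1.3, length.out = u))
  coords[, 2L] <- coords[, 2L] - mean(coords[, 2L])
  coords <- coords / sqrt(sum(coords^2))
  list(coords = coords,
       map = symmetry_map(cbind(left, right), 2L * k + seq_len(u)))
}

# Small 3D symmetric template (pairs mirrored in x, medians on x = 0).
tiny_template_3d <- function(k = 3L, u = 2L) {
  py <- seq(-0.6, 0.6, length.out = k)
  pz <- seq(0.2, -0.2, length.out = k)
  coords <- matrix(NA_real_, 2L * k + u, 3L)
  left <- seq(1L, by = 2L, length.out = k); right <- left + 1L
  coords[left, ] <- cbind(-rep(0.7, k), py, pz)
  coords[right, ] <- cbind(rep(0.7, k), py, pz)
  coords[2L * k + seq_len(u), ] <- cbind(0, seq(0.9, 1.2, length.out = u),
                                         seq(-0.3, 0.3, length.out = u))
  coords[, 2L] <- coords[, 2L] - mean(coords[, 2L])
  coords[, 3L] <- coords[, 3L] - mean(coords[, 3L])
  coords <- coords / sqrt(sum(coords^2))
  list(coords = coords,
       map = symmetry_map(cbind(left, right), 2L * k + seq_len(u)))
}

random_rotation <- function(D) {
  if (D == 2L) return(rot2(stats::runif(1, -pi, pi)))
  M <- matrix(stats::rnorm(9), 3L, 3L)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 3L] <- -Q[, 3L]
  Q
}

similarity_transform <- function(X) {
  D <- ncol(X)
  s <- exp(stats::runif(1, -1, 1))
  R <- random_rotation(D)
  tr <- stats::rnorm(D, sd = 3)
  sweep(s * X %*% R, 2L, tr, "+")
}

write_pp_fixture <- function(path, pts) {
  # pts: data.frame with name, x, y, z and optional active
  lines <- c("<!DOCTYPE PickedPoints>", "<PickedPoints>",
             " <DocumentData>", "  <DateTime date=\"2015-01-01\"/>",
             " </DocumentData>")
  for (i in seq_len(nrow(pts))) {
    act <- if (!is.null(pts$active)) sprintf(" active=\"%s\"", pts$active[i])
           else " active=\"1\""
    lines <- c(lines, sprintf(
      " <point x=\"%s\" y=\"%s\" z=\"%s\"%s name=\"%s\"/>",
      pts$x[i], pts$y[i], pts$z[i], act, pts$name[i]))
  }
  writeLines(c(lines, "</PickedPoints>"), path)
  path
}

sim_counts_df <- function(n, da, sigma, population, trait = "anterior_petals",
                          rounding = TRUE) {
  simulate_meristic(n = n, da_shift = da, sigma_fa_count = sigma,
                    rounding = rounding, population = population,
                    trait = trait)
}
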
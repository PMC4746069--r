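# Ordinary and generalized Procrustes superimposition.

coords_of <- function(x) {
  if (inherits(x, "landmark_config")) x$coords else as.matrix(x)
}

center_coords <- function(X) {
  sweep(X, 2L, colMeans(X))
}

#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of the landmarks from
#' their centroid; the size measure removed when shapes are rescaled during
#' Procrustes superimposition. Invariant under translation and rotation and
#' homogeneous of degree one under scaling.
#'
#' @param config A [landmark_config()] or coordinate matrix.
#' @return Positive scalar centroid size.
#' @examples
#' centroid_size(rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) # sqrt(8)
#' @export
centroid_size <- function(config) {
  X <- center_coords(coords_of(config))
  cs <- sqrt(sum(X^2))
  if (cs <= .Machine$double.eps * nrow(X))
    stop("degenerate configuration: all landmarks coincide")
  cs
}

# Rotation (optionally allowing reflection) that best aligns X onto target C:
# argmin over R of ||C - X R||, solved by SVD of crossprod(X, C) with a
# determinant correction to stay in SO(D).
optimal_rotation <- function(X, C, allow_reflection = FALSE) {
  H <- crossprod(X, C)
  sv <- svd(H)
  R <- sv$u %*% t(sv$v)
  if (!allow_reflection && det(R) < 0) {
    u <- sv$u
    u[, ncol(u)] <- -u[, ncol(u)]
    R <- u %*% t(sv$v)
  }
  R
}

#' Ordinary Procrustes alignment of one configuration onto another
#'
#' Least-squares superimposition of `moving` onto `target` by translation,
#' scaling and rotation (full Procrustes fit). The rotation is constrained
#' to be proper (determinant +1) unless `allow_reflection = TRUE`.
#'
#' @param moving,target Congruent configurations (matrices or
#'   [landmark_config()]).
#' @param allow_reflection Permit improper rotations.
#' @param scale Estimate the least-squares scale factor (default) or keep
#'   the moving configuration's size.
#' @return List with `aligned` (the transformed moving configuration, in the
#'   target's frame), `distance` (root summed squared landmark deviations
#'   after the fit), `rotation`, `scale` and `translation`.
#' @export
opa_align <- function(moving, target, allow_reflection = FALSE, scale = TRUE) {
  X <- coords_of(moving); Y <- coords_of(target)
  if (!all(dim(X) == dim(Y)))
    stop("configurations are not congruent: ", nrow(X), "x", ncol(X),
         " vs ", nrow(Y), "x", ncol(Y))
  cy <- colMeans(Y)
  Xc <- center_coords(X); Yc <- center_coords(Y)
  if (sqrt(sum(Xc^2)) <= .Machine$double.eps * nrow(Xc) ||
      qr(Xc)$rank < 1L)
    stop("degenerate moving configuration: alignment is undefined")
  R <- optimal_rotation(Xc, Yc, allow_reflection)
  XR <- Xc %*% R
  s <- if (scale) sum(XR * Yc) / sum(Xc^2) else 1
  aligned <- s * XR
  d2 <- sum((aligned - Yc)^2)
  aligned <- sweep(aligned, 2L, cy, "+")
  list(aligned = aligned,
       distance = sqrt(max(d2, 0)),
       rotation = R,
       scale = s,
       translation = cy - s * colMeans(X %*% R))
}

#' Procrustes distance between two configurations
#'
#' Full Procrustes distance after rescaling both shapes to unit centroid
#' size: symmetric in its arguments and zero iff the shapes are equal up to
#' a similarity transform.
#'
#' @inheritParams opa_align
#' @return Non-negative scalar.
#' @export
procrustes_distance <- function(moving, target, allow_reflection = FALSE) {
  X <- center_coords(coords_of(moving))
  Y <- center_coords(coords_of(target))
  X <- X / sqrt(sum(X^2))
  Y <- Y / sqrt(sum(Y^2))
  R <- optimal_rotation(X, Y, allow_reflection)
  XR <- X %*% R
  s <- sum(XR * Y)              # optimal scale for unit-size shapes
  # residual norm computed elementwise (stable near zero, where the
  # closed form sqrt(1 - s^2) loses half the significant digits)
  sqrt(sum((s * XR - Y)^2))
}

# One pass: rotate every (already centered, unit-size) configuration in the
# L x D x N array onto consensus C. Returns the rotated array.
rotate_all_onto <- function(arr, C, allow_reflection = FALSE) {
  N <- dim(arr)[3L]
  D <- dim(arr)[2L]
  if (D == 2L && !allow_reflection) {
    # analytic 2D rotation, vectorised across configurations
    Xx <- arr[, 1L, , drop = FALSE]; Xy <- arr[, 2L, , drop = FALSE]
    dim(Xx) <- dim(Xy) <- c(dim(arr)[1L], N)
    h11 <- colSums(Xx * C[, 1L]); h12 <- colSums(Xx * C[, 2L])
    h21 <- colSums(Xy * C[, 1L]); h22 <- colSums(Xy * C[, 2L])
    theta <- atan2(h12 - h21, h11 + h22)
    ct <- cos(theta); st <- sin(theta)
    # R = [[ct, st], [-st, ct]] maximises tr(R' H)
    out <- arr
    out[, 1L, ] <- sweep(Xx, 2L, ct, "*") - sweep(Xy, 2L, st, "*")
    out[, 2L, ] <- sweep(Xx, 2L, st, "*") + sweep(Xy, 2L, ct, "*")
    return(out)
  }
  out <- arr
  for (i in seq_len(N)) {
    R <- optimal_rotation(arr[, , i], C, allow_reflection)
    out[, , i] <- arr[, , i] %*% R
  }
  out
}

#' Generalized Procrustes analysis
#'
#' Iterative superimposition of two or more congruent configurations: every
#' configuration is centred and rescaled to unit centroid size, rotated onto
#' the running consensus, and the consensus (itself rescaled to unit centroid
#' size) is recomputed until its root-mean-square change falls below `tol`.
#' The orientation of the solution is anchored to the first configuration,
#' which makes the output deterministic.
#'
#' @param sample A [study_sample()], list of [landmark_config()] objects, or
#'   `L x D x N` array.
#' @param allow_reflection Permit improper rotations during alignment.
#' @param tol Convergence tolerance on the RMS consensus change.
#' @param max_iter Maximum number of iterations.
#' @param consensus_init Optional `L x D` matrix used as the initial
#'   consensus (it is centred and rescaled internally); defaults to the
#'   first configuration.
#' @return An object of class `"gpa_fit"`: `coords` (`L x D x N` aligned,
#'   unit-centroid-size coordinates), `centroid_sizes`, `consensus`,
#'   `iterations`, `converged`, and the observation `index` when the input
#'   was a study sample.
#' @export
gpa_align <- function(sample, allow_reflection = FALSE, tol = 1e-10,
                      max_iter = 100L, consensus_init = NULL) {
  idx <- NULL
  if (inherits(sample, "study_sample")) {
    sa <- sample_array(sample)
    arr <- sa$coords; idx <- sa$index
  } else if (is.list(sample)) {
    mats <- lapply(sample, coords_of)
    arr <- array(unlist(mats), dim = c(nrow(mats[[1L]]), ncol(mats[[1L]]),
                                       length(mats)))
    idx <- data.frame(
      specimen = vapply(seq_along(sample), function(i) {
        if (inherits(sample[[i]], "landmark_config"))
          sample[[i]]$specimen_id else paste0("obs", i)
      }, ""),
      replicate = vapply(seq_along(sample), function(i) {
        if (inherits(sample[[i]], "landmark_config"))
          sample[[i]]$replicate else 1L
      }, 1L), stringsAsFactors = FALSE)
  } else {
    arr <- sample
  }
  N <- dim(arr)[3L]
  if (N < 2L) stop("GPA needs at least 2 configurations")
  cs <- numeric(N)
  for (i in seq_len(N)) {
    Xc <- center_coords(arr[, , i])
    cs[i] <- sqrt(sum(Xc^2))
    if (cs[i] <= .Machine$double.eps * nrow(Xc))
      stop("degenerate configuration at position ", i)
    arr[, , i] <- Xc / cs[i]
  }
  C <- if (is.null(consensus_init)) arr[, , 1L] else {
    Ci <- center_coords(as.matrix(consensus_init))
    Ci / sqrt(sum(Ci^2))
  }
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    arr <- rotate_all_onto(arr, C, allow_reflection)
    Cnew <- apply(arr, c(1L, 2L), mean)
    Cnew <- center_coords(Cnew)
    Cnew <- Cnew / sqrt(sum(Cnew^2))
    delta <- sqrt(mean((Cnew - C)^2))
    C <- Cnew
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("GPA did not converge in ", max_iter,
         " iterations (last RMS consensus change ",
         format(delta, digits = 3), ")")
  structure(list(coords = arr, centroid_sizes = cs, consensus = C,
                 iterations = it, converged = converged, index = idx),
            class = "gpa_fit")
}

#' @export
print.gpa_fit <- function(x, ...) {
  d <- dim(x$coords)
  cat("Generalized Procrustes fit: ", d[3L], " configurations, ",
      d[1L], " landmarks in ", d[2L], "D\n", sep = "")
  cat("  converged in ", x$iterations, " iteration(s)\n", sep = "")
  cat("  centroid size range: ",
      paste(format(range(x$centroid_sizes), digits = 5), collapse = " - "),
      "\n", sep = "")
  invisible(x)
}
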
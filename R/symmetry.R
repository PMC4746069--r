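# Object-symmetry machinery: reflection with relabelling, joint
# superimposition of originals and mirrored copies, and decomposition of
# every observation into symmetric and asymmetric shape components.

#' Reflect a configuration and relabel its paired landmarks
#'
#' Mirrors the coordinates across the coordinate plane orthogonal to the
#' first axis (x is negated) and swaps the labels within every left/right
#' landmark pair; median landmarks keep their rows. This is the standard
#' construction for analysing object symmetry: a perfectly symmetric shape is
#' superimposable on its reflected-relabelled copy, and applying the
#' operation twice returns the input exactly.
#'
#' @param config Configuration matrix, [landmark_config()], or `L x D x N`
#'   array (applied observation-wise).
#' @param map A validated [symmetry_map()].
#' @return Object of the same form as `config`.
#' @export
reflect_relabel <- function(config, map) {
  if (is.array(config) && length(dim(config)) == 3L) {
    out <- config
    out[, 1L, ] <- -out[, 1L, ]
    perm <- seq_len(dim(config)[1L])
    perm[map$pairs[, 1L]] <- map$pairs[, 2L]
    perm[map$pairs[, 2L]] <- map$pairs[, 1L]
    return(out[perm, , , drop = FALSE])
  }
  X <- coords_of(config)
  map <- validate_symmetry_map(map, nrow(X))
  X[, 1L] <- -X[, 1L]
  perm <- seq_len(nrow(X))
  perm[map$pairs[, 1L]] <- map$pairs[, 2L]
  perm[map$pairs[, 2L]] <- map$pairs[, 1L]
  out <- X[perm, , drop = FALSE]
  rownames(out) <- rownames(X)[seq_len(nrow(X))]
  if (inherits(config, "landmark_config")) {
    config$coords <- out
    return(config)
  }
  out
}

#' Dimensions of the symmetric and asymmetric shape subspaces
#'
#' For a landmark set with `k` pairs and `u` median landmarks under object
#' symmetry, the Procrustes tangent space splits into a symmetric and an
#' asymmetric component of dimensions: in 2D, `s = a = 2k + u - 2`; in 3D,
#' `s = 3k + 2u - 4` and `a = 3k + u - 3`.
#'
#' @param k Number of landmark pairs.
#' @param u Number of median landmarks.
#' @param D Coordinate dimension (2 or 3).
#' @return Named vector `c(s = ..., a = ...)`.
#' @export
symmetry_dims <- function(k, u, D) {
  if (D == 2L) c(s = 2L * k + u - 2L, a = 2L * k + u - 2L)
  else if (D == 3L) c(s = 3L * k + 2L * u - 4L, a = 3L * k + u - 3L)
  else stop("D must be 2 or 3")
}

# Rotate a near-symmetric shape S so that its symmetry plane becomes the
# coordinate plane x = 0 (the plane reflect_relabel mirrors across).
# The best-fitting reflection G (orthogonal, det -1) mapping the
# row-permuted shape onto S is found by SVD; its -1 eigenvector is the
# plane normal, which is rotated onto the first coordinate axis.
canonical_symmetric_orientation <- function(S, map) {
  D <- ncol(S)
  perm <- seq_len(nrow(S))
  perm[map$pairs[, 1L]] <- map$pairs[, 2L]
  perm[map$pairs[, 2L]] <- map$pairs[, 1L]
  PS <- S[perm, , drop = FALSE]
  B <- crossprod(PS, S)
  sv <- svd(B)
  G <- sv$u %*% t(sv$v)
  if (det(G) > 0) {
    u <- sv$u
    u[, D] <- -u[, D]
    G <- u %*% t(sv$v)
  }
  ev <- eigen(G)
  i <- which.min(Re(ev$values))
  v <- Re(ev$vectors[, i])
  v <- v / sqrt(sum(v^2))
  if (v[which.max(abs(v))] < 0) v <- -v
  if (D == 2L) {
    R <- cbind(v, c(-v[2L], v[1L]))
  } else {
    w <- diag(3L)[, which.min(abs(v))]
    u2 <- w - sum(w * v) * v
    u2 <- u2 / sqrt(sum(u2^2))
    u3 <- c(v[2L] * u2[3L] - v[3L] * u2[2L],
            v[3L] * u2[1L] - v[1L] * u2[3L],
            v[1L] * u2[2L] - v[2L] * u2[1L])
    R <- cbind(v, u2, u3)
  }
  S %*% R
}

#' Decompose a sample into symmetric and asymmetric shape components
#'
#' For structures with object symmetry the analysis superimposes each
#' original configuration together with its reflected-relabelled copy in one
#' joint generalized Procrustes fit (proper rotations only). Each
#' observation's symmetric component is the average of its aligned original
#' and aligned mirror copy, the asymmetric component is half their
#' difference, so symmetric + asymmetric reconstructs the aligned original.
#' The consensus of the joint fit is perfectly symmetric.
#'
#' @param sample A [study_sample()] (or list of congruent
#'   [landmark_config()] objects) with at least 2 specimens.
#' @param map A [symmetry_map()], validated against the landmark count.
#' @param tol,max_iter GPA convergence controls, see [gpa_align()].
#' @return Object of class `"symmetry_decomposition"` with `L x D x N`
#'   arrays `aligned` (originals), `mirrored` (aligned reflected copies),
#'   `symmetric` and `asymmetric`; the symmetric `consensus`; subspace
#'   `dims` `c(s, a)`; the observation `index`; `centroid_sizes`; and the
#'   validated `map`.
#' @export
symmetry_decompose <- function(sample, map, tol = 1e-10, max_iter = 100L) {
  if (!inherits(sample, "study_sample") && is.list(sample))
    sample <- study_sample(sample)
  stopifnot(inherits(sample, "study_sample"))
  map <- validate_symmetry_map(map, sample$L)
  if (sample$n < 2L) stop("symmetry decomposition needs at least 2 specimens")
  sa <- sample_array(sample)
  arr <- sa$coords
  N <- dim(arr)[3L]
  mirrored <- reflect_relabel(arr, map)
  joint <- array(c(arr, mirrored), dim = c(sample$L, sample$D, 2L * N))

  # symmetric, canonically oriented initial consensus from observation 1
  X1 <- center_coords(arr[, , 1L])
  X1 <- X1 / sqrt(sum(X1^2))
  M1 <- center_coords(mirrored[, , 1L])
  M1 <- M1 / sqrt(sum(M1^2))
  S0 <- (X1 + opa_align(M1, X1, scale = FALSE)$aligned) / 2
  S0 <- canonical_symmetric_orientation(S0, map)
  C0 <- (S0 + reflect_relabel(S0, map)) / 2
  if (sqrt(sum(center_coords(C0)^2)) < 1e-6)
    stop("symmetrised initial consensus is degenerate; check the symmetry map")

  fit <- gpa_align(joint, allow_reflection = FALSE, tol = tol,
                   max_iter = max_iter, consensus_init = C0)
  aligned <- fit$coords[, , seq_len(N), drop = FALSE]
  mir_aligned <- fit$coords[, , N + seq_len(N), drop = FALSE]
  consensus <- (fit$consensus + reflect_relabel(fit$consensus, map)) / 2
  sym <- (aligned + mir_aligned) / 2
  asym <- (aligned - mir_aligned) / 2
  dims <- symmetry_dims(attr(map, "k"), attr(map, "u"), sample$D)
  structure(list(aligned = aligned, mirrored = mir_aligned,
                 symmetric = sym, asymmetric = asym,
                 consensus = consensus, dims = dims,
                 index = sa$index, map = map,
                 centroid_sizes = fit$centroid_sizes[seq_len(N)],
                 population = sample$population,
                 n = sample$n, r = sample$r,
                 gpa_iterations = fit$iterations),
            class = "symmetry_decomposition")
}

#' @export
print.symmetry_decomposition <- function(x, ...) {
  d <- dim(x$aligned)
  cat("Symmetry decomposition ('", x$population, "'): ", x$n,
      " specimens x ", x$r, " replicates, ", d[1L], " landmarks in ",
      d[2L], "D\n", sep = "")
  cat("  ", nrow(x$map$pairs), " landmark pairs, ", length(x$map$medians),
      " medians; subspace dims s = ", x$dims[["s"]], ", a = ",
      x$dims[["a"]], "\n", sep = "")
  rms_asym <- sqrt(mean(apply(x$asymmetric, 3L, function(m) sum(m^2))))
  cat("  RMS asymmetric magnitude per observation: ",
      format(rms_asym, digits = 4), "\n", sep = "")
  invisible(x)
}

# flatten an L x D x N array to N x (L*D)
flatten_obs <- function(arr) {
  d <- dim(arr)
  t(matrix(arr, nrow = d[1L] * d[2L], ncol = d[3L]))
}

# per-specimen replicate means of an N x p matrix, rows grouped by index$specimen
specimen_means <- function(M, specimen) {
  g <- factor(specimen, levels = unique(specimen))
  out <- rowsum(M, g) / as.vector(table(g))
  rownames(out) <- levels(g)
  out
}

#' Per-specimen fluctuating-asymmetry scores
#'
#' A scalar asymmetry magnitude per specimen: the Procrustes (Euclidean)
#' norm of the specimen's replicate-averaged asymmetric component, after
#' subtracting the sample mean asymmetry (the directional-asymmetry
#' estimate) when `correct_da = TRUE`. These are the scores compared across
#' populations with Levene's test.
#'
#' @param dec A [symmetry_decompose()] result.
#' @param correct_da Centre the asymmetric components on the sample mean so
#'   that directional asymmetry does not inflate the scores.
#' @return Named non-negative numeric vector, one score per specimen.
#' @export
individual_fa_scores <- function(dec, correct_da = TRUE) {
  stopifnot(inherits(dec, "symmetry_decomposition"))
  A <- flatten_obs(dec$asymmetric)
  Abar <- specimen_means(A, dec$index$specimen)
  if (correct_da)
    Abar <- sweep(Abar, 2L, colMeans(Abar))
  scores <- sqrt(rowSums(Abar^2))
  names(scores) <- rownames(Abar)
  scores
}
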
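# PCA of Procrustes shape coordinates and of symmetric/asymmetric
# components.

#' Principal component analysis of shape coordinates
#'
#' Covariance-matrix PCA of flattened Procrustes coordinates (the standard
#' choice in geometric morphometrics, where all variables share units).
#' Accepts a GPA fit, a symmetry decomposition (choose the `component`), or
#' a plain observation-by-variable matrix. Replicates are averaged per
#' specimen before the decomposition, so scores are at specimen level.
#' Loading signs are fixed deterministically: within each PC the
#' largest-magnitude loading is positive.
#'
#' @param x A [gpa_align()] fit, [symmetry_decompose()] result, or numeric
#'   matrix (`N x p`).
#' @param component For a symmetry decomposition: `"symmetric"`,
#'   `"asymmetric"` or `"aligned"`.
#' @param center Centre the data (almost always `TRUE`).
#' @return Object of class `"shape_pca"`: `values` (eigenvalues, i.e.
#'   per-PC variances), `variance_fraction`, `scores` (`N x m`), `loadings`
#'   (`p x m`), `mean_shape` (`L x D` when shape dimensions are known),
#'   `center`, and the shape `dim`.
#' @export
shape_pca <- function(x, component = c("symmetric", "asymmetric", "aligned"),
                      center = TRUE) {
  component <- match.arg(component)
  shape_dim <- NULL
  ids <- NULL
  if (inherits(x, "gpa_fit")) {
    shape_dim <- dim(x$coords)[1:2]
    M <- flatten_obs(x$coords)
    if (!is.null(x$index)) {
      M <- specimen_means(M, x$index$specimen)
      ids <- rownames(M)
    }
  } else if (inherits(x, "symmetry_decomposition")) {
    arr <- switch(component, symmetric = x$symmetric,
                  asymmetric = x$asymmetric, aligned = x$aligned)
    shape_dim <- dim(arr)[1:2]
    M <- specimen_means(flatten_obs(arr), x$index$specimen)
    ids <- rownames(M)
  } else {
    M <- as.matrix(x)
    ids <- rownames(M)
  }
  if (nrow(M) < 3L)
    stop("PCA needs at least 3 observations, got ", nrow(M))
  pc <- stats::prcomp(M, center = center, scale. = FALSE)
  m <- min(nrow(M) - 1L, ncol(M))
  values <- pc$sdev[seq_len(m)]^2
  # drop numerically null components: their directions are an arbitrary
  # basis of the data's null space, not part of the variation
  m <- max(1L, sum(values > max(values) * 1e-12))
  values <- values[seq_len(m)]
  loadings <- pc$rotation[, seq_len(m), drop = FALSE]
  scores <- pc$x[, seq_len(m), drop = FALSE]
  flip <- vapply(seq_len(m), function(j) {
    lj <- loadings[, j]
    sign(lj[which.max(abs(lj))])
  }, 1)
  flip[flip == 0] <- 1
  loadings <- sweep(loadings, 2L, flip, "*")
  scores <- sweep(scores, 2L, flip, "*")
  rownames(scores) <- ids
  total <- sum(values)
  vf <- if (total > 0) values / total else rep(0, m)
  mean_shape <- if (!is.null(shape_dim))
    matrix(if (isTRUE(center)) pc$center else colMeans(M),
           nrow = shape_dim[1L], ncol = shape_dim[2L])
  else NULL
  structure(list(values = values, variance_fraction = vf,
                 scores = scores, loadings = loadings,
                 mean_shape = mean_shape,
                 center = if (isTRUE(center)) pc$center else rep(0, ncol(M)),
                 dim = shape_dim, component = component),
            class = "shape_pca")
}

#' Cumulative variance explained by leading components
#'
#' @param result A [shape_pca()] object.
#' @param first_m Number of leading PCs to sum over.
#' @return Fraction of total variance in the first `first_m` PCs.
#' @export
variance_explained <- function(result, first_m) {
  stopifnot(inherits(result, "shape_pca"))
  m <- length(result$values)
  if (first_m < 1L || first_m > m)
    stop("first_m must be between 1 and the rank (", m, ")")
  sum(result$variance_fraction[seq_len(first_m)])
}

#' @export
print.shape_pca <- function(x, ...) {
  m <- length(x$values)
  cat("Shape PCA (", x$component, " component): ", nrow(x$scores),
      " observations, ", m, " components\n", sep = "")
  k <- min(m, 6L)
  pct <- formatC(100 * x$variance_fraction[seq_len(k)], format = "f",
                 digits = 2)
  cat("  variance explained: ",
      paste0("PC", seq_len(k), " ", pct, "%", collapse = ", "),
      if (m > k) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
summary.shape_pca <- function(object, ...) {
  data.frame(PC = seq_along(object$values),
             eigenvalue = object$values,
             proportion = object$variance_fraction,
             cumulative = cumsum(object$variance_fraction))
}

#' @export
plot.shape_pca <- function(x, axes = c(1, 2), groups = NULL, ...) {
  i <- axes[1L]; j <- axes[2L]
  col <- if (is.null(groups)) "black"
         else as.integer(factor(groups)) + 1L
  graphics::plot(x$scores[, i], x$scores[, j], col = col,
                 xlab = sprintf("PC%d (%.2f%%)", i,
                                100 * x$variance_fraction[i]),
                 ylab = sprintf("PC%d (%.2f%%)", j,
                                100 * x$variance_fraction[j]),
                 pch = 19, ...)
  graphics::abline(h = 0, v = 0, col = "grey70", lty = 2)
  if (!is.null(groups))
    graphics::legend("topright", legend = levels(factor(groups)),
                     col = seq_len(nlevels(factor(groups))) + 1L, pch = 19,
                     bty = "n")
  invisible(x)
}

#' Export PCA results as CSV files
#'
#' @param x A [shape_pca()] object.
#' @param prefix Path prefix; writes `<prefix>_scores.csv`,
#'   `<prefix>_loadings.csv` and `<prefix>_eigenvalues.csv`.
#' @return `prefix`, invisibly.
#' @export
write_pca <- function(x, prefix) {
  utils::write.csv(data.frame(specimen = rownames(x$scores) %||%
                                seq_len(nrow(x$scores)), x$scores),
                   paste0(prefix, "_scores.csv"), row.names = FALSE)
  utils::write.csv(x$loadings, paste0(prefix, "_loadings.csv"))
  utils::write.csv(summary.shape_pca(x),
                   paste0(prefix, "_eigenvalues.csv"), row.names = FALSE)
  invisible(prefix)
}
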
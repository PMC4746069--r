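# Synthetic landmark and meristic data with known ground-truth variance
# components, mirroring the generative model the Procrustes ANOVA assumes:
# random symmetric individual variation, a fixed directional-asymmetry
# displacement, individual-level random side deviations (FA) and
# replicate-level digitizing noise.

#' Built-in symmetric landmark template: echinoid oral surface
#'
#' A schematic 21-landmark, 2D template of the oral side of a spatangoid
#' echinoid test (9 paired landmarks on the paired petals and periplastronal
#' plates, 3 median landmarks on the peristome, labrum and posterior
#' plastron). The template is exactly symmetric about the plane x = 0 (the
#' mirror plane [reflect_relabel()] uses), centred, and scaled to unit
#' centroid size so simulation noise levels are in units of centroid size.
#'
#' @return List with `coords` (21 x 2 matrix) and `map` (a
#'   [symmetry_map()]: 9 pairs, 3 medians).
#' @export
echinoid_oral_template <- function() {
  pairs_xy <- rbind(
    c(0.50, 0.85),   # anterior petal tip
    c(0.55, 0.55),   # anterior petal base
    c(0.75, 0.25),   # posterior petal tip
    c(0.65, -0.10),  # posterior petal base
    c(0.45, -0.40),  # periplastronal plate, anterior suture
    c(0.30, -0.70),  # periplastronal plate, posterior suture
    c(0.25, 0.30),   # ambulacrum II/IV pore row
    c(0.35, 0.00),   # plastron lateral suture
    c(0.20, -0.25))  # periplastronal midpoint
  med_xy <- rbind(
    c(0, 0.80),      # peristome anterior margin
    c(0, 0.45),      # labrum tip
    c(0, -0.90))     # plastron posterior end
  k <- nrow(pairs_xy)
  coords <- matrix(NA_real_, nrow = 2L * k + nrow(med_xy), ncol = 2L)
  left <- seq(1L, by = 2L, length.out = k)
  right <- left + 1L
  coords[left, ] <- cbind(-pairs_xy[, 1L], pairs_xy[, 2L])
  coords[right, ] <- pairs_xy
  med <- 2L * k + seq_len(nrow(med_xy))
  coords[med, ] <- med_xy
  coords[, 2L] <- coords[, 2L] - mean(coords[, 2L])
  coords <- coords / sqrt(sum(coords^2))
  rownames(coords) <- c(rbind(paste0("p", seq_len(k), "L"),
                              paste0("p", seq_len(k), "R")),
                        c("peristome", "labrum", "plastron"))
  list(coords = coords,
       map = symmetry_map(pairs = cbind(left, right), medians = med))
}

#' Symmetric and antisymmetric parts of a configuration or displacement
#'
#' Orthogonal projections under the reflection-relabelling operator: the
#' symmetric part is the average of `X` with its reflected-relabelled copy,
#' the antisymmetric part is half the difference. They sum to `X` exactly.
#'
#' @param X `L x D` matrix (a configuration or a displacement field).
#' @param map A [symmetry_map()].
#' @return `L x D` matrix.
#' @export
sym_part <- function(X, map) (X + reflect_relabel(X, map)) / 2

#' @rdname sym_part
#' @export
asym_part <- function(X, map) (X - reflect_relabel(X, map)) / 2

# similarity directions (translations and infinitesimal rotations) at a
# configuration, as columns of a flattened orthonormal basis
similarity_directions <- function(template) {
  L <- nrow(template); D <- ncol(template)
  Tc <- sweep(template, 2L, colMeans(template))
  dirs <- lapply(seq_len(D), function(d) {
    m <- matrix(0, L, D); m[, d] <- 1; c(m)
  })
  if (D == 2L) {
    dirs <- c(dirs, list(c(cbind(-Tc[, 2L], Tc[, 1L]))))
  } else {
    gens <- list(cbind(0, -Tc[, 3L], Tc[, 2L]),
                 cbind(Tc[, 3L], 0, -Tc[, 1L]),
                 cbind(-Tc[, 2L], Tc[, 1L], 0))
    dirs <- c(dirs, lapply(gens, c))
  }
  qr.Q(qr(do.call(cbind, dirs)))
}

# default unit-norm antisymmetric displacement direction: a shift of the
# first landmark pair along the second axis, opposite on the two sides,
# projected into shape space proper (orthogonal to the translation and
# rotation directions that Procrustes alignment removes)
default_da_direction <- function(template, map) {
  e <- matrix(0, nrow(template), ncol(template))
  e[map$pairs[1L, 1L], 2L] <- 1
  d <- asym_part(e, map)
  Q <- similarity_directions(template)
  v <- c(d) - Q %*% crossprod(Q, c(d))
  d <- asym_part(matrix(v, nrow(template), ncol(template)), map)
  d / sqrt(sum(d^2))
}

#' Simulate a replicated landmark sample with known variance components
#'
#' Each observation is built as
#' `template + sym(individual) + asym(DA + FA_individual) + noise(replicate)`:
#' per-individual symmetric deviations (isotropic Gaussian, symmetrized), a
#' fixed antisymmetric directional-asymmetry displacement, per-individual
#' antisymmetric FA deviations, and unstructured per-replicate digitizing
#' noise. All standard deviations are per raw coordinate, in units of the
#' template's centroid size. The realised ground truth (including the
#' antisymmetric DA component) is attached as attribute `"truth"`.
#'
#' @param n_individuals Number of specimens.
#' @param replicates Digitization replicates per specimen.
#' @param sigma_individual SD of symmetric individual variation.
#' @param sigma_fa SD of antisymmetric individual (FA) variation.
#' @param sigma_me SD of replicate digitizing noise.
#' @param da_magnitude Procrustes norm of the injected directional-asymmetry
#'   displacement (applied along a fixed antisymmetric direction).
#' @param da_vector Optional `L x D` raw displacement; its antisymmetric
#'   part is used and `da_magnitude` is ignored.
#' @param template `L x D` exactly symmetric base shape; defaults to
#'   [echinoid_oral_template()].
#' @param map [symmetry_map()] for the template.
#' @param population Population label for the sample.
#' @param seed Optional integer seed; identical parameters and seed give an
#'   identical sample.
#' @return A [study_sample()] with attribute `"truth"` (list of the sigmas
#'   and the realised antisymmetric `da` matrix).
#' @export
simulate_landmarks <- function(n_individuals = 33L, replicates = 2L,
                               sigma_individual = 0.03, sigma_fa = 0.01,
                               sigma_me = 0.003, da_magnitude = 0,
                               da_vector = NULL, template = NULL, map = NULL,
                               population = "simulated", seed = NULL) {
  if (is.null(template) || is.null(map)) {
    tpl <- echinoid_oral_template()
    if (is.null(template)) template <- tpl$coords
    if (is.null(map)) map <- tpl$map
  }
  template <- as.matrix(template)
  map <- validate_symmetry_map(map, nrow(template))
  if (max(abs(reflect_relabel(template, map) - template)) > 1e-9)
    stop("template is not symmetric under reflect_relabel; ",
         "simulation requires an exactly symmetric template")
  if (any(c(sigma_individual, sigma_fa, sigma_me) < 0))
    stop("all sigmas must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  L <- nrow(template); D <- ncol(template)
  da <- if (!is.null(da_vector)) asym_part(as.matrix(da_vector), map)
        else if (da_magnitude > 0)
          da_magnitude * default_da_direction(template, map)
        else matrix(0, L, D)
  configs <- vector("list", n_individuals * replicates)
  idx <- 1L
  for (i in seq_len(n_individuals)) {
    symd <- sym_part(matrix(stats::rnorm(L * D, sd = sigma_individual),
                            L, D), map)
    fad <- asym_part(matrix(stats::rnorm(L * D, sd = sigma_fa), L, D), map)
    base_i <- template + symd + fad + da
    for (j in seq_len(replicates)) {
      noise <- if (sigma_me > 0)
        matrix(stats::rnorm(L * D, sd = sigma_me), L, D)
      else matrix(0, L, D)
      configs[[idx]] <- landmark_config(
        base_i + noise, sprintf("sim%03d", i), j,
        landmark_names = rownames(template))
      idx <- idx + 1L
    }
  }
  out <- study_sample(configs, population = population,
                      replicates = replicates)
  attr(out, "truth") <- list(sigma_individual = sigma_individual,
                             sigma_fa = sigma_fa, sigma_me = sigma_me,
                             da = da, map = map, template = template)
  out
}

#' Simulate bilateral pore-pair counts with allometry, DA and FA
#'
#' Sizes (test lengths) are drawn uniformly over `size_range`; the expected
#' specimen mean count follows `base_count + allometry_slope * size` (or a
#' log-linear law); the side difference `R - L` is `da_shift` plus Gaussian
#' FA noise, split half to each side. Counts are optionally rounded to
#' integers (rounding attenuates small FA, which is why it can be turned
#' off for calibration studies).
#'
#' @param n Number of specimens.
#' @param base_count Intercept of the count-size relation.
#' @param allometry_slope Slope of mean count on size.
#' @param size_range Length-2 range of test lengths (mm).
#' @param da_shift Mean of `R - L` (directional asymmetry).
#' @param sigma_fa_count SD of `R - L` (fluctuating asymmetry).
#' @param sigma_residual SD of specimen-level scatter of the mean count
#'   about the allometric line (biological residual variation; affects both
#'   sides equally, so it moves `(R + L) / 2` but not `R - L`).
#' @param rounding Round counts to integers.
#' @param log_linear Use `exp(base + slope * log(size))` for the mean count.
#' @param population,trait Labels for the records.
#' @param seed Optional integer seed.
#' @return A [meristic_records()] data frame.
#' @export
simulate_meristic <- function(n = 35L, base_count = 10, allometry_slope = 0.9,
                              size_range = c(25, 60), da_shift = 0,
                              sigma_fa_count = 2, sigma_residual = 2,
                              rounding = TRUE,
                              log_linear = FALSE, population = "simulated",
                              trait = "anterior_petals", seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  size <- stats::runif(n, size_range[1L], size_range[2L])
  mu <- if (log_linear) exp(base_count + allometry_slope * log(size))
        else base_count + allometry_slope * size
  if (min(mu) - abs(da_shift) / 2 < 0)
    stop("parameters produce negative expected counts ",
         "(min expected side count ",
         format(min(mu) - abs(da_shift) / 2, digits = 3), ")")
  mu <- mu + stats::rnorm(n, sd = sigma_residual)
  mu <- pmax(mu, 0)
  d <- da_shift + stats::rnorm(n, sd = sigma_fa_count)
  R <- mu + d / 2
  L <- mu - d / 2
  if (rounding) {
    R <- pmax(round(R), 0)
    L <- pmax(round(L), 0)
  }
  df <- data.frame(specimen_id = sprintf("sim%03d", seq_len(n)),
                   population = population, trait = trait,
                   right_count = R, left_count = L, size = size,
                   stringsAsFactors = FALSE)
  if (rounding) meristic_records(df) else {
    class(df) <- unique(c("meristic_records", class(df)))
    df
  }
}
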
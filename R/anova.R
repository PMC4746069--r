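# Mixed-model Procrustes ANOVA for object symmetry, and Levene's test on
# scalar FA scores.

#' Procrustes ANOVA for fluctuating asymmetry
#'
#' Two-factor mixed ANOVA of Procrustes coordinates with individuals
#' (random) and sides (fixed), the standard design for separating individual
#' variation, directional asymmetry (the side main effect), fluctuating
#' asymmetry (the individual-by-side interaction) and digitizing error (the
#' replicate stratum). For object symmetry the two "sides" of each
#' digitization are its aligned original and its aligned reflected-relabelled
#' copy, so the analysis is a two-way ANOVA over the `2 n r` aligned
#' observations, with sums of squares accumulated over all shape coordinates.
#'
#' F ratios follow the mixed model: the individual and side mean squares are
#' tested over the individual-by-side interaction, and the interaction (the
#' FA term) over measurement error. P values are parametric, from the F
#' distribution on the symmetric/asymmetric subspace degrees of freedom
#' (see [symmetry_dims()]).
#'
#' @param sample A [study_sample()]; `n >= 3` specimens, balanced
#'   replication. With `r = 1` the measurement-error stratum is absent and
#'   the interaction is the bottom stratum (no F for FA).
#' @param map A [symmetry_map()].
#' @param tol,max_iter GPA controls passed to [symmetry_decompose()].
#' @return Object of class `"procrustes_anova"`: the ANOVA `table`
#'   (effect, SS, MS, df, F, P), design sizes `n`, `r`, subspace `dims`, and
#'   the underlying `decomposition`.
#' @export
procrustes_anova <- function(sample, map, tol = 1e-10, max_iter = 100L) {
  if (!inherits(sample, "study_sample") && is.list(sample))
    sample <- study_sample(sample)
  if (sample$n < 3L)
    stop("Procrustes ANOVA needs at least 3 specimens, got ", sample$n)
  dec <- symmetry_decompose(sample, map, tol = tol, max_iter = max_iter)
  n <- sample$n; r <- sample$r
  s <- dec$dims[["s"]]; a <- dec$dims[["a"]]

  S <- flatten_obs(dec$symmetric)
  A <- flatten_obs(dec$asymmetric)
  Sbar_i <- specimen_means(S, dec$index$specimen)
  Abar_i <- specimen_means(A, dec$index$specimen)
  Sbar <- colMeans(Sbar_i)
  Abar <- colMeans(Abar_i)

  ss_ind <- 2 * r * sum(sweep(Sbar_i, 2L, Sbar)^2)
  ss_side <- 2 * n * r * sum(Abar^2)
  ss_ixs <- 2 * r * sum(sweep(Abar_i, 2L, Abar)^2)
  ss_err <- 2 * (sum((S - Sbar_i[dec$index$specimen, , drop = FALSE])^2) +
                 sum((A - Abar_i[dec$index$specimen, , drop = FALSE])^2))

  # refuse parametric P when the realised component rank falls short of the
  # subspace dimension it should span (degenerate template)
  rank_tol <- 1e-8
  rank_of <- function(M) {
    M <- sweep(M, 2L, colMeans(M))
    d <- svd(M, nu = 0L, nv = 0L)$d
    sum(d > rank_tol * max(d, rank_tol))
  }
  rank_def <- rank_of(Sbar_i) < min(s, n - 1L) ||
              rank_of(Abar_i) < min(a, n - 1L)

  eff <- data.frame(
    effect = c("Individual", "Side", "Individual x Side"),
    SS = c(ss_ind, ss_side, ss_ixs),
    df = c((n - 1L) * s, a, (n - 1L) * a),
    stringsAsFactors = FALSE)
  if (r >= 2L)
    eff <- rbind(eff, data.frame(effect = "Measurement error", SS = ss_err,
                                 df = n * (r - 1L) * (s + a)))
  tab <- assemble_anova_table(eff)
  if (rank_def) {
    warning("component covariance rank below the symmetric/asymmetric ",
            "subspace dimension; parametric P values suppressed")
    tab$table$P <- NA_real_
  }
  structure(list(table = tab$table, n = n, r = r, dims = dec$dims,
                 rank_deficient = rank_def, population = sample$population,
                 decomposition = dec),
            class = "procrustes_anova")
}

#' Assemble a Procrustes ANOVA table from sums of squares
#'
#' Fills in mean squares (`MS = SS/df`), F ratios and parametric P values
#' for the effects of the individuals-by-sides design: `Individual` and
#' `Side` are tested over `Individual x Side`, and `Individual x Side` over
#' `Measurement error` (when that stratum is present). Useful on its own to
#' rebuild a published table from printed SS and df.
#'
#' @param ss_df Data frame with columns `effect` (names among `Individual`,
#'   `Side`, `Individual x Side`, `Measurement error`), `SS` and `df`.
#' @return Object of class `"procrustes_anova_table"` wrapping the completed
#'   `table`.
#' @examples
#' assemble_anova_table(data.frame(
#'   effect = c("Individual", "Side", "Individual x Side",
#'              "Measurement error"),
#'   SS = c(0.26086047, 0.0053173, 0.03602375, 0.00201864),
#'   df = c(480, 14, 448, 957)))
#' @export
assemble_anova_table <- function(ss_df) {
  need <- c("effect", "SS", "df")
  if (!all(need %in% names(ss_df)))
    stop("ss_df needs columns: ", paste(need, collapse = ", "))
  known <- c("Individual", "Side", "Individual x Side", "Measurement error")
  bad <- setdiff(ss_df$effect, known)
  if (length(bad))
    stop("unknown effect name(s): ", paste(bad, collapse = ", "))
  if (any(ss_df$df <= 0))
    stop("degrees of freedom must be positive")
  if (any(ss_df$SS < 0))
    stop("sums of squares must be non-negative")
  tab <- ss_df[match(known[known %in% ss_df$effect], ss_df$effect),
               need, drop = FALSE]
  tab$MS <- tab$SS / tab$df
  ms <- function(e) if (e %in% tab$effect) tab$MS[tab$effect == e] else NA_real_
  df_of <- function(e) if (e %in% tab$effect) tab$df[tab$effect == e] else NA_real_
  denom <- c("Individual" = "Individual x Side",
             "Side" = "Individual x Side",
             "Individual x Side" = "Measurement error",
             "Measurement error" = NA)
  tab$F <- NA_real_
  tab$P <- NA_real_
  for (i in seq_len(nrow(tab))) {
    d <- denom[[tab$effect[i]]]
    if (is.na(d) || !(d %in% tab$effect)) next
    dms <- ms(d)
    if (dms == 0) {
      tab$F[i] <- if (tab$MS[i] == 0) 0 else Inf
      tab$P[i] <- if (tab$MS[i] == 0) 1 else 0
    } else {
      tab$F[i] <- tab$MS[i] / dms
      tab$P[i] <- stats::pf(tab$F[i], tab$df[i], df_of(d), lower.tail = FALSE)
    }
  }
  rownames(tab) <- NULL
  structure(list(table = tab[, c("effect", "SS", "MS", "df", "F", "P")]),
            class = "procrustes_anova_table")
}

format_anova_table <- function(tab, digits = 4) {
  out <- tab
  out$SS <- signif(out$SS, 8)
  out$MS <- signif(out$MS, 5)
  out$F <- ifelse(is.na(out$F), "", formatC(out$F, format = "f", digits = 2))
  out$P <- ifelse(is.na(out$P), "",
                  ifelse(tab$P < 1e-4, "<0.0001",
                         formatC(out$P, format = "f", digits = 4)))
  names(out)[1L] <- "Effect"
  out
}

#' @export
print.procrustes_anova_table <- function(x, ...) {
  print(format_anova_table(x$table), row.names = FALSE)
  invisible(x)
}

#' @export
print.procrustes_anova <- function(x, ...) {
  cat("Procrustes ANOVA ('", x$population, "'): ", x$n, " individuals, ",
      x$r, " replicate(s), subspace dims s = ", x$dims[["s"]], ", a = ",
      x$dims[["a"]], "\n", sep = "")
  print(format_anova_table(x$table), row.names = FALSE)
  if (x$rank_deficient)
    cat("  (rank-deficient components: parametric P suppressed)\n")
  invisible(x)
}

#' @export
summary.procrustes_anova <- function(object, ...) {
  tab <- object$table
  ms <- function(e) tab$MS[match(e, tab$effect)]
  r <- object$r
  # expected mean squares under the mixed model (per shape dimension, with
  # the 2 n r observation convention): E[MS_err] = 2*s2_me,
  # E[MS_ixs] = 2*s2_me + 2r*s2_fa, E[MS_ind] = 2*s2_me + 2r*s2_ind
  s2_me <- if ("Measurement error" %in% tab$effect) ms("Measurement error") / 2
           else NA_real_
  s2_fa <- if (!is.na(s2_me)) (ms("Individual x Side") - 2 * s2_me) / (2 * r)
           else NA_real_
  s2_ind <- if (!is.na(s2_me)) (ms("Individual") - 2 * s2_me) / (2 * r)
            else NA_real_
  out <- list(anova = object, variance_components = c(
    individual = s2_ind, fa = s2_fa, measurement_error = s2_me))
  class(out) <- "summary.procrustes_anova"
  out
}

#' @export
print.summary.procrustes_anova <- function(x, ...) {
  print(x$anova)
  vc <- x$variance_components
  cat("\nVariance components (per shape dimension):\n")
  cat("  individual (symmetric): ", format(vc[["individual"]], digits = 4),
      "\n  fluctuating asymmetry:  ", format(vc[["fa"]], digits = 4),
      "\n  measurement error:      ",
      format(vc[["measurement_error"]], digits = 4), "\n", sep = "")
  invisible(x)
}

#' Write a Procrustes ANOVA table to CSV and aligned text
#'
#' @param x A `procrustes_anova` or `procrustes_anova_table` object.
#' @param csv_path,txt_path Output paths (either may be `NULL` to skip).
#' @return The formatted table, invisibly.
#' @export
write_anova_table <- function(x, csv_path = NULL, txt_path = NULL) {
  tab <- if (inherits(x, "procrustes_anova")) x$table else x$table
  if (!is.null(csv_path))
    utils::write.csv(tab, csv_path, row.names = FALSE, na = "")
  if (!is.null(txt_path)) {
    fmt <- format_anova_table(tab)
    writeLines(utils::capture.output(print(fmt, row.names = FALSE)),
               txt_path)
  }
  invisible(tab)
}

#' Levene's test for homogeneity of variability across groups
#'
#' Compares the dispersion of values across groups by one-way ANOVA on the
#' absolute deviations from each group's centre: the median (Brown-Forsythe
#' variant, default, robust to non-normality) or the mean. Used both on
#' shape FA scores and on unsigned count asymmetries `|R - L|`.
#'
#' @param values_by_group Named list of numeric vectors (one per group), or
#'   a numeric vector when `groups` is given.
#' @param groups Optional grouping factor accompanying a vector `values`.
#' @param center `"median"` or `"mean"`.
#' @return An `htest`-like list: `statistic` (W), `parameter` (df),
#'   `p.value`, `method`.
#' @export
levene_test <- function(values_by_group, groups = NULL,
                        center = c("median", "mean")) {
  center <- match.arg(center)
  if (is.list(values_by_group)) {
    values <- unlist(values_by_group, use.names = FALSE)
    groups <- rep(names(values_by_group) %||% seq_along(values_by_group),
                  lengths(values_by_group))
  } else {
    values <- values_by_group
  }
  groups <- factor(groups)
  if (nlevels(groups) < 2L)
    stop("Levene's test needs at least 2 groups")
  if (any(table(groups) < 2L))
    stop("every group needs at least 2 observations")
  lt <- car::leveneTest(values, groups,
                        center = if (center == "median") stats::median
                                 else mean)
  W <- lt[1L, "F value"]
  p <- lt[1L, "Pr(>F)"]
  if (is.nan(W)) { W <- 0; p <- 1 }   # all deviations identical
  structure(list(statistic = c(W = W),
                 parameter = c(df1 = lt[1L, "Df"], df2 = lt[2L, "Df"]),
                 p.value = p,
                 method = paste0("Levene's test (", center, "-centered)"),
                 data.name = deparse(substitute(values_by_group))),
            class = "htest")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Levene's test on shape FA scores across populations
#'
#' Convenience wrapper: compares the per-specimen fluctuating-asymmetry
#' scores (see [individual_fa_scores()]) across populations.
#'
#' @param scores_by_population Named list of score vectors, one per
#'   population.
#' @param center Group centre, see [levene_test()].
#' @return An `htest` object.
#' @export
levene_shape_fa <- function(scores_by_population,
                            center = c("median", "mean")) {
  levene_test(scores_by_population, center = match.arg(center))
}
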
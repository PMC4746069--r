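# The meristic (bilateral count) fluctuating-asymmetry protocol: outlier
# screening, distributional checks, FA1/FA4a indices, cross-population
# Levene comparisons, allometry ANCOVA and categorical trait tabulation.

#' Iterated Grubbs outlier screen
#'
#' Two-sided Grubbs test, applied repeatedly: in each round the value
#' furthest from the mean is tested against the t-based critical value at
#' level `alpha` and removed if significant, until no further rejection.
#' Outliers in signed right-minus-left differences would otherwise inflate
#' FA estimates. Samples with zero variance are returned untouched (the
#' statistic is undefined).
#'
#' @param diffs Numeric vector (typically signed `R - L` differences),
#'   `n >= 3`.
#' @param alpha Significance level of each round.
#' @return List with `kept` (remaining values), `removed` (integer indices
#'   into the original vector) and `g` (the Grubbs statistic of each removed
#'   value).
#' @export
grubbs_screen <- function(diffs, alpha = 0.05) {
  x <- as.numeric(diffs)
  if (length(x) < 3L)
    stop("Grubbs screening needs at least 3 values, got ", length(x))
  removed <- integer()
  gs <- numeric()
  live <- seq_along(x)
  repeat {
    n <- length(live)
    if (n < 3L) break
    v <- x[live]
    s <- stats::sd(v)
    if (s == 0) break
    dev <- abs(v - mean(v))
    i <- which.max(dev)
    G <- dev[i] / s
    tcrit <- stats::qt(alpha / (2 * n), df = n - 2L, lower.tail = FALSE)
    Gcrit <- (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
    if (G > Gcrit) {
      removed <- c(removed, live[i])
      gs <- c(gs, G)
      live <- live[-i]
    } else break
  }
  list(kept = x[live], removed = removed, g = gs)
}

#' FA indices and screening tests for one bilateral count trait
#'
#' Runs the complete protocol on the signed side differences `R - L` of one
#' trait in one population, in fixed order: (1) iterated [grubbs_screen()]
#' at `alpha`; (2) Spearman rank correlation of `|R - L|` with trait size
#' `(R + L) / 2` (size dependence of FA would confound comparisons);
#' (3) Shapiro-Wilk normality test of `R - L` (ideal FA is normal with mean
#' zero; non-normality flags possible antisymmetry); (4) one-sample t test
#' of `R - L` against zero (directional asymmetry); (5) the indices
#' `FA1 = mean |R - L|` and `FA4a = 0.798 * sqrt(var(R - L))` (`n - 1`
#' denominator), FA4a being robust to directional asymmetry. When DA is
#' present, its practical weight is judged by whether `|mean(R - L)|`
#' exceeds FA4a; if not, the side variation is attributed mainly to
#' developmental instability.
#'
#' @param records A [meristic_records()] data frame (or anything coercible),
#'   restricted with `trait` / `population` if given. All remaining records
#'   must belong to one trait and one population.
#' @param trait,population Optional filters.
#' @param alpha Level for the Grubbs screen.
#' @param grubbs Apply the outlier screen (default) or keep all records.
#' @return Object of class `"fa_report"`: `trait`, `population`, `n` (after
#'   screening), `FA1`, `FA4a`, `DA_mean`, `t_statistic`, `t_P`,
#'   `shapiro_P`, `outliers_removed` (specimen ids),
#'   `size_dependence_rho`, `size_dependence_P`, `da_dominates`.
#' @export
fa_indices <- function(records, trait = NULL, population = NULL,
                       alpha = 0.05, grubbs = TRUE) {
  df <- as.data.frame(records)
  if (!is.null(trait)) df <- df[df$trait == trait, , drop = FALSE]
  if (!is.null(population))
    df <- df[df$population == population, , drop = FALSE]
  if (length(unique(df$trait)) > 1L || length(unique(df$population)) > 1L)
    stop("records span several traits/populations; filter with the ",
         "'trait' and 'population' arguments or use fa_report_table()")
  d <- df$right_count - df$left_count
  if (length(d) < 3L)
    stop("FA analysis needs at least 3 records, got ", length(d))
  if (grubbs) {
    scr <- grubbs_screen(d, alpha)
    keep <- setdiff(seq_along(d), scr$removed)
  } else {
    scr <- list(removed = integer())
    keep <- seq_along(d)
  }
  dk <- d[keep]
  size_k <- ((df$right_count + df$left_count) / 2)[keep]
  rho <- rho_p <- NA_real_
  if (stats::sd(abs(dk)) > 0 && stats::sd(size_k) > 0) {
    ct <- suppressWarnings(
      stats::cor.test(abs(dk), size_k, method = "spearman"))
    rho <- unname(ct$estimate); rho_p <- ct$p.value
  }
  shapiro_p <- if (stats::sd(dk) > 0 && length(dk) <= 5000L)
    stats::shapiro.test(dk)$p.value else NA_real_  # W is defined for n <= 5000
  if (stats::sd(dk) > 0) {
    tt <- stats::t.test(dk, mu = 0)
    t_stat <- unname(tt$statistic); t_p <- tt$p.value
  } else {
    t_stat <- NA_real_; t_p <- NA_real_
  }
  fa1 <- mean(abs(dk))
  fa4a <- 0.798 * sqrt(stats::var(dk))
  da <- mean(dk)
  structure(list(trait = df$trait[1L], population = df$population[1L],
                 n = length(dk), FA1 = fa1, FA4a = fa4a, DA_mean = da,
                 t_statistic = t_stat, t_P = t_p, shapiro_P = shapiro_p,
                 outliers_removed = df$specimen_id[scr$removed],
                 size_dependence_rho = rho, size_dependence_P = rho_p,
                 da_dominates = is.finite(fa4a) && abs(da) > fa4a),
            class = "fa_report")
}

#' @export
print.fa_report <- function(x, ...) {
  cat("FA report: trait '", x$trait, "', population '", x$population,
      "' (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  FA1 = %.3f   FA4a = %.3f   mean(R-L) = %.3f\n",
              x$FA1, x$FA4a, x$DA_mean))
  cat(sprintf("  DA t-test: t = %s, P = %s\n",
              format(x$t_statistic, digits = 3),
              format(x$t_P, digits = 3)))
  cat(sprintf("  Shapiro-Wilk P = %s   size-dependence rho = %s (P = %s)\n",
              format(x$shapiro_P, digits = 3),
              format(x$size_dependence_rho, digits = 3),
              format(x$size_dependence_P, digits = 3)))
  if (length(x$outliers_removed))
    cat("  outliers removed:", paste(x$outliers_removed, collapse = ", "),
        "\n")
  cat("  variation attributed mainly to ",
      if (isTRUE(x$da_dominates)) "directional asymmetry (|DA| > FA4a)"
      else "developmental instability (|DA| <= FA4a)", "\n", sep = "")
  invisible(x)
}

#' FA indices for every trait-by-population combination
#'
#' @inheritParams fa_indices
#' @return Data frame with one row per trait x population, mirroring the
#'   published index-table layout (FA1, FA4a, mean (R-L), t-test P, plus the
#'   screening results).
#' @export
fa_report_table <- function(records, alpha = 0.05, grubbs = TRUE) {
  df <- as.data.frame(records)
  combos <- unique(df[, c("trait", "population")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    rep_i <- fa_indices(df, trait = combos$trait[i],
                        population = combos$population[i],
                        alpha = alpha, grubbs = grubbs)
    data.frame(trait = rep_i$trait, population = rep_i$population,
               n = rep_i$n, FA1 = rep_i$FA1, FA4a = rep_i$FA4a,
               DA_mean = rep_i$DA_mean, t_P = rep_i$t_P,
               shapiro_P = rep_i$shapiro_P,
               size_dependence_rho = rep_i$size_dependence_rho,
               size_dependence_P = rep_i$size_dependence_P,
               outliers_removed = length(rep_i$outliers_removed),
               da_dominates = rep_i$da_dominates,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Levene's test on unsigned count asymmetries across populations
#'
#' Compares `|R - L|` dispersion between populations for one trait;
#' shares its engine with [levene_test()].
#'
#' @param unsigned_by_population Named list of `|R - L|` vectors, one per
#'   population.
#' @param center Group centre, see [levene_test()].
#' @return An `htest` object.
#' @export
levene_counts <- function(unsigned_by_population,
                          center = c("median", "mean")) {
  levene_test(unsigned_by_population, center = match.arg(center))
}

#' Allometry of bilateral counts: per-population slopes and ANCOVA
#'
#' Regresses the specimen mean count `(R + L) / 2` on body size (test
#' length) within each population and tests slope homogeneity via the
#' size-by-population interaction of the pooled linear model. An optional
#' log10-log10 transform fits power-law allometry.
#'
#' @param records A [meristic_records()] data frame for a single trait
#'   (filter with `trait`).
#' @param trait Optional trait filter.
#' @param log_transform Fit on `log10(count)` vs `log10(size)`.
#' @return Object of class `"allometry_ancova"`: per-population `fits`
#'   (population, slope, intercept, n), `interaction_P`, the pooled `model`,
#'   `trait` and `log_transform`.
#' @export
allometry_ancova <- function(records, trait = NULL, log_transform = FALSE) {
  df <- as.data.frame(records)
  if (!is.null(trait)) df <- df[df$trait == trait, , drop = FALSE]
  if (length(unique(df$trait)) > 1L)
    stop("records span several traits; pass the 'trait' argument")
  y <- (df$right_count + df$left_count) / 2
  x <- df$size
  if (log_transform) {
    if (any(y <= 0) || any(x <= 0))
      stop("log transform requires positive counts and sizes")
    y <- log10(y); x <- log10(x)
  }
  pop <- factor(df$population)
  if (nlevels(pop) < 2L)
    stop("ANCOVA needs at least 2 populations")
  if (any(table(pop) < 3L))
    stop("every population needs at least 3 records")
  for (p in levels(pop))
    if (stats::sd(x[pop == p]) == 0)
      stop("size is constant within population '", p, "': singular fit")
  fits <- do.call(rbind, lapply(levels(pop), function(p) {
    cf <- stats::coef(stats::lm(y[pop == p] ~ x[pop == p]))
    data.frame(population = p, slope = unname(cf[2L]),
               intercept = unname(cf[1L]), n = sum(pop == p),
               stringsAsFactors = FALSE)
  }))
  full <- stats::lm(y ~ x * pop)
  at <- stats::anova(full)
  int_p <- at["x:pop", "Pr(>F)"]
  structure(list(fits = fits, interaction_P = int_p, model = full,
                 trait = if (is.null(trait)) df$trait[1L] else trait,
                 log_transform = log_transform),
            class = "allometry_ancova")
}

#' @export
print.allometry_ancova <- function(x, ...) {
  cat("Count-size allometry ANCOVA, trait '", x$trait, "'",
      if (x$log_transform) " (log10-log10)", ":\n", sep = "")
  print(transform(x$fits, slope = signif(slope, 4),
                  intercept = signif(intercept, 4)), row.names = FALSE)
  cat("  slope homogeneity (size x population): P =",
      format(x$interaction_P, digits = 3), "\n")
  invisible(x)
}

#' Tabulate categorical trait states by population
#'
#' Counts and percentages of each state per trait and population, with
#' states reported in the declared vocabulary order. Populations left empty
#' after filtering are omitted with a warning.
#'
#' @param records Data frame with columns `specimen_id`, `population`,
#'   `trait`, `state` (see [read_states()]).
#' @param vocab Named list of per-trait state vocabularies; defaults to
#'   [trait_vocabularies()]. Traits absent from `vocab` use first-appearance
#'   order.
#' @return Data frame of class `"trait_table"` with columns `trait`,
#'   `population`, `state`, `count`, `percentage` (percentages sum to 100
#'   within trait x population).
#' @export
tabulate_states <- function(records, vocab = trait_vocabularies()) {
  df <- as.data.frame(records)
  if (!nrow(df)) stop("no records to tabulate")
  out <- list()
  for (tr in unique(df$trait)) {
    sub <- df[df$trait == tr, , drop = FALSE]
    states <- vocab[[tr]] %||% unique(sub$state)
    bad <- setdiff(sub$state, states)
    if (length(bad))
      stop("unknown state(s) for trait '", tr, "': ",
           paste(unique(bad), collapse = ", "))
    for (p in unique(df$population)) {
      psub <- sub[sub$population == p, , drop = FALSE]
      if (!nrow(psub)) {
        warning("population '", p, "' has no records for trait '", tr,
                "'; omitted")
        next
      }
      cnt <- table(factor(psub$state, levels = states))
      out[[length(out) + 1L]] <- data.frame(
        trait = tr, population = p, state = states,
        count = as.integer(cnt),
        percentage = 100 * as.integer(cnt) / nrow(psub),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("trait_table", class(res))
  res
}
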
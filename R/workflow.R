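# End-to-end study workflows: shape (GPA -> symmetric/asymmetric PCA ->
# Procrustes ANOVA -> cross-population Levene on FA scores) and meristic
# (FA protocol -> Levene -> allometry ANCOVA -> categorical tabulations).

write_provenance <- function(out_dir, what, params) {
  info <- list(analysis = what,
               package = "asymmorph",
               version = as.character(utils::packageVersion("asymmorph")),
               r_version = R.version.string,
               timestamp = format(Sys.time(), tz = "UTC"),
               parameters = params)
  jsonlite::write_json(info, file.path(out_dir, paste0(what, "_run.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the complete shape fluctuating-asymmetry workflow
#'
#' For every population: joint symmetric/asymmetric decomposition, PCA of
#' both components, Procrustes ANOVA, and per-specimen FA scores; then, when
#' two or more populations are supplied, Levene's test on the FA scores
#' across populations. All tables are written to `out_dir` as CSV (the ANOVA
#' additionally as aligned text) together with a JSON provenance sidecar.
#'
#' @param samples A [study_sample()] or named list of them (one per
#'   population).
#' @param map A [symmetry_map()] shared by all samples.
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @param correct_da Centre FA scores on the mean asymmetry, see
#'   [individual_fa_scores()].
#' @param center Levene centring, see [levene_test()].
#' @return Invisible list: per-population `anova`, `pca_symmetric`,
#'   `pca_asymmetric`, `fa_scores`; plus `levene` across populations (or
#'   `NULL` with a message when only one population is given).
#' @export
run_shape_workflow <- function(samples, map, out_dir = NULL,
                               correct_da = TRUE,
                               center = c("median", "mean")) {
  center <- match.arg(center)
  if (inherits(samples, "study_sample"))
    samples <- stats::setNames(list(samples), samples$population)
  if (is.null(names(samples)))
    names(samples) <- vapply(samples, `[[`, "", "population")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  res <- list(populations = list())
  scores_by_pop <- list()
  for (pop in names(samples)) {
    message("shape workflow: population '", pop, "'")
    an <- tryCatch(procrustes_anova(samples[[pop]], map),
                   error = function(e)
                     stop("Procrustes ANOVA failed for population '", pop,
                          "': ", conditionMessage(e), call. = FALSE))
    dec <- an$decomposition
    pca_s <- shape_pca(dec, component = "symmetric")
    pca_a <- shape_pca(dec, component = "asymmetric")
    scores <- individual_fa_scores(dec, correct_da = correct_da)
    scores_by_pop[[pop]] <- scores
    res$populations[[pop]] <- list(anova = an, pca_symmetric = pca_s,
                                   pca_asymmetric = pca_a,
                                   fa_scores = scores)
    if (!is.null(out_dir)) {
      write_anova_table(an,
        csv_path = file.path(out_dir, paste0("anova_", pop, ".csv")),
        txt_path = file.path(out_dir, paste0("anova_", pop, ".txt")))
      write_pca(pca_s, file.path(out_dir, paste0("pca_symmetric_", pop)))
      write_pca(pca_a, file.path(out_dir, paste0("pca_asymmetric_", pop)))
      utils::write.csv(data.frame(specimen = names(scores),
                                  fa_score = unname(scores)),
                       file.path(out_dir, paste0("fa_scores_", pop, ".csv")),
                       row.names = FALSE)
    }
  }
  if (length(samples) >= 2L) {
    res$levene <- levene_shape_fa(scores_by_pop, center = center)
    if (!is.null(out_dir))
      utils::write.csv(data.frame(W = res$levene$statistic,
                                  df1 = res$levene$parameter[[1L]],
                                  df2 = res$levene$parameter[[2L]],
                                  P = res$levene$p.value),
                       file.path(out_dir, "levene_shape_fa.csv"),
                       row.names = FALSE)
  } else {
    message("single population: cross-population Levene test skipped")
    res$levene <- NULL
  }
  if (!is.null(out_dir))
    write_provenance(out_dir, "shape",
                     list(populations = names(samples),
                          correct_da = correct_da, center = center,
                          n = vapply(samples, `[[`, 1L, "n"),
                          r = vapply(samples, `[[`, 1L, "r")))
  invisible(res)
}

#' Run the complete meristic fluctuating-asymmetry workflow
#'
#' For every trait x population: the full FA index protocol
#' ([fa_indices()]); per trait: Levene's test on unsigned `|R - L|` across
#' populations (on the post-screening values) and the count-size allometry
#' ANCOVA; plus categorical trait tabulations when `states` are supplied.
#'
#' @param counts A [meristic_records()] data frame (or CSV path).
#' @param states Optional categorical records (data frame or CSV path).
#' @param out_dir Output directory; `NULL` skips writing.
#' @param alpha Grubbs screening level.
#' @param log_transform Log-log allometry fit, see [allometry_ancova()].
#' @param center Levene centring.
#' @return Invisible list: `fa_table`, per-trait `levene` and `allometry`,
#'   and `states_table` when states were given.
#' @export
run_meristic_workflow <- function(counts, states = NULL, out_dir = NULL,
                                  alpha = 0.05, log_transform = FALSE,
                                  center = c("median", "mean")) {
  center <- match.arg(center)
  if (is.character(counts)) counts <- read_counts(counts)
  counts <- meristic_records(as.data.frame(counts))
  if (is.character(states)) states <- read_states(states)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  message("meristic workflow: ", length(unique(counts$trait)), " trait(s), ",
          length(unique(counts$population)), " population(s)")
  fa_tab <- fa_report_table(counts, alpha = alpha)
  res <- list(fa_table = fa_tab, levene = list(), allometry = list())
  for (tr in unique(counts$trait)) {
    sub <- counts[counts$trait == tr, , drop = FALSE]
    pops <- unique(sub$population)
    if (length(pops) >= 2L) {
      unsigned <- lapply(stats::setNames(pops, pops), function(p) {
        d <- sub$right_count[sub$population == p] -
             sub$left_count[sub$population == p]
        abs(grubbs_screen(d, alpha)$kept)
      })
      res$levene[[tr]] <- levene_counts(unsigned, center = center)
      res$allometry[[tr]] <- allometry_ancova(sub, trait = tr,
                                              log_transform = log_transform)
    } else {
      message("trait '", tr, "': single population, Levene/ANCOVA skipped")
    }
  }
  if (!is.null(states)) res$states_table <- tabulate_states(states)
  if (!is.null(out_dir)) {
    utils::write.csv(fa_tab, file.path(out_dir, "fa_indices.csv"),
                     row.names = FALSE, na = "")
    if (length(res$levene)) {
      lev <- do.call(rbind, lapply(names(res$levene), function(tr)
        data.frame(trait = tr, W = res$levene[[tr]]$statistic,
                   P = res$levene[[tr]]$p.value)))
      utils::write.csv(lev, file.path(out_dir, "levene_counts.csv"),
                       row.names = FALSE)
    }
    if (length(res$allometry)) {
      allo <- do.call(rbind, lapply(names(res$allometry), function(tr) {
        a <- res$allometry[[tr]]
        cbind(trait = tr, a$fits, interaction_P = a$interaction_P)
      }))
      utils::write.csv(allo, file.path(out_dir, "allometry.csv"),
                       row.names = FALSE)
    }
    if (!is.null(res$states_table))
      utils::write.csv(res$states_table,
                       file.path(out_dir, "trait_states.csv"),
                       row.names = FALSE)
    write_provenance(out_dir, "meristic",
                     list(alpha = alpha, log_transform = log_transform,
                          center = center,
                          traits = unique(counts$trait),
                          populations = unique(counts$population)))
  }
  invisible(res)
}
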
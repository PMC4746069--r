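# Procrustes ANOVA: brute-force oracle, table assembly, df accounting,
# invariances, expected mean squares, and Levene's test on FA scores.

test_that("all four sums of squares match an explicit-loop oracle", {
  set.seed(13)
  tpl <- tiny_template(k = 2L, u = 1L)
  s <- simulate_landmarks(n_individuals = 3L, replicates = 2L,
                          sigma_individual = 0.05, sigma_fa = 0.03,
                          sigma_me = 0.02, da_magnitude = 0.04,
                          template = tpl$coords, map = tpl$map, seed = 13)
  an <- procrustes_anova(s, tpl$map)
  oracle <- brute_anova_ss(an$decomposition)
  got <- an$table$SS
  names(got) <- an$table$effect
  expect_equal(unname(got["Individual"]), unname(oracle["ind"]),
               tolerance = 1e-9)
  expect_equal(unname(got["Side"]), unname(oracle["side"]),
               tolerance = 1e-9)
  expect_equal(unname(got["Individual x Side"]), unname(oracle["ixs"]),
               tolerance = 1e-9)
  expect_equal(unname(got["Measurement error"]), unname(oracle["err"]),
               tolerance = 1e-9)
  # SS_total (about the coordinate-wise grand mean) decomposes exactly
  A <- an$decomposition
  y <- array(c(A$aligned, A$mirrored),
             dim = dim(A$aligned) + c(0L, 0L, dim(A$aligned)[3L]))
  gm <- apply(y, c(1L, 2L), mean)
  expect_equal(sum(got), sum(sweep(y, c(1L, 2L), gm)^2), tolerance = 1e-9)
})

test_that("degrees of freedom follow the design formulas", {
  for (prm in list(list(n = 5L, r = 2L, k = 2L, u = 1L),
                   list(n = 4L, r = 3L, k = 3L, u = 2L))) {
    tpl <- tiny_template(k = prm$k, u = prm$u)
    s <- simulate_landmarks(n_individuals = prm$n, replicates = prm$r,
                            sigma_individual = 0.03, sigma_fa = 0.02,
                            sigma_me = 0.01, template = tpl$coords,
                            map = tpl$map, seed = prm$n * 100L + prm$r)
    an <- procrustes_anova(s, tpl$map)
    dims <- symmetry_dims(prm$k, prm$u, 2L)
    df <- an$table$df
    names(df) <- an$table$effect
    expect_equal(unname(df["Individual"]), (prm$n - 1L) * dims[["s"]])
    expect_equal(unname(df["Side"]), dims[["a"]])
    expect_equal(unname(df["Individual x Side"]), (prm$n - 1L) * dims[["a"]])
    expect_equal(unname(df["Measurement error"]),
                 prm$n * (prm$r - 1L) * (dims[["s"]] + dims[["a"]]))
    expect_equal(an$table$MS, an$table$SS / an$table$df, tolerance = 1e-12)
  }
})

test_that("zero digitizing noise gives zero error SS and an infinite FA test", {
  s <- simulate_landmarks(n_individuals = 5L, replicates = 2L,
                          sigma_individual = 0.03, sigma_fa = 0.02,
                          sigma_me = 0, seed = 23)
  an <- procrustes_anova(s, attr(s, "truth")$map)
  tab <- an$table
  expect_lt(tab$SS[tab$effect == "Measurement error"], 1e-12)
  expect_identical(tab$F[tab$effect == "Individual x Side"], Inf)

  # all components zero: every observation equals the template; the
  # degenerate (zero-rank) components suppress parametric P with a warning
  s0 <- simulate_landmarks(n_individuals = 4L, replicates = 2L,
                           sigma_individual = 0, sigma_fa = 0,
                           sigma_me = 0, seed = 24)
  expect_warning(an0 <- procrustes_anova(s0, attr(s0, "truth")$map),
                 "rank")
  expect_true(all(an0$table$SS < 1e-12))
  expect_true(all(is.na(an0$table$P)))
})

test_that("ANOVA SS are invariant to similarity transforms of the inputs", {
  set.seed(33)
  s <- simulate_landmarks(n_individuals = 6L, replicates = 2L,
                          sigma_individual = 0.04, sigma_fa = 0.02,
                          sigma_me = 0.01, da_magnitude = 0.02, seed = 33)
  map <- attr(s, "truth")$map
  ss0 <- procrustes_anova(s, map)$table$SS
  moved <- lapply(s$configs, function(cf) {
    cf$coords <- similarity_transform(cf$coords)
    cf
  })
  ss1 <- procrustes_anova(study_sample(moved, replicates = 2L), map)$table$SS
  expect_equal(ss1, ss0, tolerance = 1e-8)
})

test_that("side factor is calibrated without DA and powerful with DA", {
  set.seed(43)
  p_null <- vapply(1:30, function(i) {
    s <- simulate_landmarks(n_individuals = 30L, replicates = 2L,
                            sigma_individual = 0.02, sigma_fa = 0.01,
                            sigma_me = 0.005, da_magnitude = 0,
                            seed = 1000L + i)
    an <- procrustes_anova(s, attr(s, "truth")$map)
    an$table$P[an$table$effect == "Side"]
  }, 0)
  # P approximately uniform: no mass collapse at either end
  expect_gt(mean(p_null), 0.25)
  expect_lt(mean(p_null), 0.75)
  expect_gt(ks.test(p_null, "punif")$p.value, 0.01)

  s_da <- simulate_landmarks(n_individuals = 200L, replicates = 2L,
                             sigma_individual = 0.02, sigma_fa = 0.01,
                             sigma_me = 0.005, da_magnitude = 0.02,
                             seed = 99L)
  an_da <- procrustes_anova(s_da, attr(s_da, "truth")$map)
  expect_lt(an_da$table$P[an_da$table$effect == "Side"], 1e-6)
})

test_that("expected mean squares track the simulated variance components", {
  set.seed(53)
  est <- replicate(25L, {
    s <- simulate_landmarks(n_individuals = 80L, replicates = 2L,
                            sigma_individual = 0.02, sigma_fa = 0.008,
                            sigma_me = 0.004,
                            seed = sample.int(1e6, 1L))
    unlist(summary(procrustes_anova(s, attr(s, "truth")$map))
           $variance_components)
  })
  means <- rowMeans(est)
  expect_equal(unname(means["measurement_error"]), 0.004^2,
               tolerance = 0.1)
  expect_equal(unname(means["fa"]), 0.008^2, tolerance = 0.1)
  expect_equal(unname(means["individual"]), 0.02^2, tolerance = 0.1)
})

test_that("table assembly validates its inputs and degenerate F cases", {
  expect_error(assemble_anova_table(
    data.frame(effect = "Individual", SS = 1, df = 0)), "positive")
  expect_error(assemble_anova_table(
    data.frame(effect = "Sides", SS = 1, df = 2)), "unknown effect")
  tab <- assemble_anova_table(data.frame(
    effect = c("Individual", "Side", "Individual x Side",
               "Measurement error"),
    SS = c(0, 0, 0, 1), df = c(4, 2, 8, 16)))$table
  expect_equal(tab$F[tab$effect == "Individual"], 0)
  expect_equal(tab$F[tab$effect == "Side"], 0)
})

test_that("single-replicate designs drop the error stratum", {
  s <- simulate_landmarks(n_individuals = 5L, replicates = 1L,
                          sigma_individual = 0.03, sigma_fa = 0.01,
                          sigma_me = 0, seed = 63)
  an <- procrustes_anova(s, attr(s, "truth")$map)
  expect_false("Measurement error" %in% an$table$effect)
  expect_true(is.na(an$table$F[an$table$effect == "Individual x Side"]))
})

test_that("Levene on FA scores: identity, calibration edge cases", {
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  lt <- levene_shape_fa(g)
  expect_equal(unname(lt$statistic), 0)
  expect_equal(lt$p.value, 1)

  # zero-variance deviations in one group: statistic still defined
  lt2 <- levene_test(list(a = c(1, 1, 1), b = c(0, 2, 4)))
  expect_true(is.finite(lt2$statistic))
  expect_error(levene_test(list(a = 1, b = c(1, 2))), "at least 2")
  expect_error(levene_test(list(a = c(1, 2))), "2 groups")
})

test_that("Levene power: 4x variance ratio at n = 35 per group", {
  set.seed(73)
  rej <- mean(replicate(500L, {
    levene_test(list(a = rnorm(35, sd = 1),
                     b = rnorm(35, sd = 2)))$p.value < 0.05
  }))
  expect_gt(rej, 0.8)
})
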
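# Bilateral-count FA protocol: Grubbs screen, indices, Levene comparisons,
# allometry ANCOVA and categorical trait tabulation.

make_records <- function(diffs, population = "P", trait = "anterior_petals",
                         base = 30L, size = NULL) {
  n <- length(diffs)
  meristic_records(data.frame(
    specimen_id = sprintf("s%02d", seq_len(n)), population = population,
    trait = trait,
    right_count = base + pmax(diffs, 0),
    left_count = base + pmax(-diffs, 0),
    size = size %||% seq(30, 50, length.out = n)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("Grubbs screen matches published critical behaviour", {
  # G = 1.414 < G_crit(n = 6, alpha = .05) = 1.887: nothing removed
  expect_length(grubbs_screen(c(0, 1, -1, 0, 2, -2))$removed, 0L)
  # an extreme value is flagged (G = 2.04 > 1.887)
  scr <- grubbs_screen(c(0, 0, 0, 0, 0, 50))
  expect_equal(scr$removed, 6L)
  expect_equal(scr$kept, rep(0, 5))
  # zero variance: statistic undefined, keep everything
  expect_length(grubbs_screen(rep(2, 6))$removed, 0L)
  expect_error(grubbs_screen(c(1, 2)), "at least 3")
  # iterated removal peels one value per round
  scr2 <- grubbs_screen(c(rep(0, 10), 30, -40))
  expect_setequal(scr2$removed, c(11L, 12L))
})

test_that("FA indices: printed-constant arithmetic and symmetric samples", {
  r1 <- fa_indices(make_records(c(0, 1, 2)))
  expect_equal(r1$FA1, 1)
  expect_equal(r1$FA4a, 0.798)       # sample variance is exactly 1
  expect_equal(r1$DA_mean, 1)

  r2 <- fa_indices(make_records(c(-1, 1, -1, 1)))
  expect_equal(r2$FA1, 1)
  expect_equal(r2$DA_mean, 0)
  expect_equal(r2$t_P, 1)
  expect_false(r2$da_dominates)
})

test_that("FA1 and FA4a both estimate 0.798*sigma under pure normal FA", {
  set.seed(15)
  rec <- simulate_meristic(n = 1e4, base_count = 40, allometry_slope = 0,
                           size_range = c(30, 50), da_shift = 0,
                           sigma_fa_count = 3, rounding = FALSE, seed = 15)
  r <- fa_indices(rec, grubbs = FALSE)
  expect_equal(r$FA1 / r$FA4a, 1, tolerance = 0.02)
  expect_equal(r$FA4a, 0.798 * 3, tolerance = 0.03)
})

test_that("index invariances: sign flip and DA shift", {
  set.seed(25)
  d <- round(rnorm(20, sd = 2))
  ra <- fa_indices(make_records(d), grubbs = FALSE)
  rb <- fa_indices(make_records(-d), grubbs = FALSE)
  expect_equal(ra$FA1, rb$FA1)
  expect_equal(ra$FA4a, rb$FA4a)
  expect_equal(ra$DA_mean, -rb$DA_mean)
  # FA4a unchanged by adding a constant DA shift; FA1 is not
  rc <- fa_indices(make_records(d + 5L), grubbs = FALSE)
  expect_equal(rc$FA4a, ra$FA4a)
  expect_gt(rc$FA1, ra$FA1)
  expect_true(rc$da_dominates)
})

test_that("screening pipeline: outlier removal precedes the index computation", {
  d <- c(0, 1, -1, 0, 1, -2, 2, 0, 25)
  rep_scr <- fa_indices(make_records(d))
  expect_equal(rep_scr$outliers_removed, "s09")
  expect_equal(rep_scr$n, 8L)
  expect_equal(rep_scr$FA1, mean(abs(d[-9])))
  rep_raw <- fa_indices(make_records(d), grubbs = FALSE)
  expect_gt(rep_raw$FA4a, 2 * rep_scr$FA4a)
  # degenerate post-screen variance: FA4a = 0, t test undefined
  r0 <- fa_indices(make_records(rep(0L, 5)))
  expect_equal(r0$FA4a, 0)
  expect_true(is.na(r0$t_P))
})

test_that("Levene on counts: identity case, type-I calibration, power", {
  expect_equal(levene_counts(list(a = c(0, 1, 2, 1), b = c(0, 1, 2, 1)))
               $p.value, 1)
  set.seed(35)
  # populations like the published contrast: clearly different FA scales
  # at n = 36 vs 35 are detected in the majority of replicate draws
  hits <- mean(replicate(200L, {
    li <- simulate_meristic(n = 36L, da_shift = 1.89,
                            sigma_fa_count = 2.83, population = "Liencres")
    er <- simulate_meristic(n = 35L, da_shift = 0.57,
                            sigma_fa_count = 1.45, population = "Erwitte")
    dli <- abs(li$right_count - li$left_count)
    der <- abs(er$right_count - er$left_count)
    levene_counts(list(L = dli, E = der))$p.value < 0.05
  }))
  expect_gt(hits, 0.5)
})

test_that("allometry ANCOVA: exact fits, calibrated and powerful contrasts", {
  # exact shared slope: both groups on y = 2x
  size <- rep(seq(20, 64, by = 4), 2L)
  pop <- rep(c("A", "B"), each = 12L)
  y <- 2 * size
  rec <- meristic_records(data.frame(
    specimen_id = sprintf("s%02d", 1:24), population = pop,
    trait = "anterior_petals", right_count = as.integer(y),
    left_count = as.integer(y), size = size))
  fit <- suppressWarnings(allometry_ancova(rec))  # perfect-fit F warning
  expect_equal(fit$fits$slope, c(2, 2), tolerance = 1e-10)
  # with a perfect fit the interaction F is 0/0; duplicate real residuals
  # across groups instead, where the interaction SS is exactly zero
  wiggle <- rep(c(-2L, 3L, -1L, 0L, 2L, -2L), 2L)[1:12]
  rec$right_count <- rec$right_count + rep(wiggle, 2L)
  rec$left_count <- rec$left_count + rep(wiggle, 2L)
  fit2 <- allometry_ancova(rec)
  expect_equal(fit2$fits$slope[1L], fit2$fits$slope[2L], tolerance = 1e-12)
  expect_equal(fit2$interaction_P, 1, tolerance = 1e-8)

  set.seed(45)
  # slopes 0.93 vs 0.90 with count-level noise: rarely "significant"
  sim_two <- function(s1, s2, sigma, n = 35L) {
    a <- simulate_meristic(n = n, base_count = 10, allometry_slope = s1,
                           sigma_fa_count = sigma, population = "A")
    b <- simulate_meristic(n = n, base_count = 10, allometry_slope = s2,
                           sigma_fa_count = sigma, population = "B")
    allometry_ancova(rbind(a, b))$interaction_P
  }
  ns <- mean(replicate(200L, sim_two(0.93, 0.90, 2) > 0.05))
  expect_gt(ns, 0.8)
  # grossly different slopes with low noise are detected
  expect_lt(sim_two(1.5, 0.5, 0.5), 0.01)
})

test_that("ANCOVA input validation", {
  rec <- make_records(c(0, 1, -1, 2))
  expect_error(allometry_ancova(rec), "at least 2 populations")
  rec2 <- rbind(make_records(c(0, 1, -1), population = "A",
                             size = c(30, 30, 30)),
                make_records(c(0, 1, -1), population = "B"))
  expect_error(allometry_ancova(rec2), "constant within population 'A'")
})

test_that("categorical states tabulate in vocabulary order with percentages", {
  rec <- data.frame(
    specimen_id = sprintf("s%02d", 1:10), population = "Erwitte",
    trait = "fasciole",
    state = c(rep("absent", 4L), rep("parafasciole", 6L)))
  tab <- tabulate_states(rec)
  expect_equal(tab$state, trait_vocabularies()$fasciole)
  expect_equal(tab$percentage[tab$state == "absent"], 40)
  expect_equal(tab$percentage[tab$state == "parafasciole"], 60)
  expect_equal(sum(tab$percentage), 100, tolerance = 0.1)

  one <- tabulate_states(data.frame(specimen_id = "x", population = "P",
                                    trait = "labrum", state = "covered"))
  expect_equal(one$percentage[one$state == "covered"], 100)
  expect_error(tabulate_states(data.frame(specimen_id = "x",
                                          population = "P",
                                          trait = "labrum",
                                          state = "sealed")),
               "unknown state")
  # a population with no records for a trait is omitted with a warning
  two_pop <- data.frame(specimen_id = c("a", "b"),
                        population = c("P", "Q"),
                        trait = c("labrum", "fasciole"),
                        state = c("open", "absent"))
  w <- capture_warnings(tabulate_states(two_pop))
  expect_match(w, "omitted", all = TRUE)
  expect_length(w, 2L)
})
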
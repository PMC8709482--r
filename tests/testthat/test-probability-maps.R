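test_that("exceedance probability enumerates pairs correctly", {
  expect_equal(exceedance_probability(c(3, 5), c(1, 2, 4), "facilitation"), 5 / 6)
  expect_equal(exceedance_probability(c(3, 5), c(1, 2, 4), "inhibition"), 1 / 6)
  expect_equal(exceedance_probability(c(10, 11), c(1, 2), "facilitation"), 1)
  # strict comparisons: all-tied data is neither facilitation nor inhibition
  expect_equal(exceedance_probability(c(1, 1, 1), c(1, 1, 1), "facilitation"), 0)
  expect_equal(exceedance_probability(c(1, 1, 1), c(1, 1, 1), "inhibition"), 0)
  expect_error(exceedance_probability(numeric(0), 1), "non-empty")

  # exceeds-all interpretation: conditioned values beating every control
  expect_equal(
    exceedance_probability(c(3, 5), c(1, 2, 4), "facilitation", mode = "exceeds_all"),
    1 / 2)
})

test_that("facilitation, inhibition and tie probabilities sum to one exactly", {
  withr::with_seed(51, {
    for (i in 1:50) {
      cond <- sample(1:5, sample(2:8, 1), replace = TRUE)
      ctrl <- sample(1:5, sample(2:8, 1), replace = TRUE)
      cnt <- semp:::exceedance_counts(cond, ctrl)
      # rational bookkeeping: every pair is a facilitation, inhibition or tie
      tie <- sum(outer(cond, ctrl, "=="))
      expect_identical(cnt[["fac"]] + cnt[["inh"]] + tie, cnt[["total"]])
    }
  })
})

test_that("exceedance probability is shift monotone and label symmetric", {
  withr::with_seed(61, {
    for (i in 1:50) {
      cond <- rnorm(6); ctrl <- rnorm(8)
      p0 <- exceedance_probability(cond, ctrl, "facilitation")
      p1 <- exceedance_probability(cond + abs(rnorm(1)), ctrl, "facilitation")
      expect_gte(p1, p0)
      # swapping roles swaps the directions
      expect_equal(exceedance_probability(ctrl, cond, "inhibition"), p0)
    }
  })
})

test_that("probability maps have the full muscle x CTI grid", {
  p <- default_protocol(movements = "dorsiflexion", conditions = "auditory",
                        muscles = c("LVL", "LMH", "LTA", "LSOL"), rt_reps = 1,
                        seed = 2)
  x <- simulate_experiment(p, effect_model(), n_participants = 2, seed = 3)
  m <- build_probability_map(x, "dorsiflexion", "auditory")
  expect_s3_class(m, "semp_probability_map")
  expect_equal(nrow(m), 4 * 5) # 4 muscles x 5 CTIs
  expect_equal(m$p_facilitation + m$p_inhibition + m$p_tie, rep(1, 20))
  # pairwise comparisons per cell: 10 conditioned x 20 controls x 2 participants
  expect_true(all(m$n_comparisons <= 400))

  iso <- default_protocol(movements = "dorsiflexion", conditions = "isometric",
                          muscles = "LTA", rt_reps = 1, seed = 2)
  xi <- simulate_experiment(iso, effect_model(), n_participants = 2, seed = 3)
  mi <- build_probability_map(xi, "dorsiflexion", "isometric")
  expect_equal(nrow(mi), 1) # single isometric column
  expect_true(is.na(mi$cti_ms))

  expect_error(build_probability_map(x, "knee_flexion", "auditory"), "no doublets")
})

test_that("strong separation gives probability one, dominance classification works", {
  em <- effect_model(modulation = 4, amplitude_cv = 0.1)
  x <- simulate_experiment(mc_protocol(), em, n_participants = 5, seed = 17)
  m <- build_probability_map(x, "plantarflexion", "auditory")
  expect_equal(m$p_facilitation, rep(1, nrow(m)))

  expect_equal(classify_modulation(0.7, 0.2), "facilitation")
  expect_equal(classify_modulation(0.2, 0.7), "inhibition")
  expect_equal(classify_modulation(0.4, 0.4), "balanced")
  expect_equal(classify_modulation(c(0.9, 0.1), c(0.05, 0.8)),
               c("facilitation", "inhibition"))
})

test_that("render_outputs writes tables and one heatmap per map", {
  em <- effect_model(modulation = effect_table(cti_ms = 250, value = 3))
  x <- simulate_experiment(mc_protocol(), em, n_participants = 8, seed = 23)
  mod <- analyze_modulation(x)
  maps <- list(build_probability_map(x, "plantarflexion", "auditory"))
  out <- withr::local_tempdir()
  files <- render_outputs(mod, maps, out)
  expect_true(file.exists(file.path(out, "modulation.csv")))
  expect_true(file.exists(file.path(out, "probability_map.csv")))
  expect_true(file.exists(file.path(out, "significance_summary.csv")))
  expect_length(list.files(out, pattern = "^map_.*png$"), 1)

  sig <- as.data.frame(readr::read_csv(
    file.path(out, "significance_summary.csv"), show_col_types = FALSE))
  if (nrow(sig) > 0) {
    expect_equal(sig$connection_width, abs(sig$normalized_pct - 100))
  }

  # empty significant set -> header-only summary
  null_mod <- analyze_modulation(
    simulate_experiment(mc_protocol(), effect_model(), n_participants = 5, seed = 3))
  out2 <- withr::local_tempdir()
  render_outputs(null_mod[null_mod$significant, ], NULL, out2)
  sig2 <- readr::read_csv(file.path(out2, "significance_summary.csv"),
                          show_col_types = FALSE)
  expect_equal(nrow(sig2), 0)
})
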
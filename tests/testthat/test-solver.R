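small_cfg <- function(...) {
  imo_config(ions = 10, iterations = 60, solid_num = 10, ...)
}

test_that("trivial sequences give trivial optima", {
  fit <- run_imog("PPPPPPPPPP", small_cfg(), seed = 1)
  expect_identical(fit$best_energy, 0L)
  expect_identical(fit$status, "ok")

  fit <- run_imog("HPH", small_cfg(), seed = 1)
  expect_identical(fit$best_energy, -1L)
  expect_true(is_self_avoiding(fit$best_embedding)$valid)
})

test_that("runs are reproducible and internally consistent", {
  seq <- parse_hp("HHPHPHPHPH")
  a <- run_imog(seq, small_cfg(), seed = 7)
  b <- run_imog(seq, small_cfg(), seed = 7)
  expect_identical(a$best_conformation, b$best_conformation)
  expect_identical(a$history, b$history)
  expect_identical(a$best_energy, b$best_energy)

  # history is the best fitness so far: monotone non-increasing
  expect_true(all(diff(a$history) <= 0))
  # the reported embedding re-scores to the reported energy
  expect_identical(hp_energy(seq, a$best_conformation)$energy, a$best_energy)
  expect_identical(decode_conformation(a$best_conformation, seq),
                   a$best_embedding)

  c <- run_imog(seq, small_cfg(), seed = 8)
  expect_false(identical(a$history, c$history))
})

test_that("batches aggregate run statistics and derive per-run seeds", {
  seq <- parse_hp("HPPHPHPH")
  one <- run_batch(seq, small_cfg(runs = 1), seed = 3)
  expect_identical(one$best, as.integer(one$mean))
  expect_identical(nrow(one$per_run), 1L)

  b <- run_batch(seq, small_cfg(runs = 4), seed = 3)
  expect_identical(b$per_run$seed, 3:6)
  expect_identical(b$best, min(b$per_run$best_energy))
  expect_equal(b$mean, mean(b$per_run$best_energy))
  # the stored best fit is one of the runs and matches the batch best
  expect_identical(b$best_fit$best_energy, b$best)
})

test_that("batch best can never beat the exhaustive minimum", {
  set.seed(91)
  for (rep in 1:3) {
    seq <- random_hp(8)
    oracle <- enumerate_min_energy(seq)$min_energy
    b <- run_batch(seq, small_cfg(runs = 3), seed = rep)
    expect_gte(b$best, oracle)
  }
})

test_that("early stopping at a known target shortens the work", {
  seq <- parse_hp("HPH")
  cfg <- small_cfg(target_energy = -1, stop_at_target = TRUE)
  fit <- run_imog(seq, cfg, seed = 1)
  expect_identical(fit$best_energy, -1L)
  expect_lt(fit$iterations_used, cfg$iterations)
  b <- run_batch(seq, cfg, seed = 1, runs = 10)
  expect_lt(b$runs, 10L)
})

test_that("tidy and glance expose the documented columns", {
  seq <- parse_hp("HHPHPHPHPH", label = "demo")
  fit <- run_imog(seq, small_cfg(), seed = 2)
  g <- glance(fit)
  expect_identical(names(g),
                   c("label", "n", "best_energy", "contacts",
                     "iterations_used", "seed", "status"))
  expect_identical(g$label, "demo")
  expect_identical(g$contacts, -g$best_energy)
  ct <- tidy(fit)
  expect_identical(nrow(ct), -fit$best_energy)

  b <- run_batch(seq, small_cfg(runs = 2), seed = 2)
  expect_identical(names(tidy(b)),
                   c("run", "seed", "best_energy", "iterations_used"))
  expect_identical(glance(b)$runs, 2L)
})

test_that("benchmark driver tabulates against the published energies", {
  cfg <- small_cfg()
  res <- run_benchmark(2, cfg, seed = 1, runs = 1, use_targets = TRUE)
  expect_identical(nrow(res), 20L)
  expect_identical(res$stated_best_energy, hp_benchmarks(2)$stated_best_energy)
  expect_true(all(res$best <= 0))
})
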
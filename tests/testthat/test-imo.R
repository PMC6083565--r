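test_that("configuration validation lists offending fields", {
  cfg <- imo_config()
  expect_identical(cfg$ions, 100L)
  expect_identical(cfg$iterations, 2000L)
  expect_identical(cfg$greedy_prob, 0.25)
  expect_identical(cfg$solid_num, 50L)
  expect_identical(cfg$runs, 30L)
  expect_error(imo_config(greedy_prob = 2), "greedy_prob")
  expect_error(imo_config(ions = 0, reinit_prob = -1),
               "ions.*\n.*reinit_prob")
  expect_error(imo_config(solid_variant = "other"))
})

test_that("discretization rounds half away from zero and wraps cyclically", {
  expect_identical(discretize_directions(c(3.4, 6.7, 0.2)), c(3L, 1L, 6L))
  expect_identical(discretize_directions(c(0.5, 6.5, -0.5, 7.5)),
                   c(1L, 1L, 5L, 2L))
  m <- discretize_directions(matrix(c(1.2, 5.8, 6.6, 0.4), 2, 2))
  expect_true(is.matrix(m))
  expect_identical(as.vector(m), c(1L, 6L, 1L, 6L))
  set.seed(51)
  x <- stats::runif(500, -20, 20)
  d <- discretize_directions(x)
  expect_true(all(d >= 1L & d <= 6L))
  # wrapping the continuous coordinate first never changes the decoded label
  expect_identical(discretize_directions(((x - 1) %% 6) + 1), d)
})

test_that("the attraction force is sigmoid in inverse distance", {
  expect_equal(attraction_force(0.1), 1 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(attraction_force(0.1), 0.7311, tolerance = 1e-4)
  expect_identical(attraction_force(0), 1)
  expect_equal(attraction_force(1e9), 0.5, tolerance = 1e-6)
  d <- seq(0.01, 10, length.out = 200)
  f <- attraction_force(d)
  expect_true(all(diff(f) < 0))
  expect_true(all(f > 0.5 & f <= 1))
  expect_error(attraction_force(-1), "non-negative")
})

test_that("population initialization is uniform on [1,6] and seed-stable", {
  seq <- parse_hp("HHPHPHPHPHPHPH")
  cfg <- imo_config(ions = 20)
  set.seed(61)
  pop <- init_population(seq, cfg)
  expect_identical(dim(pop$A), c(20L, 13L))
  expect_identical(dim(pop$C), c(20L, 13L))
  expect_true(all(pop$A >= 1 & pop$A <= 6))
  expect_true(all(pop$C >= 1 & pop$C <= 6))
  expect_length(pop$fit_a, 20L)
  set.seed(61)
  pop2 <- init_population(seq, cfg)
  expect_identical(pop, pop2)
  expect_error(init_population(parse_hp("H"), cfg), "at least 2")
})

test_that("the liquid phase contracts by exactly (1 - AF) per coordinate", {
  seq <- parse_hp("HPHPHPH")
  cfg <- imo_config(ions = 15)
  set.seed(62)
  pop <- init_population(seq, cfg)
  best <- list(Abest = stats::runif(6, 1, 6), Cbest = stats::runif(6, 1, 6))
  before <- abs(sweep(pop$A, 2, best$Cbest))
  af <- attraction_force(before)
  moved <- liquid_phase_update(pop, best)
  after <- abs(sweep(moved$A, 2, best$Cbest))
  expect_equal(after, (1 - af) * before, tolerance = 1e-12)
  expect_true(all(after <= before))

  # an anion sitting on the best cation is a fixed point
  pop$A[1, ] <- best$Cbest
  moved <- liquid_phase_update(pop, best)
  expect_equal(moved$A[1, ], best$Cbest, tolerance = 1e-12)
})

test_that("the original solid phase only acts when its condition holds", {
  seq <- parse_hp("HPHPHPHP")
  cfg <- imo_config(ions = 10)
  set.seed(63)
  pop <- init_population(seq, cfg)
  best <- imogfold:::new_best_record()
  best <- imogfold:::update_best_record(best, pop)
  # force the ratio condition false: pretend the bests are far below worst/2
  off <- best
  off$abest_fit <- -100
  off$cbest_fit <- -100
  off$aworst_fit <- 10
  off$cworst_fit <- 10
  expect_identical(solid_phase_original(pop, off, seq, cfg), pop)

  on <- best
  on$abest_fit <- 6
  on$cbest_fit <- 6
  on$aworst_fit <- 8
  on$cworst_fit <- 8
  set.seed(64)
  out <- solid_phase_original(pop, on, seq, cfg)
  expect_false(identical(out$A, pop$A))
  expect_true(all(out$A >= 1 & out$A < 7))
  expect_true(all(out$C >= 1 & out$C < 7))
})

test_that("the improved solid phase fires only after both bests stall", {
  seq <- parse_hp("HPHPHPHPHP")
  cfg <- imo_config(ions = 12, solid_num = 5)
  set.seed(65)
  pop <- init_population(seq, cfg)
  best <- imogfold:::new_best_record()
  best <- imogfold:::update_best_record(best, pop)
  best$abest_stall <- 5L
  best$cbest_stall <- 99L
  expect_identical(solid_phase_improved(pop, best, seq, cfg), pop)

  best$abest_stall <- 6L
  set.seed(66)
  out <- solid_phase_improved(pop, best, seq, cfg)
  expect_false(identical(out$A, pop$A))
  expect_true(all(out$A >= 1 & out$A < 7))
  expect_true(all(out$C >= 1 & out$C < 7))
  # fitnesses were re-evaluated against the discretized coordinates
  expect_identical(out$fit_a,
                   imogfold:::fitness_batch(discretize_directions(out$A), seq))
})

test_that("best-record updates improve strictly and drift on plateaus", {
  pop <- list(A = matrix(2, 2, 3), C = matrix(3, 2, 3),
              fit_a = c(-2, -1), fit_c = c(0, -3))
  best <- imogfold:::new_best_record()
  best <- imogfold:::update_best_record(best, pop)
  expect_identical(best$abest_fit, -2)
  expect_identical(best$cbest_fit, -3)
  expect_identical(best$abest_stall, 0L)

  # equal fitness: the vector is adopted, but the stall counter still ticks
  pop2 <- list(A = matrix(5, 2, 3), C = matrix(6, 2, 3),
               fit_a = c(-2, 0), fit_c = c(-1, -1))
  best <- imogfold:::update_best_record(best, pop2)
  expect_identical(best$abest_fit, -2)
  expect_identical(best$Abest, rep(5, 3))
  expect_identical(best$abest_stall, 1L)
  # worse fitness: vector kept
  expect_identical(best$Cbest, rep(3, 3))
  expect_identical(best$cbest_stall, 1L)
})
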
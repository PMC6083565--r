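#' IMOG run configuration
#'
#' Tunables of the ions-motion optimizer with greedy local search. Defaults
#' are the published study settings: 100 anions and 100 cations, 2000
#' iterations, greedy per-position probability 0.25.
#'
#' @param ions Population size per charge (anions and cations each).
#' @param iterations Iteration budget of a single run.
#' @param greedy_prob Per-position selection probability of the greedy sweep.
#' @param solid_num Stall-length threshold: the improved solid phase fires
#'   when both global bests have gone unimproved for more than this many
#'   iterations.
#' @param reinit_prob Probability (the `rand3 < 0.05` restart clause) that
#'   an anion/cation pair is re-initialized uniformly inside the solid
#'   phase; all other pairs receive the greedy local search.
#' @param solid_variant `"improved"` (stall-triggered, with greedy; default)
#'   or `"original"` (fitness-ratio condition, re-initialization only).
#' @param runs Number of independent runs in a batch.
#' @param target_energy Optional known optimum; only used when
#'   `stop_at_target` is `TRUE`.
#' @param stop_at_target Stop a run (and a batch) early once `target_energy`
#'   is reached. Off by default.
#' @return A validated list of class `imo_config`.
#' @export
imo_config <- function(ions = 100L, iterations = 2000L, greedy_prob = 0.25,
                       solid_num = 50L, reinit_prob = 0.05,
                       solid_variant = c("improved", "original"),
                       runs = 30L, target_energy = NULL,
                       stop_at_target = FALSE) {
  solid_variant <- match.arg(solid_variant)
  cfg <- list(
    ions = as.integer(ions), iterations = as.integer(iterations),
    greedy_prob = as.numeric(greedy_prob), solid_num = as.integer(solid_num),
    reinit_prob = as.numeric(reinit_prob), solid_variant = solid_variant,
    runs = as.integer(runs),
    target_energy = if (is.null(target_energy)) NULL else as.numeric(target_energy),
    stop_at_target = isTRUE(stop_at_target)
  )
  problems <- character(0)
  if (is.na(cfg$ions) || cfg$ions < 1L) {
    problems <- c(problems, "ions: must be a positive integer")
  }
  if (is.na(cfg$iterations) || cfg$iterations < 1L) {
    problems <- c(problems, "iterations: must be a positive integer")
  }
  if (is.na(cfg$greedy_prob) || cfg$greedy_prob < 0 || cfg$greedy_prob > 1) {
    problems <- c(problems, "greedy_prob: must lie in [0, 1]")
  }
  if (is.na(cfg$solid_num) || cfg$solid_num < 1L) {
    problems <- c(problems, "solid_num: must be a positive integer")
  }
  if (is.na(cfg$reinit_prob) || cfg$reinit_prob < 0 || cfg$reinit_prob > 1) {
    problems <- c(problems, "reinit_prob: must lie in [0, 1]")
  }
  if (is.na(cfg$runs) || cfg$runs < 1L) {
    problems <- c(problems, "runs: must be a positive integer")
  }
  if (length(problems) > 0L) {
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  structure(cfg, class = "imo_config")
}

#' @export
print.imo_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<imo_config> ions = %d per charge, iterations = %d, greedy_prob = %g,\n",
    "  solid_num = %d, reinit_prob = %g, solid_variant = %s, runs = %d\n"),
    x$ions, x$iterations, x$greedy_prob, x$solid_num, x$reinit_prob,
    x$solid_variant, x$runs))
  invisible(x)
}

#' Discretize ion coordinates into direction labels
#'
#' Each real coordinate is rounded half-away-from-zero and wrapped cyclically
#' onto `{1..6}` via `((k - 1) mod 6) + 1`. Directions are cyclic on the
#' hexagon, so wrapping (rather than clamping) avoids biasing toward labels
#' 1 and 6.
#'
#' @param x Numeric vector or matrix of ion coordinates.
#' @return Integer labels in `{1..6}`, same shape as `x`.
#' @examples
#' discretize_directions(c(3.4, 6.7, 0.2))  # 3, 1, 6
#' @export
discretize_directions <- function(x) {
  k <- trunc(x + 0.5 * sign(x))
  out <- ((k - 1) %% 6) + 1
  if (is.matrix(x)) {
    out <- matrix(as.integer(out), nrow(x), ncol(x))
  } else {
    out <- as.integer(out)
  }
  out
}

# Cyclic wrap of continuous coordinates (period 6, fundamental domain [1, 7)).
# Commutes with discretize_directions, so decoded conformations are unchanged.
wrap_coords <- function(x) {
  ((x - 1) %% 6) + 1
}

#' Sigmoid attraction force
#'
#' The attraction between an ion and the opposite-charge best decays with
#' their per-coordinate distance `d` as `1 / (1 + exp(-0.1 / d))`, which is
#' `1` at `d = 0` (taken as the continuous limit) and tends to `0.5` as
#' `d` grows.
#'
#' @param distance Non-negative numeric vector of distances.
#' @return Forces in `(0.5, 1]`, same shape as `distance`.
#' @examples
#' attraction_force(0.1)   # ~0.7311
#' @export
attraction_force <- function(distance) {
  if (any(distance < 0, na.rm = TRUE)) {
    stop("distances must be non-negative", call. = FALSE)
  }
  out <- ifelse(distance == 0, 1, 1 / (1 + exp(-0.1 / distance)))
  dim(out) <- dim(distance)
  out
}

#' Initialize an ion population
#'
#' Anion and cation coordinate vectors are drawn uniformly on `[1, 6]`, one
#' coordinate per chain bond, and evaluated against the sequence.
#'
#' @param seq An [hp_seq()].
#' @param config An [imo_config()].
#' @return A list of class `imo_population`: matrices `A`, `C`
#'   (`ions` x `n - 1`) and fitness vectors `fit_a`, `fit_c`.
#' @export
init_population <- function(seq, config = imo_config()) {
  seq <- as_hp(seq)
  if (seq$n < 2L) {
    stop("sequences must have at least 2 residues", call. = FALSE)
  }
  d <- seq$n - 1L
  n <- config$ions
  pop <- list(
    A = matrix(stats::runif(n * d, 1, 6), n, d),
    C = matrix(stats::runif(n * d, 1, 6), n, d)
  )
  pop$fit_a <- fitness_batch(discretize_directions(pop$A), seq)
  pop$fit_c <- fitness_batch(discretize_directions(pop$C), seq)
  structure(pop, class = "imo_population")
}

new_best_record <- function() {
  list(
    Abest = NULL, Cbest = NULL,
    abest_fit = Inf, cbest_fit = Inf,
    aworst_fit = -Inf, cworst_fit = -Inf,
    abest_stall = 0L, cbest_stall = 0L
  )
}

# Index of a minimal fitness, chosen uniformly among ties so that plateau
# moves sample the current energy level without positional bias.
pick_min_index <- function(f) {
  i <- which(f == min(f))
  if (length(i) > 1L) sample(i, 1L) else i
}

# Update the global bests / current worsts and the stall counters from
# freshly evaluated fitnesses. A strictly better fitness replaces the best
# and resets its stall counter. An EQUAL fitness adopts the new vector but
# still counts as a stalled iteration: the counters track the best fitness
# value, while the position is free to drift across the plateaus that
# dominate HP contact landscapes (without this drift the optimizer gets
# pinned at the first conformation of each energy level).
update_best_record <- function(best, pop) {
  ia <- pick_min_index(pop$fit_a)
  ic <- pick_min_index(pop$fit_c)
  if (pop$fit_a[ia] < best$abest_fit) {
    best$abest_fit <- pop$fit_a[ia]
    best$Abest <- pop$A[ia, ]
    best$abest_stall <- 0L
  } else {
    if (pop$fit_a[ia] == best$abest_fit) best$Abest <- pop$A[ia, ]
    best$abest_stall <- best$abest_stall + 1L
  }
  if (pop$fit_c[ic] < best$cbest_fit) {
    best$cbest_fit <- pop$fit_c[ic]
    best$Cbest <- pop$C[ic, ]
    best$cbest_stall <- 0L
  } else {
    if (pop$fit_c[ic] == best$cbest_fit) best$Cbest <- pop$C[ic, ]
    best$cbest_stall <- best$cbest_stall + 1L
  }
  best$aworst_fit <- max(pop$fit_a)
  best$cworst_fit <- max(pop$fit_c)
  best
}

#' Liquid-phase attraction update
#'
#' Every anion coordinate moves toward the best cation by the fraction given
#' by the attraction force of their per-coordinate distance, and cations move
#' symmetrically toward the best anion. The update is a strict contraction:
#' the residual distance shrinks by the factor `1 - AF` in every coordinate.
#'
#' @param pop An `imo_population`.
#' @param best Best record holding `Abest` and `Cbest` (see [run_imog()]).
#' @return The updated population (fitnesses not re-evaluated).
#' @export
liquid_phase_update <- function(pop, best) {
  stopifnot(!is.null(best$Abest), !is.null(best$Cbest))
  cb <- matrix(best$Cbest, nrow(pop$A), ncol(pop$A), byrow = TRUE)
  ab <- matrix(best$Abest, nrow(pop$C), ncol(pop$C), byrow = TRUE)
  af <- attraction_force(abs(pop$A - cb))
  cf <- attraction_force(abs(pop$C - ab))
  pop$A <- pop$A + af * (cb - pop$A)
  pop$C <- pop$C + cf * (ab - pop$C)
  pop
}

# Phi-perturbation shared by both solid-phase variants: per individual,
# A_i += Phi1 * (Cbest - 1) or A_i += Phi1 * Cbest depending on rand1,
# cations symmetric. "Cbest - 1" subtracts the scalar 1 from every
# coordinate. Draws are per individual per invocation.
solid_perturb <- function(pop, best) {
  n <- nrow(pop$A)
  phi1 <- stats::runif(n, -1, 1)
  rand1 <- stats::runif(n)
  cb <- matrix(best$Cbest, n, ncol(pop$A), byrow = TRUE)
  pop$A <- pop$A + phi1 * (cb - as.numeric(rand1 > 0.5))
  phi2 <- stats::runif(n, -1, 1)
  rand2 <- stats::runif(n)
  ab <- matrix(best$Abest, n, ncol(pop$C), byrow = TRUE)
  pop$C <- pop$C + phi2 * (ab - as.numeric(rand2 > 0.5))
  pop
}

#' Original solid-phase strategy
#'
#' The fitness-ratio trigger: when `CbestFit >= CworstFit / 2` and
#' `AbestFit >= AworstFit / 2`, every individual receives the random
#' Phi-perturbation toward the opposite-charge best, and with probability
#' `reinit_prob` an anion/cation pair is re-initialized uniformly.
#' Coordinates are wrapped back into range. Provided for fidelity to the
#' original optimizer; the improved stall-triggered variant is the default
#' because the ratio condition is ill-behaved for negative fitnesses.
#'
#' @inheritParams liquid_phase_update
#' @param seq The [hp_seq()] being folded.
#' @param config An [imo_config()].
#' @return The updated population, fitnesses re-evaluated (unchanged when
#'   the trigger condition is false).
#' @export
solid_phase_original <- function(pop, best, seq, config = imo_config()) {
  seq <- as_hp(seq)
  triggered <- (best$cbest_fit >= best$cworst_fit / 2) &&
    (best$abest_fit >= best$aworst_fit / 2)
  if (!triggered) {
    return(pop)
  }
  pop <- solid_perturb(pop, best)
  d <- ncol(pop$A)
  rand3 <- stats::runif(nrow(pop$A))
  for (i in which(rand3 < config$reinit_prob)) {
    pop$A[i, ] <- stats::runif(d, 1, 6)
    pop$C[i, ] <- stats::runif(d, 1, 6)
  }
  pop$A <- wrap_coords(pop$A)
  pop$C <- wrap_coords(pop$C)
  pop$fit_a <- fitness_batch(discretize_directions(pop$A), seq)
  pop$fit_c <- fitness_batch(discretize_directions(pop$C), seq)
  pop
}

#' Improved solid-phase strategy with greedy local search
#'
#' Fires while both global bests have stalled for more than `solid_num`
#' iterations (the stall counters track the best fitness values and are
#' reset only by a strict improvement, so once the search stagnates the
#' phase runs every iteration until something better is found). Each
#' individual receives the Phi-perturbation; afterwards, with probability
#' `reinit_prob` the anion/cation pair is re-initialized uniformly (the
#' restart clause of the original phase), otherwise both decoded
#' conformations are improved by one greedy sweep ([greedy_sweep()]) and
#' written back as real coordinates.
#'
#' @inheritParams solid_phase_original
#' @return The updated population with fitnesses re-evaluated (unchanged
#'   when the stall condition is not met).
#' @export
solid_phase_improved <- function(pop, best, seq, config = imo_config()) {
  seq <- as_hp(seq)
  if (!(best$abest_stall > config$solid_num &&
        best$cbest_stall > config$solid_num)) {
    return(pop)
  }
  pop <- solid_perturb(pop, best)
  pop$A <- wrap_coords(pop$A)
  pop$C <- wrap_coords(pop$C)
  d <- ncol(pop$A)
  n <- nrow(pop$A)
  reinit <- stats::runif(n) < config$reinit_prob
  for (i in which(!reinit)) {
    pop$A[i, ] <- as.numeric(
      greedy_sweep(seq, discretize_directions(pop$A[i, ]),
                   prob = config$greedy_prob))
    pop$C[i, ] <- as.numeric(
      greedy_sweep(seq, discretize_directions(pop$C[i, ]),
                   prob = config$greedy_prob))
  }
  n_re <- sum(reinit)
  if (n_re > 0) {
    pop$A[reinit, ] <- stats::runif(n_re * d, 1, 6)
    pop$C[reinit, ] <- stats::runif(n_re * d, 1, 6)
  }
  pop$fit_a <- fitness_batch(discretize_directions(pop$A), seq)
  pop$fit_c <- fitness_batch(discretize_directions(pop$C), seq)
  pop
}

# Greedy sweeps repeated until the fitness stops improving: the local
# search applied to a decoded best solution while the search is stalled.
# A random sweep failing to improve does not prove a single-label local
# optimum (it only visited a subset of positions), so convergence is
# verified with one deterministic full-position sweep before stopping.
drill_conformation <- function(seq, directions, config) {
  is_h <- is_h_vec(seq)
  f <- eval_dirs_cpp(directions, is_h)$fitness
  repeat {
    nd <- greedy_sweep(seq, directions, prob = config$greedy_prob)
    nf <- eval_dirs_cpp(nd, is_h)$fitness
    if (nf < f) {
      directions <- nd
      f <- nf
      next
    }
    full <- greedy_sweep_cpp(directions, is_h, seq_along(directions))
    ff <- eval_dirs_cpp(full, is_h)$fitness
    if (ff < f) {
      directions <- as.integer(full)
      f <- ff
    } else {
      return(list(directions = directions, fitness = f))
    }
  }
}
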
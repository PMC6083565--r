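#' Run the IMOG optimizer on an HP sequence
#'
#' One full optimization run: initialize the anion/cation populations,
#' then iterate evaluation, global-best bookkeeping, the liquid-phase
#' attraction update and the conditional solid phase (stall-triggered with
#' greedy local search by default) for the configured number of iterations.
#' The best self-avoiding conformation ever evaluated is returned.
#'
#' @param seq An [hp_seq()] or a string accepted by [parse_hp()].
#' @param config An [imo_config()].
#' @param seed Integer seed; every source of randomness in the run derives
#'   from it, so identical seed and configuration reproduce the run exactly.
#' @return An object of class `imog_fit` with fields `best_energy`,
#'   `best_conformation`, `best_embedding` (tibble), `history` (best fitness
#'   so far per iteration, non-increasing), `seed`, `iterations_used`,
#'   `status` (`"ok"`, or `"no-valid-fold"` when no self-avoiding decode was
#'   ever seen).
#' @examples
#' fit <- run_imog("HPH", imo_config(ions = 10, iterations = 20), seed = 1)
#' fit$best_energy
#' @export
run_imog <- function(seq, config = imo_config(), seed = 1L) {
  seq <- as_hp(seq)
  if (seq$n < 2L) {
    stop("sequences must have at least 2 residues", call. = FALSE)
  }
  stopifnot(inherits(config, "imo_config"))
  set.seed(as.integer(seed))

  pop <- init_population(seq, config)
  best <- new_best_record()
  history <- numeric(config$iterations)
  best_fit <- Inf
  best_valid_fit <- Inf
  best_dirs <- NULL
  iterations_used <- config$iterations
  target <- if (config$stop_at_target) config$target_energy else NULL

  record_pop <- function(pop) {
    for (side in c("fit_a", "fit_c")) {
      f <- pop[[side]]
      i <- which.min(f)
      if (f[i] < best_valid_fit && f[i] <= 0) {
        best_valid_fit <<- f[i]
        m <- if (side == "fit_a") pop$A else pop$C
        best_dirs <<- discretize_directions(m[i, ])
      }
      if (f[i] < best_fit) best_fit <<- f[i]
    }
  }

  evaluate <- function(pop) {
    pop$fit_a <- fitness_batch(discretize_directions(pop$A), seq)
    pop$fit_c <- fitness_batch(discretize_directions(pop$C), seq)
    pop
  }

  solid_phase <- if (config$solid_variant == "improved") {
    solid_phase_improved
  } else {
    solid_phase_original
  }

  for (it in seq_len(config$iterations)) {
    pop <- evaluate(pop)                      # step 2: fitness (Eq. 9)
    record_pop(pop)
    best <- update_best_record(best, pop)     # step 3: bests + stall counters
    pop <- liquid_phase_update(pop, best)     # step 4: attraction moves
    fired <- config$solid_variant == "improved" &&
      best$abest_stall > config$solid_num &&
      best$cbest_stall > config$solid_num
    pop <- solid_phase(pop, best, seq, config)  # step 5: conditional escape
    # stall counters are reset only by an improvement of the respective
    # best, so the escape phase keeps firing while the search is stalled
    if (fired) {
      record_pop(pop)
      # local search of the incumbent best solutions themselves
      da <- drill_conformation(seq, discretize_directions(best$Abest), config)
      if (da$fitness <= 0 && da$fitness < best_valid_fit) {
        best_valid_fit <- da$fitness
        best_dirs <- da$directions
      }
      if (da$fitness < best$abest_fit) {
        best$Abest <- as.numeric(da$directions)
        best$abest_fit <- da$fitness
        best$abest_stall <- 0L
      }
      dc <- drill_conformation(seq, discretize_directions(best$Cbest), config)
      if (dc$fitness <= 0 && dc$fitness < best_valid_fit) {
        best_valid_fit <- dc$fitness
        best_dirs <- dc$directions
      }
      if (dc$fitness < best$cbest_fit) {
        best$Cbest <- as.numeric(dc$directions)
        best$cbest_fit <- dc$fitness
        best$cbest_stall <- 0L
      }
      if (best$abest_fit < best_fit) best_fit <- best$abest_fit
      if (best$cbest_fit < best_fit) best_fit <- best$cbest_fit
    }
    history[it] <- min(best_fit, best_valid_fit)
    if (!is.null(target) && best_valid_fit <= target) {
      iterations_used <- it
      history <- history[seq_len(it)]
      break
    }
  }
  if (iterations_used == config$iterations) {
    pop <- evaluate(pop)                      # score the final update
    record_pop(pop)
    history[config$iterations] <-
      min(history[config$iterations], best_fit, best_valid_fit)
  }

  if (is.null(best_dirs)) {
    return(structure(
      list(seq = seq, config = config, seed = as.integer(seed),
           best_energy = NA_integer_, best_conformation = NULL,
           best_embedding = NULL, history = history,
           iterations_used = iterations_used, status = "no-valid-fold"),
      class = "imog_fit"))
  }
  structure(
    list(
      seq = seq, config = config, seed = as.integer(seed),
      best_energy = as.integer(best_valid_fit),
      best_conformation = best_dirs,
      best_embedding = decode_conformation(best_dirs, seq),
      history = history,
      iterations_used = iterations_used,
      status = "ok"
    ),
    class = "imog_fit"
  )
}

#' @export
print.imog_fit <- function(x, ...) {
  cat(sprintf("<imog_fit> %s (n = %d), seed %d\n",
              if (nzchar(x$seq$label)) x$seq$label else "HP sequence",
              x$seq$n, x$seed))
  if (x$status == "ok") {
    cat(sprintf("  best energy %d after %d iterations\n  directions: %s\n",
                x$best_energy, x$iterations_used,
                paste(x$best_conformation, collapse = " ")))
  } else {
    cat("  no self-avoiding fold found\n")
  }
  invisible(x)
}

#' Batch of independent IMOG runs
#'
#' Runs the optimizer `runs` times with per-run seeds `seed, seed + 1, ...`
#' and aggregates the best and mean of the per-run best energies, the
#' batch statistic reported for stability comparisons.
#'
#' @inheritParams run_imog
#' @param runs Number of runs; defaults to `config$runs` (30).
#' @return An object of class `imog_batch`: tibble `per_run` (columns `run`,
#'   `seed`, `best_energy`, `iterations_used`), scalars `best` and `mean`,
#'   plus the sequence and configuration. When `config$stop_at_target` is
#'   set and a run reaches `config$target_energy`, remaining runs are
#'   skipped.
#' @examples
#' b <- run_batch("HPH", imo_config(ions = 10, iterations = 20, runs = 3),
#'                seed = 1)
#' b$best
#' @export
run_batch <- function(seq, config = imo_config(), seed = 1L,
                      runs = config$runs) {
  seq <- as_hp(seq)
  stopifnot(inherits(config, "imo_config"))
  runs <- as.integer(runs)
  if (is.na(runs) || runs < 1L) stop("`runs` must be >= 1", call. = FALSE)
  fits <- vector("list", runs)
  used <- 0L
  for (k in seq_len(runs)) {
    fits[[k]] <- run_imog(seq, config, seed = as.integer(seed) + k - 1L)
    used <- k
    if (config$stop_at_target && !is.null(config$target_energy) &&
        !is.na(fits[[k]]$best_energy) &&
        fits[[k]]$best_energy <= config$target_energy) {
      break
    }
  }
  fits <- fits[seq_len(used)]
  per_run <- tibble::tibble(
    run = seq_len(used),
    seed = as.integer(seed) + seq_len(used) - 1L,
    best_energy = vapply(fits, function(f) as.integer(f$best_energy),
                         integer(1)),
    iterations_used = vapply(fits, function(f) f$iterations_used, integer(1))
  )
  best_idx <- if (all(is.na(per_run$best_energy))) 1L else
    which.min(per_run$best_energy)
  structure(
    list(
      seq = seq, config = config, seed = as.integer(seed),
      runs = used,
      per_run = per_run,
      best = min(per_run$best_energy, na.rm = TRUE),
      mean = mean(per_run$best_energy, na.rm = TRUE),
      best_fit = fits[[best_idx]]
    ),
    class = "imog_batch"
  )
}

#' @export
print.imog_batch <- function(x, ...) {
  cat(sprintf("<imog_batch> %s (n = %d): %d run(s), best %d, mean %.2f\n",
              if (nzchar(x$seq$label)) x$seq$label else "HP sequence",
              x$seq$n, x$runs, x$best, x$mean))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-run results of a batch
#'
#' @param x An `imog_batch`.
#' @param ... Unused.
#' @return The per-run tibble: `run`, `seed`, `best_energy`,
#'   `iterations_used`.
#' @export
tidy.imog_batch <- function(x, ...) x$per_run

#' H-H contacts of the best fold
#'
#' @param x An `imog_fit`.
#' @param ... Unused.
#' @return Tibble of contact pairs `i`, `j` of the best conformation.
#' @export
tidy.imog_fit <- function(x, ...) {
  if (x$status != "ok") {
    return(tibble::tibble(i = integer(0), j = integer(0)))
  }
  hp_contacts(x$seq, x$best_embedding)
}

#' One-row summary of a run
#'
#' @param x An `imog_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `label`, `n`, `best_energy`, `contacts`,
#'   `iterations_used`, `seed`, `status`.
#' @export
glance.imog_fit <- function(x, ...) {
  tibble::tibble(
    label = x$seq$label, n = x$seq$n,
    best_energy = x$best_energy,
    contacts = if (x$status == "ok") -x$best_energy else NA_integer_,
    iterations_used = x$iterations_used,
    seed = x$seed, status = x$status
  )
}

#' One-row summary of a batch
#'
#' @param x An `imog_batch`.
#' @param ... Unused.
#' @return A one-row tibble: `label`, `n`, `runs`, `best`, `mean`.
#' @export
glance.imog_batch <- function(x, ...) {
  tibble::tibble(
    label = x$seq$label, n = x$seq$n, runs = x$runs,
    best = x$best, mean = x$mean
  )
}

#' Benchmark a built-in table with IMOG
#'
#' Runs a batch for every sequence of a packaged benchmark table and tabulates
#' best and mean energies next to the published best-known values.
#'
#' @param table Benchmark table, `1` or `2`.
#' @param config An [imo_config()].
#' @param seed Master seed; sequence `k` uses `seed + (k - 1) * 1000` so runs
#'   never share streams.
#' @param runs Runs per sequence.
#' @param use_targets When `TRUE` (default) each batch stops early once the
#'   published best-known energy for that sequence is reached.
#' @return A tibble: `table`, `index`, `label`, `n`, `stated_best_energy`,
#'   `best`, `mean`, `runs_used`.
#' @export
run_benchmark <- function(table = 2, config = imo_config(), seed = 1L,
                          runs = config$runs, use_targets = TRUE) {
  bench <- hp_benchmarks(table)
  rows <- lapply(seq_len(nrow(bench)), function(k) {
    target <- bench$stated_best_energy[k]
    cfg <- config
    if (use_targets && !is.na(target)) {
      cfg$target_energy <- as.numeric(target)
      cfg$stop_at_target <- TRUE
    }
    b <- run_batch(bench$hp[[k]], cfg,
                   seed = as.integer(seed) + (k - 1L) * 1000L, runs = runs)
    tibble::tibble(
      table = bench$table[k], index = bench$index[k], label = bench$label[k],
      n = bench$stated_length[k],
      stated_best_energy = target,
      best = b$best, mean = b$mean, runs_used = b$runs
    )
  })
  dplyr::bind_rows(rows)
}
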
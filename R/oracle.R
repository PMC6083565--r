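#' Exact minimum energy by exhaustive enumeration
#'
#' Depth-first enumeration of every self-avoiding walk of `n - 1` steps on
#' the triangular lattice, with incremental contact counting and an
#' occupied-cell pruning grid. Feasible only for short chains (the search
#' space grows like the SAW connective constant to the power `n`), so `n` is
#' capped. With `symmetry_fix` (default) the first step is pinned to label 1
#' and the first off-axis step to the upper half-plane, exploiting the 12
#' point-group isometries of the lattice without changing the minimum.
#'
#' @param seq An [hp_seq()] or string accepted by [parse_hp()].
#' @param symmetry_fix Fix the 12-fold lattice symmetry (default `TRUE`).
#' @param cap Refuse sequences longer than this (default 13); the optimizer
#'   is the tool for longer chains.
#' @return An object of class `hp_enumeration`: list with `n`,
#'   `walks_visited`, `nodes`, `min_energy`, `argmin` (one optimal
#'   conformation), `symmetry_fixed`.
#' @examples
#' enumerate_min_energy("HHH")$min_energy   # -1
#' @export
enumerate_min_energy <- function(seq, symmetry_fix = TRUE, cap = 13L) {
  seq <- as_hp(seq)
  if (seq$n > cap) {
    stop("sequence length ", seq$n, " exceeds the enumeration cap (", cap,
         "); use the optimizer for long chains", call. = FALSE)
  }
  res <- enumerate_min_energy_cpp(is_h_vec(seq), isTRUE(symmetry_fix))
  structure(
    list(
      n = seq$n,
      label = seq$label,
      walks_visited = res$walks_visited,
      nodes = res$nodes,
      min_energy = as.integer(res$min_energy),
      argmin = as.integer(res$argmin),
      symmetry_fixed = isTRUE(symmetry_fix)
    ),
    class = "hp_enumeration"
  )
}

#' @export
print.hp_enumeration <- function(x, ...) {
  cat(sprintf(
    "<hp_enumeration> n = %d: min energy %d over %s self-avoiding walks%s\n",
    x$n, x$min_energy, format(x$walks_visited, big.mark = ","),
    if (x$symmetry_fixed) " (symmetry-fixed)" else ""))
  invisible(x)
}

#' Count self-avoiding walks on the triangular lattice
#'
#' @param steps Number of steps (walks from the origin of this length).
#' @param symmetry_fix Count only walks with the first step pinned to label 1
#'   and the first off-axis step in the upper half-plane.
#' @param cap Refuse step counts above this (default 12).
#' @return The walk count (double, as counts overflow integers quickly).
#' @examples
#' count_saws(1)  # 6
#' count_saws(2)  # 30
#' @export
count_saws <- function(steps, symmetry_fix = FALSE, cap = 12L) {
  steps <- as.integer(steps)
  if (is.na(steps) || steps < 0L) {
    stop("`steps` must be a non-negative integer", call. = FALSE)
  }
  if (steps > cap) {
    stop("`steps` exceeds the enumeration cap (", cap, ")", call. = FALSE)
  }
  count_saws_cpp(steps, isTRUE(symmetry_fix))
}
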
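#' Greedy re-optimization of a single direction label
#'
#' Evaluates the full-chain fitness with the direction at `index` replaced by
#' each of the six labels and keeps the best. Changing one label rigidly
#' moves the whole chain tail, so the chain is re-decoded and re-scored in
#' full, including the collision policy. The incumbent label is kept on
#' ties; among non-incumbent ties the smallest label wins.
#'
#' @param seq An [hp_seq()] (or string accepted by [parse_hp()]).
#' @param directions Integer conformation of length `n - 1`.
#' @param index Position to re-optimize, in `1..(n - 1)`.
#' @return The (possibly improved) conformation; its fitness never exceeds
#'   the input's.
#' @examples
#' greedy_point_search("HPH", c(1, 2), 2)
#' @export
greedy_point_search <- function(seq, directions, index) {
  seq <- as_hp(seq)
  directions <- validate_conformation(directions, n = seq$n)
  index <- as.integer(index)
  if (length(index) != 1L || is.na(index) || index < 1L ||
      index > length(directions)) {
    stop("`index` must lie in 1..", length(directions), call. = FALSE)
  }
  as.integer(greedy_sweep_cpp(directions, is_h_vec(seq), index))
}

#' Greedy sweep over chain positions
#'
#' Visits positions `1..(n - 1)` in chain order; each is selected
#' independently with probability `prob` (the published per-position mutation
#' probability is 0.25) and re-optimized with [greedy_point_search()]
#' sequentially, so later searches see earlier improvements. Fitness never
#' increases.
#'
#' @inheritParams greedy_point_search
#' @param prob Per-position selection probability in `[0, 1]`.
#' @return The (possibly improved) conformation.
#' @export
greedy_sweep <- function(seq, directions, prob = 0.25) {
  seq <- as_hp(seq)
  directions <- validate_conformation(directions, n = seq$n)
  if (!is.numeric(prob) || length(prob) != 1L || is.na(prob) ||
      prob < 0 || prob > 1) {
    stop("`prob` must lie in [0, 1]", call. = FALSE)
  }
  picked <- which(stats::runif(length(directions)) < prob)
  if (length(picked) == 0L) {
    return(directions)
  }
  as.integer(greedy_sweep_cpp(directions, is_h_vec(seq), picked))
}
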
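#' H-H contacts of an embedded chain
#'
#' A contact is a pair of hydrophobic residues `(i, j)` with `j >= i + 2`
#' (not consecutive along the chain) whose lattice points are neighbors. On
#' the triangular lattice `j = i + 2` pairs can be contacts, unlike on the
#' square lattice. Each contact contributes `-1` (in units of the contact
#' energy magnitude) to the conformation energy.
#'
#' @param seq An [hp_seq()].
#' @param emb A self-avoiding embedding of `seq` (see
#'   [decode_conformation()]).
#' @return A tibble with columns `i`, `j` (1-based residue indices,
#'   `i < j`), one row per contact.
#' @examples
#' s <- parse_hp("HPH")
#' hp_contacts(s, decode_conformation(c(1, 3)))
#' @export
hp_contacts <- function(seq, emb) {
  seq <- as_hp(seq)
  xy <- embedding_coords(emb)
  if (nrow(xy) != seq$n) {
    stop("embedding has ", nrow(xy), " points but the sequence has ",
         seq$n, " residues", call. = FALSE)
  }
  pairs <- contact_pairs_cpp(xy, is_h_vec(seq))
  tibble::tibble(i = pairs[, 1], j = pairs[, 2])
}

#' Contact energy of a conformation
#'
#' Decodes the conformation and scores it. For a self-avoiding fold the
#' energy is minus the number of H-H contacts and equals the optimization
#' fitness. A colliding (invalid) decode gets the surrogate fitness
#' `+collisions` (the number of coincident residue pairs) with contacts
#' ignored, so every valid fold strictly dominates every invalid one while
#' the optimizer still senses progress toward fewer collisions.
#'
#' @param seq An [hp_seq()] (or string accepted by [parse_hp()]).
#' @param directions Integer conformation of length `n - 1`.
#' @return An object of class `hp_energy`: list with `energy` (integer, `NA`
#'   for invalid folds), `fitness` (numeric surrogate used by the
#'   optimizer), `contacts`, `collisions`, `valid`.
#' @examples
#' hp_energy("HPH", c(1, 3))   # energy -1
#' hp_energy("HPH", c(1, 4))   # invalid, fitness +1
#' @export
hp_energy <- function(seq, directions) {
  seq <- as_hp(seq)
  directions <- validate_conformation(directions, n = seq$n)
  res <- eval_dirs_cpp(directions, is_h_vec(seq))
  structure(
    list(
      energy = if (res$valid) as.integer(-res$contacts) else NA_integer_,
      fitness = res$fitness,
      contacts = as.integer(res$contacts),
      collisions = as.integer(res$collisions),
      valid = res$valid
    ),
    class = "hp_energy"
  )
}

#' @export
print.hp_energy <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("<hp_energy> E = %d (%d H-H contacts), self-avoiding\n",
                x$energy, x$contacts))
  } else {
    cat(sprintf("<hp_energy> invalid fold: %d collision pair(s), fitness +%g\n",
                x$collisions, x$fitness))
  }
  invisible(x)
}

# Fitness of many direction rows at once (matrix: individuals x bonds).
fitness_batch <- function(dirs_matrix, seq) {
  fitness_batch_cpp(dirs_matrix, is_h_vec(seq))
}
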
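#' Triangular-lattice direction map
#'
#' Axial coordinates `(q, r)` are used throughout: each lattice point has six
#' neighbors, reached by the six unit step vectors. Direction labels `1..6`
#' enumerate these vectors in counterclockwise cyclic order starting from
#' `(1, 0)`:
#' `1 -> (1,0)`, `2 -> (0,1)`, `3 -> (-1,1)`, `4 -> (-1,0)`, `5 -> (0,-1)`,
#' `6 -> (1,-1)`.
#'
#' @return A 6 x 2 integer matrix of step vectors; row `k` is the vector for
#'   label `k`, columns are `q` and `r`.
#' @export
tri_directions <- function() {
  m <- matrix(c(1L, 0L,
                0L, 1L,
                -1L, 1L,
                -1L, 0L,
                0L, -1L,
                1L, -1L),
              ncol = 2, byrow = TRUE,
              dimnames = list(as.character(1:6), c("q", "r")))
  m
}

#' Neighbors of a lattice point
#'
#' @param p Integer vector `c(q, r)`.
#' @return A 6 x 2 integer matrix: the six lattice points adjacent to `p`.
#' @examples
#' tri_neighbors(c(0, 0))
#' @export
tri_neighbors <- function(p) {
  stopifnot(length(p) == 2, p == round(p))
  sweep(tri_directions(), 2, as.integer(p), `+`) * 1L
}

#' Are two lattice points adjacent?
#'
#' @param p,q Integer vectors `c(q, r)`.
#' @return `TRUE` iff `q` is one of the six neighbors of `p`.
#' @export
tri_adjacent <- function(p, q) {
  d <- as.integer(q) - as.integer(p)
  dirs <- tri_directions()
  any(dirs[, 1] == d[1] & dirs[, 2] == d[2])
}

validate_conformation <- function(directions, n = NULL) {
  directions <- as.integer(directions)
  if (anyNA(directions) || (length(directions) > 0 &&
                            (min(directions) < 1L || max(directions) > 6L))) {
    stop("direction labels must all lie in {1..6}", call. = FALSE)
  }
  if (!is.null(n) && length(directions) != n - 1L) {
    stop("conformation must have length n - 1 = ", n - 1L,
         " (got ", length(directions), ")", call. = FALSE)
  }
  directions
}

#' Decode a conformation into lattice coordinates
#'
#' A conformation is the genotype: one direction label in `{1..6}` per chain
#' bond. Decoding places residue 1 at the origin and walks the chain; all
#' points are returned even when the walk collides with itself (validity is
#' checked separately with [is_self_avoiding()]).
#'
#' @param directions Integer vector of labels in `{1..6}` (length `n - 1`).
#' @param seq Optional [hp_seq()]; when supplied its residues are attached
#'   and its length must match.
#' @return A tibble with columns `index`, `q`, `r` (and `residue` when `seq`
#'   is given): the embedding, `length(directions) + 1` rows.
#' @examples
#' decode_conformation(c(1, 3))
#' @export
decode_conformation <- function(directions, seq = NULL) {
  directions <- validate_conformation(directions,
                                      n = if (is.null(seq)) NULL else seq$n)
  coords <- decode_dirs_cpp(directions)
  out <- tibble::tibble(
    index = seq_len(nrow(coords)),
    q = coords[, 1],
    r = coords[, 2]
  )
  if (!is.null(seq)) out$residue <- seq$residues
  out
}

embedding_coords <- function(emb) {
  if (is.matrix(emb)) {
    storage.mode(emb) <- "integer"
    return(emb)
  }
  if (is.data.frame(emb) && all(c("q", "r") %in% names(emb))) {
    return(cbind(as.integer(emb$q), as.integer(emb$r)))
  }
  stop("an embedding must be a matrix or data frame with columns q and r",
       call. = FALSE)
}

#' Self-avoidance check
#'
#' @param emb An embedding: matrix or data frame with columns `q`, `r`
#'   (as produced by [decode_conformation()]).
#' @return A list with `valid` (`TRUE` iff all points are pairwise distinct)
#'   and `collisions` (number of unordered coincident point pairs).
#' @examples
#' is_self_avoiding(decode_conformation(c(1, 4)))  # revisits the origin
#' @export
is_self_avoiding <- function(emb) {
  xy <- embedding_coords(emb)
  key <- paste(xy[, 1], xy[, 2])
  tab <- table(key)
  collisions <- sum(choose(tab, 2))
  list(valid = collisions == 0, collisions = as.integer(collisions))
}
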
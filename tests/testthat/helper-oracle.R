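# Independent reference implementation of the contact-energy model, coded
# as a plain double loop over residue pairs. Used as the oracle against
# which the package's grid-based kernel is checked; deliberately shares
# nothing with the implementation beyond the canonical direction map.

ref_step_vectors <- list(
  c(1L, 0L), c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(0L, -1L), c(1L, -1L)
)

ref_decode <- function(dirs) {
  n <- length(dirs) + 1L
  pts <- matrix(0L, n, 2)
  for (k in seq_along(dirs)) {
    pts[k + 1L, ] <- pts[k, ] + ref_step_vectors[[dirs[k]]]
  }
  pts
}

ref_adjacent <- function(p, q) {
  d <- q - p
  any(vapply(ref_step_vectors, function(v) all(v == d), logical(1)))
}

# Returns list(fitness, valid, contacts, collisions) under the same policy:
# valid folds score -contacts, colliding folds score +collision pairs.
ref_energy <- function(residues, dirs) {
  pts <- ref_decode(dirs)
  n <- nrow(pts)
  collisions <- 0L
  contacts <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (all(pts[i, ] == pts[j, ])) collisions <- collisions + 1L
      if (j >= i + 2L && residues[i] == "H" && residues[j] == "H" &&
          ref_adjacent(pts[i, ], pts[j, ])) {
        contacts <- contacts + 1L
      }
    }
  }
  if (collisions > 0L) {
    list(fitness = collisions, valid = FALSE, contacts = contacts,
         collisions = collisions)
  } else {
    list(fitness = -contacts, valid = TRUE, contacts = contacts,
         collisions = 0L)
  }
}

random_hp <- function(n) {
  hp_seq(sample(c("H", "P"), n, replace = TRUE))
}

random_dirs <- function(n) {
  sample(6L, n - 1L, replace = TRUE)
}

# The 12 point-group isometries of the triangular lattice as direction-label
# permutations: rotations add a constant (mod 6); the reflection across the
# axis of label 1 swaps 2<->6 and 3<->5.
label_isometries <- function() {
  reflect <- c(1L, 6L, 5L, 4L, 3L, 2L)
  out <- list()
  for (k in 0:5) {
    rot <- ((seq_len(6) - 1L + k) %% 6L) + 1L
    out[[length(out) + 1L]] <- rot
    out[[length(out) + 1L]] <- rot[reflect]
  }
  out
}

# The same isometries acting on axial coordinates: R60 (q,r) -> (-r, q+r),
# reflection across the x-axis (q,r) -> (q+r, -r).
apply_axial_isometry <- function(pts, k, mirror) {
  if (mirror) {
    pts <- cbind(pts[, 1] + pts[, 2], -pts[, 2])
  }
  for (i in seq_len(k)) {
    pts <- cbind(-pts[, 2], pts[, 1] + pts[, 2])
  }
  pts
}
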
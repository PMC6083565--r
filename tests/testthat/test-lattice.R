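test_that("the direction map is a bijection onto the six unit steps", {
  m <- tri_directions()
  expect_identical(dim(m), c(6L, 2L))
  expect_identical(nrow(unique(m)), 6L)
  nb <- tri_neighbors(c(0, 0))
  expect_identical(nrow(nb), 6L)
  # the map's vectors ARE the neighbor set of the origin
  expect_setequal(paste(m[, 1], m[, 2]), paste(nb[, 1], nb[, 2]))
  expect_identical(unname(m["1", ]), c(1L, 0L))
  expect_identical(unname(m["4", ]), c(-1L, 0L))
})

test_that("lattice adjacency is symmetric", {
  set.seed(11)
  for (i in 1:25) {
    p <- sample(-5:5, 2, replace = TRUE)
    q <- sample(-5:5, 2, replace = TRUE)
    expect_identical(tri_adjacent(p, q), tri_adjacent(q, p))
  }
  p <- c(2, -3)
  nb <- tri_neighbors(p)
  for (k in 1:6) expect_true(tri_adjacent(p, nb[k, ]))
  expect_false(tri_adjacent(p, p))
})

test_that("decoding walks the chain from the origin", {
  e <- decode_conformation(c(1, 1, 1))
  expect_identical(e$q, c(0L, 1L, 2L, 3L))
  expect_identical(e$r, c(0L, 0L, 0L, 0L))

  e <- decode_conformation(c(1, 4))
  expect_identical(e$q[3], 0L)
  expect_identical(e$r[3], 0L)

  e <- decode_conformation(c(1, 3))
  expect_identical(unlist(e[3, c("q", "r")], use.names = FALSE), c(0L, 1L))
  # first and third points are lattice-adjacent: an i/i+2 contact is possible
  expect_true(tri_adjacent(c(e$q[1], e$r[1]), c(e$q[3], e$r[3])))

  expect_identical(nrow(decode_conformation(integer(0))), 1L)
  expect_error(decode_conformation(c(1, 7)), "\\{1..6\\}")
})

test_that("self-avoidance counts coincident pairs", {
  expect_identical(is_self_avoiding(decode_conformation(c(1, 1))),
                   list(valid = TRUE, collisions = 0L))
  expect_identical(is_self_avoiding(decode_conformation(c(1, 4))),
                   list(valid = FALSE, collisions = 1L))
  # walking the same bond back and forth piles up many coincidences
  r <- is_self_avoiding(decode_conformation(c(1, 4, 1, 4)))
  expect_false(r$valid)
  expect_identical(r$collisions, 2L + 2L)
})

test_that("decode length is always one more than the direction count", {
  set.seed(21)
  for (n in c(2L, 5L, 13L, 30L)) {
    dirs <- random_dirs(n)
    expect_identical(nrow(decode_conformation(dirs)), n)
  }
})

test_that("the published example code embeds validly under some labeling", {
  # direction string printed for the 14-residue example fold; the figure's
  # own label->vector assignment is unknown, but a valid embedding must
  # exist under at least one of the 720 bijections
  code <- c(4, 5, 6, 2, 6, 2, 1, 3, 2, 4, 3, 5, 4)
  all_perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      rest <- all_perms(v[-i])
      out <- c(out, lapply(rest, function(r) c(v[i], r)))
    }
    out
  }
  valid_under <- 0L
  for (p in all_perms(1:6)) {
    emb <- decode_conformation(p[code])
    if (is_self_avoiding(emb)$valid) valid_under <- valid_under + 1L
  }
  expect_gt(valid_under, 0L)
})

test_that("lattice isometries preserve collisions and contacts", {
  set.seed(31)
  seq <- random_hp(12)
  for (rep in 1:5) {
    dirs <- random_dirs(12)
    pts <- as.matrix(decode_conformation(dirs)[, c("q", "r")])
    base_valid <- is_self_avoiding(pts)
    base_e <- ref_energy(seq$residues, dirs)
    for (k in 0:5) {
      for (mirror in c(FALSE, TRUE)) {
        tp <- apply_axial_isometry(pts, k, mirror)
        expect_identical(is_self_avoiding(tp), base_valid)
        if (base_valid$valid) {
          expect_identical(nrow(hp_contacts(seq, tp)), base_e$contacts)
        }
      }
    }
    # translation invariance
    shifted <- sweep(pts, 2, c(7L, -3L), `+`)
    expect_identical(is_self_avoiding(shifted), base_valid)
  }
})
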
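#' Expand binary repeat notation
#'
#' HP benchmark tables print sequences as binary strings with a compact
#' repeat notation: a parenthesized group followed by a repeat count, e.g.
#' `"(010)_2"` expands to `"010010"`. Underscores around the count are
#' decorative and ignored, so `"(010)_2_"`, `"(010)_2"` and `"(010)2"` are
#' equivalent. Groups may not be nested.
#'
#' @param raw A single string over `0`, `1`, parenthesized groups and repeat
#'   counts.
#' @return The fully expanded binary string.
#' @examples
#' expand_hp_notation("(010)_2_")          # "010010"
#' expand_hp_notation("1(100)_2_1(001)_5_1")
#' @export
expand_hp_notation <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L, !is.na(raw))
  chars <- strsplit(raw, "", fixed = TRUE)[[1]]
  out <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("0", "1")) {
      out <- c(out, ch)
      i <- i + 1L
    } else if (ch == "(") {
      close <- NA_integer_
      j <- i + 1L
      while (j <= n) {
        if (chars[j] == "(") {
          stop("nested group opened at position ", j, call. = FALSE)
        }
        if (chars[j] == ")") {
          close <- j
          break
        }
        if (!chars[j] %in% c("0", "1")) {
          stop("character '", chars[j], "' inside group at position ", j,
               call. = FALSE)
        }
        j <- j + 1L
      }
      if (is.na(close)) {
        stop("unbalanced parenthesis opened at position ", i, call. = FALSE)
      }
      group <- chars[(i + 1L):(close - 1L)]
      if (length(group) == 0L || close == i + 1L) {
        stop("empty group at position ", i, call. = FALSE)
      }
      k <- close + 1L
      if (k <= n && chars[k] == "_") k <- k + 1L
      digs <- character(0)
      while (k <= n && grepl("[0-9]", chars[k])) {
        digs <- c(digs, chars[k])
        k <- k + 1L
      }
      if (length(digs) == 0L) {
        stop("missing repeat count after group closing at position ", close,
             call. = FALSE)
      }
      if (k <= n && chars[k] == "_") k <- k + 1L
      times <- as.integer(paste(digs, collapse = ""))
      out <- c(out, rep(group, times))
      i <- k
    } else if (ch == ")") {
      stop("unbalanced closing parenthesis at position ", i, call. = FALSE)
    } else if (ch %in% c(" ", "\t")) {
      i <- i + 1L
    } else {
      stop("unexpected character '", ch, "' at position ", i, call. = FALSE)
    }
  }
  paste(out, collapse = "")
}

#' Construct an HP sequence
#'
#' An `hp_seq` is an ordered chain of residues, each hydrophobic (`H`) or
#' polar (`P`) — the optimization instance of the HP lattice folding problem.
#'
#' @param residues Character vector over `"H"`/`"P"`.
#' @param label Free-text identifier.
#' @return An object of class `hp_seq` with fields `residues`, `n`, `label`.
#' @export
hp_seq <- function(residues, label = "") {
  residues <- toupper(as.character(residues))
  if (length(residues) < 1L) {
    stop("an HP sequence must contain at least one residue", call. = FALSE)
  }
  bad <- setdiff(unique(residues), c("H", "P"))
  if (length(bad) > 0L) {
    stop("invalid residue symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(residues = residues, n = length(residues), label = as.character(label)),
    class = "hp_seq"
  )
}

#' @export
print.hp_seq <- function(x, ...) {
  lab <- if (nzchar(x$label)) paste0(" '", x$label, "'") else ""
  cat(sprintf("<hp_seq%s> n = %d, H = %d\n%s\n",
              lab, x$n, sum(x$residues == "H"),
              paste(x$residues, collapse = "")))
  invisible(x)
}

#' @export
format.hp_seq <- function(x, ...) paste(x$residues, collapse = "")

#' @export
length.hp_seq <- function(x) x$n

is_h_vec <- function(seq) {
  stopifnot(inherits(seq, "hp_seq"))
  seq$residues == "H"
}

#' Parse an HP sequence string
#'
#' Accepts the letter alphabet `H`/`P` (case-insensitive) or a binary string
#' over `0`/`1`, optionally in the parenthesized repeat notation understood by
#' [expand_hp_notation()]. Binary digits map to residues via `one_is`:
#' the default treats `1` as hydrophobic and `0` as polar.
#'
#' @param text A single sequence string.
#' @param one_is `"H"` (default) or `"P"`: residue type the digit `1` denotes.
#' @param label Optional identifier attached to the result.
#' @return An [hp_seq()] object.
#' @examples
#' parse_hp("HHPPHPHPHPHPHP")
#' parse_hp("1(10)_5_1")   # binary repeat notation, 1 -> H
#' @export
parse_hp <- function(text, one_is = c("H", "P"), label = "") {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  one_is <- match.arg(one_is)
  text <- gsub("[ \t]", "", text)
  if (!nzchar(text)) {
    stop("empty sequence", call. = FALSE)
  }
  if (grepl("[()]", text)) {
    text <- expand_hp_notation(text)
  }
  chars <- toupper(strsplit(text, "", fixed = TRUE)[[1]])
  is_letter <- chars %in% c("H", "P")
  is_digit <- chars %in% c("0", "1")
  if (all(is_letter)) {
    residues <- chars
  } else if (all(is_digit)) {
    zero_is <- setdiff(c("H", "P"), one_is)
    residues <- ifelse(chars == "1", one_is, zero_is)
  } else {
    bad <- which(!(is_letter | is_digit))[1]
    if (any(is_letter) && any(is_digit)) {
      stop("mixed H/P and 0/1 alphabets in sequence", call. = FALSE)
    }
    stop("invalid symbol '", chars[bad], "' at position ", bad, call. = FALSE)
  }
  hp_seq(residues, label = label)
}

#' Coerce to an HP sequence
#'
#' @param x An `hp_seq`, or a string accepted by [parse_hp()].
#' @param ... Passed on to [parse_hp()] for character input.
#' @return An [hp_seq()] object.
#' @export
as_hp <- function(x, ...) {
  if (inherits(x, "hp_seq")) return(x)
  if (is.character(x) && length(x) == 1L) return(parse_hp(x, ...))
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to hp_seq", call. = FALSE)
}

# Benchmark instances as printed: binary repeat notation, stated length and
# stated best-known 2D triangular-lattice energy (NA where the table prints
# none). Transcribed once by hand; locked by the length-consistency test.
benchmark_table_1 <- function() {
  tibble::tribble(
    ~index, ~stated_length, ~stated_best_energy, ~raw_notation,
    1L, 20L, -15L, "(101001)_2_0110(01)_2_",
    2L, 24L, -17L, "1(100)_2_1(001)_5_1",
    3L, 25L, -12L, "(001)_2_(100001)_3_1",
    4L, 36L, -24L, "0(0011)_2_(0)_5_(1)_7_(001100)_2_100",
    5L, 48L, -43L, "001(0011)_2_(0)_5_(1)_10_(0)_6_(1100)_2_100(1)_5_",
    6L, 50L, -41L, "1(10)_4_(1)_4_(0100)_3_00(1000)_2_10111(10)_4_11",
    7L, 60L, NA_integer_, "001110(1)_8_000(1)_10_01000(1)_12_(0)_4_(1)_6_011010",
    8L, 64L, NA_integer_, "(1)_12_(01)_2_00(1100)_2_(1001)_2_(100)_2_(1100)_2_(10)_2_(1)_12_"
  )
}

benchmark_table_2 <- function() {
  tibble::tribble(
    ~index, ~stated_length, ~stated_best_energy, ~raw_notation,
    1L, 12L, -11L, "1(10)_5_1",
    2L, 14L, -11L, "1100(10)_5_",
    3L, 14L, -11L, "1(100)_2_(10)_3_1",
    4L, 16L, -11L, "110(100)_4_1",
    5L, 16L, -11L, "1(100)_2_(10)_3_010",
    6L, 17L, -11L, "1(100)_5_1",
    7L, 17L, -17L, "1(11)_7_11",
    8L, 20L, -17L, "1(100)_2_(10)_3_(01)_3_1",
    9L, 20L, -17L, "1(10)_4_1(001)_3_1",
    10L, 21L, -17L, "1(100)_2_(10100)_2_1011",
    11L, 21L, -17L, "110(100)_2_(10)_2_(100)_2_11",
    12L, 21L, -17L, "1100(10)_3_(01)_2_(001)_2_1",
    13L, 22L, -17L, "1(100)_2_(10)_3_(010)_2_011",
    14L, 23L, -25L, "11(10)_9_111",
    15L, 24L, -17L, "1(100)_7_11",
    16L, 24L, -25L, "11(10)_3_(01)_7_11",
    17L, 24L, -25L, "11(10)_4_(01)_6_11",
    18L, 30L, -25L, "11(100)_4_1(01001)_2_00111",
    19L, 30L, -25L, "11(100)_3_(10)_2_(01)_2_(001)_3_11",
    20L, 37L, -29L, "11(100)_3_(10)_2_1(001)_3_(0)_5_(10)_2_111"
  )
}

#' Built-in HP benchmark instances
#'
#' The 28 classic 2D triangular-lattice HP benchmark sequences, printed in
#' binary repeat notation together with their stated lengths and best-known
#' energies (two entries of the first set have no published energy and carry
#' `NA`). The digit convention is `1` = hydrophobic, `0` = polar.
#'
#' @param table `1`, `2`, or `c(1, 2)` (default) for both benchmark sets.
#' @return A tibble with columns `table`, `index`, `label`, `stated_length`,
#'   `stated_best_energy`, `raw_notation`, `sequence` (expanded H/P string)
#'   and `hp` (list-column of [hp_seq()] objects).
#' @examples
#' hp_benchmarks(2)
#' @export
hp_benchmarks <- function(table = c(1, 2)) {
  table <- as.integer(table)
  if (length(table) < 1L || !all(table %in% c(1L, 2L))) {
    stop("`table` must be 1, 2 or c(1, 2)", call. = FALSE)
  }
  pieces <- lapply(sort(unique(table)), function(t) {
    df <- if (t == 1L) benchmark_table_1() else benchmark_table_2()
    df$table <- t
    df
  })
  out <- dplyr::bind_rows(pieces)
  out$label <- sprintf("T%dS%d", out$table, out$index)
  out$hp <- lapply(seq_len(nrow(out)), function(i) {
    parse_hp(out$raw_notation[i], one_is = "H", label = out$label[i])
  })
  out$sequence <- vapply(out$hp, format, character(1))
  out[, c("table", "index", "label", "stated_length", "stated_best_energy",
          "raw_notation", "sequence", "hp")]
}

#' Read HP sequences from a file
#'
#' Two plain-text dialects are understood: tab-separated lines
#' `label<TAB>sequence`, or FASTA-style records whose header lines start with
#' `>`. Sequences may be H/P letters or binary repeat notation.
#'
#' @param path File path.
#' @param one_is Digit convention, see [parse_hp()].
#' @return A tibble with columns `label`, `sequence` and `hp` (list-column of
#'   [hp_seq()] objects).
#' @export
read_hp_sequences <- function(path, one_is = c("H", "P")) {
  one_is <- match.arg(one_is)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("no sequences found in ", path, call. = FALSE)
  }
  if (any(startsWith(lines, ">"))) {
    heads <- which(startsWith(lines, ">"))
    labels <- sub("^>\\s*", "", lines[heads])
    bounds <- c(heads, length(lines) + 1L)
    seqs <- vapply(seq_along(heads), function(i) {
      from <- bounds[i] + 1L
      to <- bounds[i + 1L] - 1L
      if (from > to) {
        stop("FASTA record '", labels[i], "' has no sequence lines",
             call. = FALSE)
      }
      paste(trimws(lines[from:to]), collapse = "")
    }, character(1))
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    two <- vapply(parts, length, integer(1)) >= 2L
    labels <- ifelse(two, vapply(parts, `[[`, character(1), 1L), "")
    seqs <- vapply(seq_along(parts), function(i) {
      if (two[i]) parts[[i]][[2]] else parts[[i]][[1]]
    }, character(1))
  }
  hp <- lapply(seq_along(seqs), function(i) {
    parse_hp(seqs[i], one_is = one_is, label = labels[i])
  })
  tibble::tibble(
    label = labels,
    sequence = vapply(hp, format, character(1)),
    hp = hp
  )
}
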
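#' Load an IMOG configuration from YAML or JSON
#'
#' Unspecified fields take the published defaults (100 ions per charge, 2000
#' iterations, greedy probability 0.25). Unknown fields are rejected, and
#' out-of-range values produce a validation error listing every offending
#' field.
#'
#' @param path Path to a YAML (or JSON, a YAML subset) file; an empty file
#'   yields the default configuration.
#' @return An [imo_config()].
#' @export
load_imog_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) {
    stop("configuration file must contain a mapping of fields", call. = FALSE)
  }
  allowed <- names(formals(imo_config))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown) > 0L) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(imo_config, vals)
}

#' Save an IMOG configuration to YAML
#'
#' @param config An [imo_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_imog_config <- function(config, path) {
  stopifnot(inherits(config, "imo_config"))
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  yaml::write_yaml(vals, path)
  invisible(path)
}

run_manifest <- function(seq, config, seed) {
  tf <- tempfile()
  on.exit(unlink(tf), add = TRUE)
  writeLines(format(seq), tf)
  list(
    package = "imogfold",
    version = as.character(utils::packageVersion("imogfold")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input_checksum = unname(tools::md5sum(tf)),
    seed = as.integer(seed),
    config = unclass(config)[!vapply(unclass(config), is.null, logical(1))]
  )
}

fit_record <- function(fit) {
  list(
    seed = fit$seed,
    status = fit$status,
    best_energy = fit$best_energy,
    iterations_used = fit$iterations_used,
    directions = fit$best_conformation,
    coordinates = if (is.null(fit$best_embedding)) NULL else
      list(q = fit$best_embedding$q, r = fit$best_embedding$r)
  )
}

#' Serialize a single run to JSON
#'
#' The file embeds the sequence, configuration, result and a manifest
#' (package version, timestamp, input checksum, seed) so every result is
#' traceable to what produced it. Energies are written as integers.
#'
#' @param fit An `imog_fit` from [run_imog()].
#' @param path Output path; when `NULL` the JSON string is returned instead.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
write_run_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "imog_fit"))
  obj <- list(
    sequence = format(fit$seq),
    label = fit$seq$label,
    result = fit_record(fit),
    manifest = run_manifest(fit$seq, fit$config, fit$seed)
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", digits = NA,
                           pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' Serialize a batch to JSON
#'
#' @param batch An `imog_batch` from [run_batch()].
#' @param path Output path; when `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
write_batch_json <- function(batch, path = NULL) {
  stopifnot(inherits(batch, "imog_batch"))
  obj <- list(
    sequence = format(batch$seq),
    label = batch$seq$label,
    best = batch$best,
    mean = round(batch$mean, 2),
    per_run = lapply(seq_len(nrow(batch$per_run)), function(k) {
      as.list(batch$per_run[k, ])
    }),
    best_result = fit_record(batch$best_fit),
    manifest = run_manifest(batch$seq, batch$config, batch$seed)
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", digits = NA,
                           pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' Read a result JSON written by this package
#'
#' @param path File written by [write_run_json()] or [write_batch_json()].
#' @return The parsed list.
#' @export
read_result_json <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
}

#' Batch summary as a Best/Mean TSV table
#'
#' One row per batch, columns `label`, `n`, `best` and `mean` (two decimal
#' places), mirroring the Best/Mean stability tables of the HP benchmark
#' literature.
#'
#' @param batches An `imog_batch` or list of them.
#' @param path Output path; when `NULL` the TSV lines are returned.
#' @return `path` invisibly, or a character vector of lines.
#' @export
write_batch_tsv <- function(batches, path = NULL) {
  if (inherits(batches, "imog_batch")) batches <- list(batches)
  rows <- vapply(batches, function(b) {
    sprintf("%s\t%d\t%d\t%.2f",
            if (nzchar(b$seq$label)) b$seq$label else format(b$seq),
            b$seq$n, b$best, b$mean)
  }, character(1))
  lines <- c("label\tn\tbest\tmean", rows)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}

#' Write an embedding as TSV
#'
#' Columns `index`, `q`, `r`, `residue` (1-based residue order, axial lattice
#' coordinates).
#'
#' @param emb Embedding tibble from [decode_conformation()] (with residues).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embedding_tsv <- function(emb, path) {
  stopifnot(is.data.frame(emb), all(c("index", "q", "r") %in% names(emb)))
  utils::write.table(emb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an embedding TSV
#'
#' @param path File written by [write_embedding_tsv()].
#' @return An embedding tibble.
#' @export
read_embedding_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

# Cartesian drawing coordinates of the triangular lattice.
axial_to_cart <- function(q, r) {
  list(x = q + r / 2, y = r * sqrt(3) / 2)
}

#' ASCII rendering of a fold
#'
#' Residues are drawn on a character grid (`H` hydrophobic, `P` polar, with
#' the chain start marked by lower case); each lattice row is offset by one
#' column to suggest the triangular geometry.
#'
#' @param seq An [hp_seq()].
#' @param directions Conformation of length `n - 1`.
#' @return Character vector of lines, invisibly printed with `cat()` when
#'   auto-printed.
#' @export
render_fold_ascii <- function(seq, directions) {
  seq <- as_hp(seq)
  emb <- decode_conformation(directions, seq)
  col <- 2L * emb$q + emb$r          # doubled-width columns keep rows aligned
  row <- emb$r
  col <- col - min(col)
  row <- max(row) - row
  grid <- matrix(" ", nrow = max(row) + 1L, ncol = max(col) + 1L)
  for (k in seq_len(nrow(emb))) {
    ch <- emb$residue[k]
    if (k == 1L) ch <- tolower(ch)
    grid[row[k] + 1L, col[k] + 1L] <- ch
  }
  apply(grid, 1, paste, collapse = "")
}

#' SVG rendering of a fold
#'
#' Backbone as solid segments, H-H contacts as red dotted segments,
#' hydrophobic residues as filled dark circles and polar residues as open
#' circles. Output is plain-text SVG.
#'
#' @param seq An [hp_seq()].
#' @param directions Conformation of length `n - 1`.
#' @param path Output path; when `NULL` the SVG string is returned.
#' @param scale Pixels per lattice unit.
#' @return `path` invisibly, or the SVG string.
#' @export
render_fold_svg <- function(seq, directions, path = NULL, scale = 40) {
  seq <- as_hp(seq)
  emb <- decode_conformation(directions, seq)
  cart <- axial_to_cart(emb$q, emb$r)
  x <- cart$x * scale
  y <- -cart$y * scale
  pad <- scale
  x <- x - min(x) + pad
  y <- y - min(y) + pad
  w <- max(x) + pad
  h <- max(y) + pad
  seg <- function(i, j, style) {
    sprintf('<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" %s/>',
            x[i], y[i], x[j], y[j], style)
  }
  backbone <- vapply(seq_len(nrow(emb) - 1L), function(k) {
    seg(k, k + 1L, 'stroke="black" stroke-width="2"')
  }, character(1))
  ct <- hp_contacts(seq, emb)
  contact_lines <- if (nrow(ct) > 0) {
    vapply(seq_len(nrow(ct)), function(k) {
      seg(ct$i[k], ct$j[k],
          'stroke="red" stroke-width="1.5" stroke-dasharray="3,4"')
    }, character(1))
  } else character(0)
  nodes <- vapply(seq_len(nrow(emb)), function(k) {
    fill <- if (emb$residue[k] == "H") "#333333" else "#ffffff"
    sprintf(paste0('<circle cx="%.1f" cy="%.1f" r="%.1f" fill="%s" ',
                   'stroke="black"/>'),
            x[k], y[k], scale * 0.22, fill)
  }, character(1))
  labels <- sprintf(
    '<text x="%.1f" y="%.1f" font-size="%.1f" text-anchor="middle">%d</text>',
    x, y - scale * 0.3, scale * 0.25, emb$index)
  svg <- c(
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%.0f" ',
                   'height="%.0f" viewBox="0 0 %.0f %.0f">'), w, h, w, h),
    backbone, contact_lines, nodes, labels, "</svg>")
  if (is.null(path)) return(paste(svg, collapse = "\n"))
  writeLines(svg, path)
  invisible(path)
}
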
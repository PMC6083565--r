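#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Draw an embedded fold with ggplot2
#'
#' Backbone as a solid path, H-H contacts as red dotted segments, residues
#' as points (filled for hydrophobic, open for polar), on the true
#' triangular-lattice geometry.
#'
#' @param seq An [hp_seq()].
#' @param directions Conformation of length `n - 1`.
#' @return A ggplot object.
#' @export
plot_fold <- function(seq, directions) {
  seq <- as_hp(seq)
  emb <- decode_conformation(directions, seq)
  cart <- axial_to_cart(emb$q, emb$r)
  df <- tibble::tibble(x = cart$x, y = cart$y, residue = emb$residue,
                       index = emb$index)
  seg <- tibble::tibble(
    x = df$x[-nrow(df)], y = df$y[-nrow(df)],
    xend = df$x[-1], yend = df$y[-1]
  )
  ct <- hp_contacts(seq, emb)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  if (nrow(ct) > 0) {
    cseg <- tibble::tibble(
      x = df$x[ct$i], y = df$y[ct$i], xend = df$x[ct$j], yend = df$y[ct$j]
    )
    p <- p + ggplot2::geom_segment(
      data = cseg,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      colour = "red", linetype = "dotted", linewidth = 0.6)
  }
  p +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      colour = "grey30", linewidth = 0.8) +
    ggplot2::geom_point(ggplot2::aes(fill = .data$residue),
                        shape = 21, size = 4, colour = "black") +
    ggplot2::scale_fill_manual(values = c(H = "grey20", P = "white")) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = NULL)
}

#' Plot an optimizer run
#'
#' @param object An `imog_fit`.
#' @param type `"fold"` (the best conformation; default) or `"history"`
#'   (best fitness so far per iteration).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.imog_fit <- function(object, type = c("fold", "history"), ...) {
  type <- match.arg(type)
  if (type == "fold") {
    if (object$status != "ok") {
      stop("run found no self-avoiding fold; nothing to draw", call. = FALSE)
    }
    return(plot_fold(object$seq, object$best_conformation) +
             ggplot2::ggtitle(sprintf("E = %d", object$best_energy)))
  }
  df <- tibble::tibble(iteration = seq_along(object$history),
                       best_fitness = object$history)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration,
                                   y = .data$best_fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "iteration", y = "best fitness so far") +
    ggplot2::theme_minimal()
}

#' Plot per-run best energies of a batch
#'
#' @param object An `imog_batch`.
#' @param ... Unused.
#' @return A ggplot object (per-run best energies with the batch best and
#'   mean marked).
#' @export
autoplot.imog_batch <- function(object, ...) {
  df <- object$per_run
  ggplot2::ggplot(df, ggplot2::aes(x = .data$run, y = .data$best_energy)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$best, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = object$mean, colour = "red") +
    ggplot2::labs(x = "run", y = "best energy") +
    ggplot2::theme_minimal()
}
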
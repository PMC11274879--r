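# Base-graphics displays for the main result objects.

#' Plot an oligomer size distribution
#'
#' Bar plot of the propensities with SEM error bars when available.
#'
#' @param x A `size_distribution`.
#' @param max_size Largest oligomer order shown (default: last non-zero).
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plot.size_distribution <- function(x, max_size = NULL, ...) {
  p <- x$propensity
  if (is.null(max_size)) max_size <- max(c(1L, which(p > 0)))
  p <- p[seq_len(max_size)]
  mid <- graphics::barplot(p, names.arg = seq_len(max_size),
                           xlab = "oligomer order n",
                           ylab = sprintf("%s propensity", x$kind), ...)
  if (!is.null(x$sem)) {
    s <- x$sem[seq_len(max_size)]
    graphics::arrows(mid, p - s, mid, p + s, angle = 90, code = 3,
                     length = 0.03)
  }
  invisible(mid)
}

#' Plot a free-energy surface
#'
#' Heatmap of W over the two reaction coordinates; unoccupied bins are
#' blank.
#'
#' @param x A `free_energy_surface`.
#' @param xlab,ylab Axis labels.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.free_energy_surface <- function(x,
                                     xlab = "hydrophobic SASA (A^2)",
                                     ylab = "N-C distance (A)", ...) {
  graphics::image(x$breaks1, x$breaks2, x$W, col = grDevices::hcl.colors(
    64, "viridis", rev = TRUE), xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Plot a contact map
#'
#' Heatmap of mean contact counts over residue pairs.
#'
#' @param x A `contact_map`.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.contact_map <- function(x, ...) {
  L <- nrow(x$map)
  graphics::image(seq_len(L), seq_len(L), x$map,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "residue i", ylab = "residue j",
                  main = sprintf("%smolecular contacts, %d-mer", x$kind,
                                 x$state), ...)
  invisible(x)
}
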
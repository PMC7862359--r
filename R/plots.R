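# Base-graphics rendering of component planes (red = high, blue = low).

#' Plot component planes
#'
#' Draws one or more component planes with the conventional colour coding:
#' red pixels are high values of the variable, blue low.
#'
#' @param grid A trained `som_grid` (or a `bdk_model`'s `$grid`).
#' @param variables Variables to draw (indices or names); default all.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the list of plane matrices.
#' @export
plot_component_planes <- function(grid, variables = NULL, ...) {
  if (is.null(variables)) {
    variables <- if (!is.null(grid$var_names)) grid$var_names
                 else seq_len(grid$N)
  }
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(64)
  nv <- length(variables)
  mfrow <- c(ceiling(nv / 3), min(nv, 3))
  old <- graphics::par(mfrow = mfrow, mar = c(1, 1, 2, 1))
  on.exit(graphics::par(old))
  planes <- lapply(variables, function(v) {
    p <- component_plane(grid, v)
    graphics::image(seq_len(grid$X), seq_len(grid$Y), p, col = pal,
                    axes = FALSE, xlab = "", ylab = "",
                    main = if (is.character(v)) v else
                      grid$var_names[v] %||% paste("var", v), ...)
    p
  })
  invisible(planes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
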
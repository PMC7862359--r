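# Per-variable z-score normalisation for map training.

#' Fit a z-score normaliser
#'
#' Computes per-variable mean and standard deviation over the training
#' records so each variable can be scaled to mean 0, variance 1 before map
#' training. The *population* variance convention (divisor `K`) is used, so
#' the transformed training matrix has unit variance exactly.
#'
#' @param records Numeric matrix or data frame, records in rows.
#' @return Object of class `som_normalizer` with fields `mean`, `sd`,
#'   `variables`.
#' @export
fit_normalizer <- function(records) {
  x <- as.matrix(records)
  stopifnot(nrow(x) >= 2)
  mu <- colMeans(x)
  sdev <- sqrt(colMeans(sweep(x, 2, mu)^2))
  if (any(sdev <= 0)) {
    bad <- colnames(x)[sdev <= 0]
    if (is.null(bad)) bad <- which(sdev <= 0)
    stop("constant variable(s) cannot be normalised: ",
         paste(bad, collapse = ", "))
  }
  structure(list(mean = mu, sd = sdev, variables = colnames(x)),
            class = "som_normalizer")
}

#' Apply or invert a z-score normaliser
#'
#' @param params A [fit_normalizer()] result.
#' @param records Numeric matrix/data frame (records in rows) or a single
#'   record as a numeric vector.
#' @return Transformed records, same shape as the input.
#' @export
apply_normalizer <- function(params, records) {
  if (is.null(dim(records))) {
    (as.numeric(records) - params$mean) / params$sd
  } else {
    x <- as.matrix(records)
    sweep(sweep(x, 2, params$mean), 2, params$sd, "/")
  }
}

#' @rdname apply_normalizer
#' @export
invert_normalizer <- function(params, records) {
  if (is.null(dim(records))) {
    as.numeric(records) * params$sd + params$mean
  } else {
    x <- as.matrix(records)
    sweep(sweep(x, 2, params$sd, "*"), 2, params$mean, "+")
  }
}
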
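# Supervised map training: bi-directional Kohonen (BDK) networks couple a
# feature grid with a class-membership grid. Early in training the BMU
# search is dominated by the class part, later by the feature part, so
# class structure organises the map before features refine it.

#' Train a bi-directional Kohonen (BDK) model
#'
#' Joint training of a feature weight grid and a class-membership grid.
#' At epoch `t` of `T`, the BMU of a record minimises the mixed squared
#' distance `(t/T) * d2_features + (1 - t/T) * d2_class`, where the class
#' part compares the node's class-membership vector with the record's
#' one-hot label. Both grids then receive the Gaussian-neighbourhood
#' update towards the record (features) and its one-hot label (classes).
#' Class-membership vectors start uniform and, being convex combinations
#' of one-hot targets, stay non-negative and sum to one at every node.
#' The per-node majority label (largest class weight) defines the map's
#' class regions.
#'
#' @param Z Numeric matrix of normalised records, one per row.
#' @param labels Class label per record (factor or character; no missing
#'   values allowed).
#' @param grid_shape Integer `c(X, Y)`.
#' @param schedule A [training_schedule()].
#' @param norm Optional `som_normalizer` to attach.
#' @return Object of class `bdk_model`: `grid` (the feature `som_grid`),
#'   `class_weights` (nodes x classes), `classes`, `node_label` (majority
#'   label per node).
#' @export
train_bdk <- function(Z, labels, grid_shape = c(10L, 10L),
                      schedule = training_schedule(), norm = NULL) {
  Z <- as.matrix(Z)
  if (anyNA(labels)) stop("every record must carry a class label")
  labels <- as.factor(labels)
  stopifnot(nrow(Z) == length(labels))
  classes <- levels(labels)
  L <- length(classes)
  onehot <- diag(L)[as.integer(labels), , drop = FALSE]
  K <- nrow(Z)
  X <- grid_shape[1]; Y <- grid_shape[2]; M <- X * Y
  sigma <- if (is.null(schedule$sigma0)) max(X, Y) / 2 else schedule$sigma0
  alpha <- schedule$alpha0
  coords <- grid_coords(X, Y)
  D2 <- outer(coords[, "x"], coords[, "x"], "-")^2 +
    outer(coords[, "y"], coords[, "y"], "-")^2
  Tn <- schedule$epochs
  with_local_seed(schedule$seed, {
    W <- init_weights(M, ncol(Z))
    Cw <- matrix(1 / L, M, L)
    for (epoch in seq_len(Tn)) {
      w_feat <- epoch / Tn
      for (k in sample.int(K)) {
        z <- Z[k, ]; y <- onehot[k, ]
        d2f <- rowSums(W * W) - 2 * drop(W %*% z) + sum(z * z)
        d2c <- rowSums(Cw * Cw) - 2 * drop(Cw %*% y) + sum(y * y)
        i <- which.min(w_feat * d2f + (1 - w_feat) * d2c)
        ab <- alpha * exp(-D2[, i] / (2 * sigma^2))
        W <- W + ab * (matrix(z, M, ncol(Z), byrow = TRUE) - W)
        Cw <- Cw + ab * (matrix(y, M, L, byrow = TRUE) - Cw)
      }
      alpha <- alpha * schedule$alpha_decay
      sigma <- sigma * schedule$sigma_decay
    }
    grid <- new_som_grid(W, X, Y, var_names = colnames(Z), norm = norm,
                         epochs = Tn, alpha_final = alpha,
                         sigma_final = sigma)
    structure(
      list(grid = grid, class_weights = Cw, classes = classes,
           node_label = classes[max.col(Cw, ties.method = "first")]),
      class = "bdk_model"
    )
  })
}

#' @export
print.bdk_model <- function(x, ...) {
  cat("<bdk_model> ", x$grid$X, "x", x$grid$Y, " nodes, ",
      length(x$classes), " classes: ", paste(x$classes, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Predict classes from a BDK model
#'
#' Each record is mapped to its BMU on the feature grid alone; the node's
#' majority label is returned.
#'
#' @param model A [train_bdk()] result.
#' @param Z Numeric matrix of normalised records.
#' @return Factor of predicted labels with the model's class levels.
#' @export
predict_bdk <- function(model, Z) {
  asg <- map_records(model$grid, Z)
  factor(model$node_label[asg$node], levels = model$classes)
}
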
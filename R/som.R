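# Self-organising map: rectangular grid of weight vectors trained by
# best-matching-unit search and Gaussian-neighbourhood updates.

#' Training schedule for map training
#'
#' The learning rate and the neighbourhood spread both decay geometrically
#' after each epoch (one epoch = every record visited once, in a seeded
#' random order), giving the monotone reduction the algorithm requires.
#'
#' @param epochs Number of passes over the data.
#' @param alpha0 Initial learning rate, in (0, 1].
#' @param alpha_decay,sigma_decay Per-epoch multipliers in (0, 1].
#' @param sigma0 Initial Gaussian neighbourhood spread in grid units;
#'   default (`NULL`) is half the larger grid dimension.
#' @param seed Integer seed controlling weight initialisation and record
#'   order.
#' @return Object of class `training_schedule`.
#' @export
training_schedule <- function(epochs = 50L, alpha0 = 0.5, alpha_decay = 0.95,
                              sigma0 = NULL, sigma_decay = 0.95, seed = 1L) {
  stopifnot(epochs >= 1, alpha0 > 0, alpha0 <= 1,
            alpha_decay > 0, alpha_decay <= 1,
            sigma_decay > 0, sigma_decay <= 1,
            is.null(sigma0) || sigma0 > 0)
  structure(list(epochs = as.integer(epochs), alpha0 = alpha0,
                 alpha_decay = alpha_decay, sigma0 = sigma0,
                 sigma_decay = sigma_decay, seed = as.integer(seed)),
            class = "training_schedule")
}

grid_coords <- function(X, Y) {
  # node index runs x-fastest: index = (y - 1) * X + x
  cbind(x = rep(seq_len(X), times = Y), y = rep(seq_len(Y), each = X))
}

new_som_grid <- function(W, X, Y, var_names = NULL, norm = NULL,
                         epochs = 0L, alpha_final = NA_real_,
                         sigma_final = NA_real_) {
  structure(
    list(W = W, X = as.integer(X), Y = as.integer(Y), N = ncol(W),
         coords = grid_coords(X, Y), var_names = var_names, norm = norm,
         epochs = epochs, alpha_final = alpha_final,
         sigma_final = sigma_final),
    class = "som_grid"
  )
}

#' @export
print.som_grid <- function(x, ...) {
  cat("<som_grid> ", x$X, "x", x$Y, " nodes, ", x$N, " variables, ",
      x$epochs, " epochs trained\n", sep = "")
  invisible(x)
}

bmu_index <- function(W, z) {
  d2 <- rowSums(W * W) - 2 * drop(W %*% z) + sum(z * z)
  which.min(d2) # ties: smallest node index (x-fastest ordering)
}

#' Best matching unit of a record
#'
#' Returns the grid coordinates of the node whose weight vector has minimum
#' Euclidean distance to the (normalised) record. Ties are broken towards
#' the smallest node index, nodes ordered x-fastest then y.
#'
#' @param grid A `som_grid`.
#' @param z Numeric vector of length `grid$N`.
#' @return Named integer vector `c(x =, y =)` with attribute `"index"` (the
#'   node index) and `"distance"` (the Euclidean distance).
#' @export
find_bmu <- function(grid, z) {
  z <- as.numeric(z)
  stopifnot(length(z) == grid$N)
  i <- bmu_index(grid$W, z)
  out <- c(x = grid$coords[i, "x"], y = grid$coords[i, "y"])
  attr(out, "index") <- i
  attr(out, "distance") <- sqrt(sum((grid$W[i, ] - z)^2))
  out
}

#' Gaussian-neighbourhood weight update
#'
#' Moves every node towards the record `z` by
#' `alpha * beta_xy * (z - w_xy)` with
#' `beta_xy = exp(-d^2 / (2 sigma^2))`, where `d` is the Euclidean distance
#' between the node's grid position and the BMU's. `beta` is 1 at the BMU,
#' so `alpha = 1` pins the BMU exactly onto `z`, and `alpha = 0` leaves the
#' grid unchanged. Since `0 < alpha * beta <= 1`, every node's distance to
#' `z` can only shrink.
#'
#' @param grid A `som_grid`.
#' @param z Record (numeric, length `grid$N`).
#' @param bmu BMU as returned by [find_bmu()] (or a node index).
#' @param alpha Learning rate in \[0, 1\].
#' @param sigma Neighbourhood spread (> 0), grid units.
#' @return The updated `som_grid`.
#' @export
update_weights <- function(grid, z, bmu, alpha, sigma) {
  stopifnot(alpha >= 0, alpha <= 1, sigma > 0)
  i <- if (!is.null(attr(bmu, "index"))) attr(bmu, "index")
       else if (length(bmu) == 2) (bmu[2] - 1L) * grid$X + bmu[1]
       else as.integer(bmu)
  d2 <- (grid$coords[, "x"] - grid$coords[i, "x"])^2 +
    (grid$coords[, "y"] - grid$coords[i, "y"])^2
  beta <- exp(-d2 / (2 * sigma^2))
  z <- as.numeric(z)
  grid$W <- grid$W + (alpha * beta) *
    (matrix(z, nrow(grid$W), grid$N, byrow = TRUE) - grid$W)
  grid
}

init_weights <- function(M, N) matrix(runif(M * N, -1, 1), M, N)

#' Train a self-organising map
#'
#' Iterative training: per epoch, all records are visited in a seeded
#' random permutation; each visit finds the record's BMU and applies the
#' Gaussian-neighbourhood update; after each epoch, the learning rate and
#' the neighbourhood spread are multiplied by their decay factors. Weights
#' are initialised uniformly at random in \[-1, 1\] per (normalised)
#' variable. Deterministic under a fixed schedule seed.
#'
#' @param Z Numeric matrix of normalised records, one per row (see
#'   [fit_normalizer()]).
#' @param grid_shape Integer `c(X, Y)`.
#' @param schedule A [training_schedule()].
#' @param norm Optional `som_normalizer` to attach for de-normalisation in
#'   [component_plane()].
#' @return A trained `som_grid`.
#' @export
train_som <- function(Z, grid_shape = c(10L, 10L), schedule = training_schedule(),
                      norm = NULL) {
  Z <- as.matrix(Z)
  K <- nrow(Z)
  stopifnot(K >= 1)
  X <- grid_shape[1]; Y <- grid_shape[2]; M <- X * Y
  sigma <- if (is.null(schedule$sigma0)) max(X, Y) / 2 else schedule$sigma0
  alpha <- schedule$alpha0
  coords <- grid_coords(X, Y)
  # pairwise squared grid distances between nodes
  D2 <- outer(coords[, "x"], coords[, "x"], "-")^2 +
    outer(coords[, "y"], coords[, "y"], "-")^2
  with_local_seed(schedule$seed, {
    W <- init_weights(M, ncol(Z))
    for (epoch in seq_len(schedule$epochs)) {
      for (k in sample.int(K)) {
        z <- Z[k, ]
        i <- bmu_index(W, z)
        beta <- exp(-D2[, i] / (2 * sigma^2))
        W <- W + (alpha * beta) * (matrix(z, M, ncol(Z), byrow = TRUE) - W)
      }
      alpha <- alpha * schedule$alpha_decay
      sigma <- sigma * schedule$sigma_decay
    }
    new_som_grid(W, X, Y, var_names = colnames(Z), norm = norm,
                 epochs = schedule$epochs, alpha_final = alpha,
                 sigma_final = sigma)
  })
}

#' Assign records to their best matching units
#'
#' @param grid A trained `som_grid` (for a BDK model, pass `model$grid`).
#' @param Z Numeric matrix of normalised records, one per row.
#' @param record_ids Optional identifiers (default: row numbers).
#' @return Tibble with columns `record_id`, `node`, `x`, `y`.
#' @export
map_records <- function(grid, Z, record_ids = NULL) {
  Z <- as.matrix(Z)
  if (is.null(record_ids)) record_ids <- as.character(seq_len(nrow(Z)))
  node <- vapply(seq_len(nrow(Z)),
                 function(k) bmu_index(grid$W, Z[k, ]), integer(1))
  tibble::tibble(
    record_id = record_ids, node = node,
    x = grid$coords[node, "x"], y = grid$coords[node, "y"]
  )
}

#' Mean distance of records to their best matching units
#'
#' The quantization error: the average Euclidean distance between each
#' record and its BMU's weight vector. Training should not increase it
#' relative to the random initial grid.
#'
#' @inheritParams map_records
#' @return A single number.
#' @export
quantization_error <- function(grid, Z) {
  Z <- as.matrix(Z)
  mean(vapply(seq_len(nrow(Z)), function(k) {
    i <- bmu_index(grid$W, Z[k, ])
    sqrt(sum((grid$W[i, ] - Z[k, ])^2))
  }, numeric(1)))
}

#' Component plane of one input variable
#'
#' The map coloured by a single variable: entry `(x, y)` is the
#' de-normalised weight value of that variable at node `(x, y)`. Reading
#' all planes side by side (each herd sits on the same pixel in every
#' plane) is how class-discriminating structure is extracted.
#'
#' @param grid A trained `som_grid` with attached normaliser (or pass
#'   `norm`).
#' @param variable Variable index or name.
#' @param norm Optional `som_normalizer` overriding `grid$norm`.
#' @return `X` by `Y` numeric matrix (rows index x, columns y).
#' @export
component_plane <- function(grid, variable, norm = NULL) {
  if (is.character(variable)) {
    variable <- match(variable, grid$var_names)
  }
  if (is.na(variable) || variable < 1 || variable > grid$N) {
    stop("variable index out of range")
  }
  if (is.null(norm)) norm <- grid$norm
  v <- grid$W[, variable]
  if (!is.null(norm)) v <- v * norm$sd[variable] + norm$mean[variable]
  matrix(v, nrow = grid$X, ncol = grid$Y)
}

#' Histogram of a raw variable over a map region
#'
#' Histograms the raw (un-normalised) values of one variable over the
#' records whose BMU lies in a given node subset — the tool used to confirm
#' split thresholds for a sub-region of the map. An empty region yields a
#' zero-count histogram, not an error.
#'
#' @param assignments Node assignments from [map_records()] (tibble or
#'   integer vector of node indices, one per record).
#' @param nodes Integer node indices defining the region.
#' @param values Raw variable values, one per record.
#' @param breaks Bin edges (default: 20 equal bins on \[0, 1\], suiting
#'   proportion-valued variables).
#' @return List with `counts`, `breaks`, `mids` and `n` (records in the
#'   region).
#' @export
region_histogram <- function(assignments, nodes, values,
                             breaks = seq(0, 1, by = 0.05)) {
  node_vec <- if (is.data.frame(assignments)) assignments$node
              else as.integer(assignments)
  sel <- values[node_vec %in% nodes]
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  if (length(sel) == 0) {
    return(list(counts = integer(length(mids)), breaks = breaks,
                mids = mids, n = 0L))
  }
  h <- graphics::hist(sel, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  list(counts = h$counts, breaks = h$breaks, mids = h$mids,
       n = length(sel))
}
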
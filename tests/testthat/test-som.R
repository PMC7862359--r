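test_that("the z-score normaliser centres, scales, inverts and rejects", {
  x <- matrix(c(0, 1, 10, 30), 2, 2, dimnames = list(NULL, c("a", "b")))
  p <- fit_normalizer(x)
  expect_equal(unname(p$mean), c(0.5, 20))
  z <- apply_normalizer(p, x)
  expect_equal(unname(z[, 1]), c(-1, 1)) # two-point z-score (population sd)
  expect_equal(unname(colMeans(z)), c(0, 0), tolerance = 1e-10)
  expect_equal(invert_normalizer(p, z), x, tolerance = 1e-12)

  xc <- cbind(a = c(1, 2, 3), flat = c(5, 5, 5))
  expect_error(fit_normalizer(xc), "flat")

  set.seed(2)
  big <- matrix(rnorm(200, 3, 7), 50, 4)
  zb <- apply_normalizer(fit_normalizer(big), big)
  expect_true(all(abs(colMeans(zb)) < 1e-10))
  expect_equal(unname(apply(zb, 2, function(c) mean(c^2))), rep(1, 4),
               tolerance = 1e-10)
})

test_that("find_bmu equals exhaustive search and honours tie-breaking", {
  set.seed(31)
  W <- matrix(runif(36 * 4, -1, 1), 36, 4)
  grid <- herdtyper:::new_som_grid(W, 6, 6)

  # exact hit
  b <- find_bmu(grid, W[17, ])
  expect_equal(attr(b, "index"), 17)
  expect_equal(attr(b, "distance"), 0)

  # 1x2 grid, z nearer the second node
  g2 <- herdtyper:::new_som_grid(rbind(c(0, 0), c(1, 1)), 2, 1)
  expect_equal(attr(find_bmu(g2, c(0.9, 0.9)), "index"), 2)

  # 100 random queries against the brute-force oracle
  for (i in 1:100) {
    z <- runif(4, -1.5, 1.5)
    expect_equal(attr(find_bmu(grid, z), "index"), oracle_bmu(W, z))
  }

  # exact tie: two identical nodes -> smallest index wins
  Wt <- rbind(c(1, 1), c(1, 1), c(0, 0))
  gt <- herdtyper:::new_som_grid(Wt, 3, 1)
  expect_equal(attr(find_bmu(gt, c(1, 1)), "index"), 1)
})

test_that("the Gaussian update has its closed-form fixed points", {
  set.seed(5)
  W <- matrix(runif(25 * 3, -1, 1), 25, 3)
  grid <- herdtyper:::new_som_grid(W, 5, 5)
  z <- runif(3)
  bmu <- find_bmu(grid, z)

  # alpha = 1 pins the BMU onto z; alpha = 0 changes nothing
  g1 <- update_weights(grid, z, bmu, alpha = 1, sigma = 1)
  expect_equal(g1$W[attr(bmu, "index"), ], z, tolerance = 1e-12)
  g0 <- update_weights(grid, z, bmu, alpha = 0.5 * 0, sigma = 1)
  expect_equal(g0$W, grid$W)

  # a node at grid distance sigma * sqrt(2 ln 2) moves half as far as
  # the BMU (Gaussian neighbourhood at half height)
  sigma <- 1 / sqrt(2 * log(2)) # then d = 1 gives beta = 1/2
  gl <- herdtyper:::new_som_grid(matrix(0, 2, 1), 2, 1)
  zz <- 1
  gu <- update_weights(gl, zz, c(x = 1, y = 1), alpha = 0.8, sigma = sigma)
  move_bmu <- gu$W[1, 1] - 0
  move_nb <- gu$W[2, 1] - 0
  expect_equal(move_nb / move_bmu, 0.5, tolerance = 1e-12)

  # contraction: no node ends farther from z than it started
  for (i in 1:20) {
    z <- runif(3, -2, 2)
    a <- runif(1, 0.05, 1); s <- runif(1, 0.2, 4)
    gu <- update_weights(grid, z, find_bmu(grid, z), a, s)
    pre <- sqrt(rowSums(sweep(grid$W, 2, z)^2))
    post <- sqrt(rowSums(sweep(gu$W, 2, z)^2))
    expect_true(all(post <= pre + 1e-12))
  }
})

test_that("training contracts the map onto the data", {
  # a single record attracts every node (wide, non-shrinking
  # neighbourhood so no node freezes before converging)
  z1 <- matrix(c(0.3, -0.7), 1, 2)
  g <- train_som(z1, grid_shape = c(4, 4),
                 schedule = training_schedule(epochs = 200, alpha0 = 0.5,
                                              sigma0 = 10, sigma_decay = 1,
                                              seed = 2))
  expect_true(all(abs(sweep(g$W, 2, z1[1, ])) < 1e-3))

  # quantization error does not exceed that of the random initial grid
  Z <- two_cluster_data()
  sched <- training_schedule(epochs = 40, seed = 14)
  trained <- train_som(Z, grid_shape = c(6, 6), sched)
  init <- herdtyper:::with_local_seed(sched$seed, {
    herdtyper:::new_som_grid(herdtyper:::init_weights(36, ncol(Z)), 6, 6)
  })
  expect_lt(quantization_error(trained, Z), quantization_error(init, Z))

  # the two clusters occupy disjoint, internally connected node sets
  asg <- map_records(trained, Z)
  n_per <- nrow(Z) / 2
  set1 <- unique(asg$node[seq_len(n_per)])
  set2 <- unique(asg$node[n_per + seq_len(n_per)])
  expect_length(intersect(set1, set2), 0)
  connected <- function(nodes, grid) {
    if (length(nodes) <= 1) return(TRUE)
    xy <- grid$coords[nodes, , drop = FALSE]
    seen <- 1L
    repeat {
      reach <- which(vapply(seq_along(nodes), function(i) {
        any(abs(xy[i, 1] - xy[seen, 1]) <= 1 &
              abs(xy[i, 2] - xy[seen, 2]) <= 1)
      }, logical(1)))
      if (length(reach) == length(seen)) break
      seen <- reach
    }
    length(seen) == length(nodes)
  }
  expect_true(connected(set1, trained))
  expect_true(connected(set2, trained))

  # determinism and independence from record identity
  again <- train_som(Z, grid_shape = c(6, 6), sched)
  expect_identical(trained$W, again$W)
  Zr <- Z
  rownames(Zr) <- paste0("r", seq_len(nrow(Z)))
  expect_equal(train_som(Zr, grid_shape = c(6, 6), sched)$W, trained$W,
               ignore_attr = TRUE)
})

test_that("record mapping is consistent and conserves counts", {
  Z <- two_cluster_data(n_per = 10, seed = 8)
  g <- train_som(Z, c(5, 5), training_schedule(epochs = 20, seed = 8))
  asg <- map_records(g, Z)
  expect_equal(nrow(asg), nrow(Z))
  expect_equal(sum(table(asg$node)), nrow(Z))
  for (k in c(1, 7, 20)) {
    expect_equal(asg$node[k], attr(find_bmu(g, Z[k, ]), "index"))
  }
  # identical records share a node
  Z2 <- rbind(Z, Z[1, ])
  asg2 <- map_records(g, Z2)
  expect_equal(asg2$node[nrow(Z2)], asg2$node[1])
})

test_that("component planes de-normalise node weights per variable", {
  raw <- cbind(p1 = runif(40, 0, 1), p2 = runif(40, 0.4, 0.6))
  norm <- fit_normalizer(raw)
  Z <- apply_normalizer(norm, raw)
  g <- train_som(Z, c(4, 4), training_schedule(epochs = 30, seed = 4),
                 norm = norm)

  planes <- lapply(seq_len(g$N), function(j) component_plane(g, j))
  expect_length(planes, 2)
  expect_equal(dim(planes[[1]]), c(4, 4))
  expect_error(component_plane(g, 3), "range")

  # de-normalisation inverts the z-transform exactly on each weight
  expect_equal(as.vector(planes[[2]]),
               g$W[, 2] * norm$sd[2] + norm$mean[2], tolerance = 1e-12)
  # and a trained map's plane stays near the observed data range
  expect_true(all(planes[[1]] > -0.25 & planes[[1]] < 1.25))
})

test_that("region histograms restrict, conserve and localise", {
  values <- c(rep(0.1, 20), rep(0.9, 20)) + runif(40, -0.02, 0.02)
  norm <- fit_normalizer(matrix(values))
  Z <- apply_normalizer(norm, matrix(values))
  g <- train_som(Z, c(4, 4), training_schedule(epochs = 30, seed = 6))
  asg <- map_records(g, Z)

  all_nodes <- seq_len(16)
  h_all <- region_histogram(asg, all_nodes, values)
  expect_equal(sum(h_all$counts), 40)

  # counts are additive over disjoint regions
  left <- which(g$coords[, "x"] <= 2)
  right <- which(g$coords[, "x"] > 2)
  h_l <- region_histogram(asg, left, values)
  h_r <- region_histogram(asg, right, values)
  expect_equal(h_l$counts + h_r$counts, h_all$counts)

  # restricting to the high cluster's nodes leaves a single right mode
  hi_nodes <- unique(asg$node[values > 0.5])
  h_hi <- region_histogram(asg, hi_nodes, values)
  expect_equal(sum(h_hi$counts[h_hi$mids < 0.5]), 0)
  expect_equal(sum(h_hi$counts[h_hi$mids > 0.5]), 20)

  # empty region: zero counts, not an error
  h_none <- region_histogram(asg, integer(0), values)
  expect_equal(sum(h_none$counts), 0)
})
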
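random_features <- function(n, seed = 1) {
  set.seed(seed)
  f <- as.data.frame(matrix(runif(n * 9), n, 9))
  names(f) <- feature_variables()
  f$herd_id <- sprintf("R%03d", seq_len(n))
  tibble::as_tibble(f)
}

test_that("the default tree has the published structure", {
  tree <- build_default_tree()
  st <- tree_stats(tree)
  expect_equal(st$n_leaves, 17)
  expect_equal(st$n_decisions, 13)
  expect_equal(st$n_binary, 10)
  expect_equal(st$n_ternary, 3)
  expect_equal(st$n_variables, 9)
  expect_equal(st$max_depth, 6)

  # sub-group sizes: 4 dairy, 5 beef, 5 store/rearing (plus M, F, T)
  leaves <- unlist(lapply(tree$nodes, function(nd) {
    nd$children[!nd$children %in% names(tree$nodes)]
  }))
  groups <- herd_types()
  tab <- table(groups$main_group[match(leaves, groups$herd_type)])
  expect_equal(unname(tab[["dairy"]]), 4)
  expect_equal(unname(tab[["beef"]]), 5)
  expect_equal(unname(tab[["store/rearing"]]), 5)
})

test_that("small hand-built trees report their stats by traversal", {
  single <- herd_tree(list(
    N1 = list(variable = "pCalvedAnimals", thresholds = 0.5,
              children = c("T", "F"))
  ), root = "N1")
  st <- tree_stats(single)
  expect_equal(st$n_leaves, 2)
  expect_equal(st$n_decisions, 1)
  expect_equal(st$max_depth, 1)

  ternary <- herd_tree(list(
    N1 = list(variable = "pFemaleAnimals", thresholds = c(0.3, 0.7),
              children = c("Sbm", "Sbmx", "Sbf"))
  ), root = "N1")
  st <- tree_stats(ternary)
  expect_equal(st$n_leaves, 3)
  expect_equal(st$n_decisions, 1)
  expect_equal(st$n_ternary, 1)
})

test_that("classification follows the documented herd-type signatures", {
  tree <- build_default_tree()
  base <- setNames(as.list(rep(0, 9)), feature_variables())

  dairy <- modifyList(base, list(pCalvedAnimals = 0.4, pDairyBreed = 0.8,
                                 pMalesBetween1and2Years = 0.05,
                                 pInMovesToBirthHerd = 0.05))
  expect_equal(classify_herd(tree, dairy)$herd_type, "D")

  trader <- modifyList(base, list(pCalvedAnimals = 0.1,
                                  pAnimalsLess30Days = 0.8))
  expect_equal(classify_herd(tree, trader)$herd_type, "T")

  fattener <- modifyList(base, list(pCalvedAnimals = 0.1,
                                    pAnimalsLess30Days = 0.1,
                                    pOutMovesToSL = 0.9))
  cl <- classify_herd(tree, fattener)
  expect_equal(cl$herd_type, "F")
  expect_equal(cl$main_group, "fattening")
  expect_lte(nrow(cl$path), 6)

  # every path in a batch stays within six decisions
  cls <- classify_herds(tree, random_features(200, seed = 4))
  expect_true(all(cls$n_decisions <= 6))
  expect_true(all(cls$herd_type %in% herd_types()$herd_type))
})

test_that("tree classification is consistent with the initial rules", {
  tree <- build_default_tree()
  f <- random_features(300, seed = 9)
  init <- as.character(initial_classification(f))
  cls <- classify_herds(tree, f)
  group_of <- c(dairy = "dairy", beef = "beef", mixed = "mixed")
  breeding <- init != "unknown"
  expect_equal(cls$main_group[breeding], unname(group_of[init[breeding]]))
})

test_that("labels are piecewise constant between thresholds", {
  tree <- build_default_tree()
  f <- random_features(50, seed = 30)
  cls <- classify_herds(tree, f)
  eps <- 1e-7
  for (i in seq_len(20)) {
    for (v in feature_variables()) {
      g <- f[i, ]
      g[[v]] <- g[[v]] + eps
      expect_equal(classify_herd(tree, g)$herd_type, cls$herd_type[i])
    }
  }
})

test_that("printed thresholds are fixed while others are configurable", {
  expect_error(build_default_tree(thresholds = list(D1 = 0.3)), "fixed")
  tweaked <- build_default_tree(thresholds = list(D3 = 0.55))
  expect_equal(tweaked$nodes$D3$thresholds, 0.55)
  expect_equal(tweaked$nodes$D1$thresholds, 0.25)
})

test_that("trees survive a YAML round-trip", {
  tree <- build_default_tree()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_tree(tree, path)
  back <- read_tree(path)
  expect_equal(back$nodes, tree$nodes)
  expect_equal(back$root, tree$root)
  f <- random_features(50, seed = 12)
  expect_equal(classify_herds(back, f)$herd_type,
               classify_herds(tree, f)$herd_type)
})

test_that("sensitivity bands count herds across the empirical distribution", {
  # 100 herds spread uniformly at 0.005, 0.015, ..., 0.995 around a 0.5
  # threshold: moving it to 0.605 (resp. 0.395) reassigns 10 herds
  single <- herd_tree(list(
    N1 = list(variable = "pOutMovesToSL", thresholds = 0.5,
              children = c("T", "F"))
  ), root = "N1")
  f <- tibble::tibble(herd_id = sprintf("h%03d", 1:100),
                      pOutMovesToSL = seq(0.005, 0.995, by = 0.01))
  band <- threshold_sensitivity(single, "N1", f, fraction = 0.10)
  expect_equal(band$m, 10)
  expect_equal(band$low, 0.395)
  expect_equal(band$high, 0.605)
  expect_false(band$open_low || band$open_high)

  # all herds far on one side: the other bound is open and flagged
  f1 <- tibble::tibble(herd_id = sprintf("g%02d", 1:20),
                       pOutMovesToSL = seq(0.70, 0.995, length.out = 20))
  band1 <- threshold_sensitivity(single, "N1", f1, fraction = 0.10)
  expect_true(band1$open_low)
  expect_false(band1$open_high)

  # zero fraction degenerates to the threshold itself
  band0 <- threshold_sensitivity(single, "N1", f, fraction = 0)
  expect_equal(c(band0$low, band0$high), c(0.5, 0.5))

  # only herds reaching the node are counted
  tree <- build_default_tree()
  ff <- random_features(400, seed = 44)
  cls <- classify_herds(tree, ff)
  reached <- vapply(cls$path, function(p) "D10" %in% p, logical(1))
  bandd <- threshold_sensitivity(tree, "D10", ff, fraction = 0.10)
  expect_equal(bandd$n, sum(reached))
})
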
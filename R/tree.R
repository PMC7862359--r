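# The extracted classification rules: a 13-decision tree (10 binary, 3
# ternary) over the nine herd variables with 17 leaf herd types.

#' Construct a decision tree
#'
#' Nodes are named; each has a `variable` (one of [feature_variables()]),
#' one threshold (binary split) or two strictly increasing thresholds
#' (ternary split), and 2 or 3 `children` — either node names or leaf herd
#' types. Comparison uses `>=` on every stated boundary: a binary node
#' sends `value >= t` to the second child; a ternary node sends
#' `value < t1` to the first, `t1 <= value < t2` to the second and
#' `value >= t2` to the third.
#'
#' @param nodes Named list of nodes, each
#'   `list(variable =, thresholds =, children =)`.
#' @param root Name of the root node.
#' @return Object of class `herd_tree`.
#' @export
herd_tree <- function(nodes, root) {
  stopifnot(root %in% names(nodes))
  for (nm in names(nodes)) {
    nd <- nodes[[nm]]
    stopifnot(
      nd$variable %in% the_nine_variables,
      length(nd$thresholds) %in% c(1L, 2L),
      length(nd$children) == length(nd$thresholds) + 1L
    )
    if (length(nd$thresholds) == 2) stopifnot(diff(nd$thresholds) > 0)
    kids <- nd$children
    unknown <- kids[!(kids %in% names(nodes)) & !(kids %in% herd_types()$herd_type)]
    if (length(unknown) > 0) {
      stop("node ", nm, " has unknown child(ren): ",
           paste(unknown, collapse = ", "))
    }
  }
  structure(list(nodes = nodes, root = root), class = "herd_tree")
}

#' The default herd-type classification tree
#'
#' The canonical 13-decision tree over the nine variables, yielding the 17
#' herd types. The externally fixed thresholds are the breeding criterion
#' (`pCalvedAnimals >= 0.25`), the dairy/beef ternary split
#' (`pDairyBreed >= 0.70` dairy, `< 0.30` beef, else mixed) and the
#' fattening criterion (`pOutMovesToSL >= 0.5`); the trading split rests on
#' the 30-day stay window built into `pAnimalsLess30Days`. All remaining
#' thresholds are package configuration defaults and can be overridden.
#'
#' @param thresholds Optional named list overriding the configurable
#'   defaults, keyed by node name (`D3`, `D4`, `D5`, `D6`, `D7`, `D8`,
#'   `D9`, `D11`, `D12`, `D13`).
#' @return A `herd_tree` with 13 decision nodes (10 binary, 3 ternary),
#'   17 leaves, 9 distinct variables and a maximum depth of 6 decisions.
#' @export
build_default_tree <- function(thresholds = NULL) {
  th <- list(
    D1 = 0.25, D2 = c(0.30, 0.70), D3 = 0.40, D4 = 0.60, D5 = 0.40,
    D6 = 0.15, D7 = 0.30, D8 = c(0.20, 0.75), D9 = 0.50, D10 = 0.50,
    D11 = 0.40, D12 = 0.50, D13 = c(0.30, 0.70)
  )
  if (!is.null(thresholds)) {
    fixed <- c("D1", "D2", "D10")
    if (any(names(thresholds) %in% fixed)) {
      stop("thresholds of ", paste(intersect(names(thresholds), fixed),
                                   collapse = ", "),
           " are fixed classification constants")
    }
    stopifnot(all(names(thresholds) %in% names(th)))
    th[names(thresholds)] <- thresholds
  }
  nodes <- list(
    D1 = list(variable = "pCalvedAnimals", thresholds = th$D1,
              children = c("D9", "D2")),
    # breeding branch
    D2 = list(variable = "pDairyBreed", thresholds = th$D2,
              children = c("D6", "M", "D3")),
    D3 = list(variable = "pMalesBetween1and2Years", thresholds = th$D3,
              children = c("D4", "DRm")),
    D4 = list(variable = "pCalvedAnimals", thresholds = th$D4,
              children = c("D", "D5")),
    D5 = list(variable = "pInMovesToBirthHerd", thresholds = th$D5,
              children = c("DnR-nC", "DnR-C")),
    D6 = list(variable = "pCrossBreed", thresholds = th$D6,
              children = c("BP", "D7")),
    D7 = list(variable = "pOutMovesToSL", thresholds = th$D7,
              children = c("D8", "BSB")),
    D8 = list(variable = "pMalesBetween1and2Years", thresholds = th$D8,
              children = c("BSW", "BSY", "BSY-nR")),
    # non-breeding branch
    D9 = list(variable = "pAnimalsLess30Days", thresholds = th$D9,
              children = c("D10", "T")),
    D10 = list(variable = "pOutMovesToSL", thresholds = th$D10,
               children = c("D11", "F")),
    D11 = list(variable = "pOutMovesToBirthHerd", thresholds = th$D11,
               children = c("D12", "Rdf")),
    D12 = list(variable = "pDairyBreed", thresholds = th$D12,
               children = c("D13", "Sdm")),
    D13 = list(variable = "pFemaleAnimals", thresholds = th$D13,
               children = c("Sbm", "Sbmx", "Sbf"))
  )
  herd_tree(nodes, root = "D1")
}

branch_of <- function(value, thresholds) {
  # index of the child to follow, under the >= boundary convention
  sum(value >= thresholds) + 1L
}

#' Classify one herd
#'
#' Deterministic root-to-leaf traversal; the decision path records every
#' node visited with the variable value seen and the branch taken.
#'
#' @param tree A `herd_tree`.
#' @param features One-row data frame (or named list/vector) holding the
#'   nine variables.
#' @return List with `herd_type`, `main_group` and `path` (tibble: `node`,
#'   `variable`, `value`, `branch`).
#' @export
classify_herd <- function(tree, features) {
  if (is.data.frame(features)) {
    stopifnot(nrow(features) == 1)
    features <- as.list(features)
  }
  cur <- tree$root
  path <- list()
  repeat {
    nd <- tree$nodes[[cur]]
    v <- as.numeric(features[[nd$variable]])
    b <- branch_of(v, nd$thresholds)
    path[[length(path) + 1]] <- tibble::tibble(
      node = cur, variable = nd$variable, value = v, branch = b
    )
    nxt <- nd$children[b]
    if (nxt %in% names(tree$nodes)) cur <- nxt else break
  }
  groups <- herd_types()
  list(
    herd_type = nxt,
    main_group = groups$main_group[match(nxt, groups$herd_type)],
    path = dplyr::bind_rows(path)
  )
}

#' Classify a table of herds
#'
#' @param tree A `herd_tree`.
#' @param features Feature table from [compute_features()].
#' @return Tibble: `herd_id`, `herd_type`, `main_group`, `n_decisions`,
#'   plus a list-column `path` of visited node names.
#' @export
classify_herds <- function(tree, features) {
  res <- lapply(seq_len(nrow(features)), function(i) {
    cl <- classify_herd(tree, features[i, ])
    tibble::tibble(
      herd_id = features$herd_id[i],
      herd_type = cl$herd_type,
      main_group = cl$main_group,
      n_decisions = nrow(cl$path),
      path = list(cl$path$node)
    )
  })
  dplyr::bind_rows(res)
}

#' Structural statistics of a tree
#'
#' @param tree A `herd_tree`.
#' @return List: `n_leaves`, `n_decisions`, `n_binary`, `n_ternary`,
#'   `n_variables`, `max_depth`.
#' @export
tree_stats <- function(tree) {
  leaves <- character(0)
  max_depth <- 0L
  walk <- function(name, depth) {
    nd <- tree$nodes[[name]]
    for (ch in nd$children) {
      if (ch %in% names(tree$nodes)) {
        walk(ch, depth + 1L)
      } else {
        leaves <<- c(leaves, ch)
        max_depth <<- max(max_depth, depth)
      }
    }
  }
  walk(tree$root, 1L)
  arity <- vapply(tree$nodes, function(nd) length(nd$children), integer(1))
  list(
    n_leaves = length(leaves),
    n_decisions = length(tree$nodes),
    n_binary = sum(arity == 2),
    n_ternary = sum(arity == 3),
    n_variables = dplyr::n_distinct(
      vapply(tree$nodes, `[[`, character(1), "variable")),
    max_depth = max_depth
  )
}

#' Write / read a tree as editable YAML
#'
#' Serialises the tree as a structured text file (node name, variable,
#' thresholds, children) so that domain experts can edit thresholds.
#'
#' @param tree A `herd_tree`.
#' @param path File path.
#' @return `write_tree`: the path, invisibly. `read_tree`: a `herd_tree`.
#' @export
write_tree <- function(tree, path) {
  yaml::write_yaml(list(root = tree$root, nodes = tree$nodes), path)
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  x <- yaml::read_yaml(path)
  nodes <- lapply(x$nodes, function(nd) {
    list(variable = nd$variable, thresholds = as.numeric(nd$thresholds),
         children = as.character(nd$children))
  })
  herd_tree(nodes, root = x$root)
}

#' Threshold-sensitivity band at a decision node
#'
#' Among the herds that reach a node, finds the smallest interval around
#' the node's threshold such that moving the threshold to either end would
#' reassign `ceiling(fraction * n)` herds across the boundary (n = herds at
#' the node). With too few herds beyond the threshold on one side, that
#' bound is open (`-Inf`/`Inf`) and flagged.
#'
#' @param tree A `herd_tree`.
#' @param node_id Node name.
#' @param features Feature table of the herd population.
#' @param fraction Fraction of herds to reassign (default 0.10).
#' @param threshold_index For ternary nodes, which of the two thresholds
#'   (1 or 2).
#' @return Object of class `sensitivity_band`: `node_id`, `variable`,
#'   `threshold`, `low`, `high`, `n`, `m`, `open_low`, `open_high`.
#' @export
threshold_sensitivity <- function(tree, node_id, features, fraction = 0.10,
                                  threshold_index = 1L) {
  stopifnot(node_id %in% names(tree$nodes))
  cls <- classify_herds(tree, features)
  reached <- vapply(cls$path, function(p) node_id %in% p, logical(1))
  if (!any(reached)) stop("no herd reaches node ", node_id)
  nd <- tree$nodes[[node_id]]
  theta <- nd$thresholds[threshold_index]
  values <- features[[nd$variable]][reached]
  n <- length(values)
  m <- ceiling(fraction * n)
  if (m == 0) {
    band <- list(low = theta, high = theta, open_low = FALSE,
                 open_high = FALSE)
  } else {
    vh <- sort(values[values >= theta])
    vl <- sort(values[values < theta], decreasing = TRUE)
    band <- list(
      low = if (length(vl) >= m + 1) vl[m + 1] else -Inf,
      high = if (length(vh) >= m + 1) vh[m + 1] else Inf,
      open_low = length(vl) < m + 1,
      open_high = length(vh) < m + 1
    )
  }
  structure(
    c(list(node_id = node_id, variable = nd$variable, threshold = theta,
           n = n, m = m), band),
    class = "sensitivity_band"
  )
}

#' @export
print.sensitivity_band <- function(x, ...) {
  cat("<sensitivity_band> ", x$node_id, " (", x$variable, " >= ",
      x$threshold, "): [", x$low, ", ", x$high, "] reassigning ", x$m,
      " of ", x$n, " herds",
      if (x$open_low || x$open_high) " (open-ended)" else "", "\n", sep = "")
  invisible(x)
}
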
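# C4.5 tree induction with exact or Maclaurin-approximated (TAM) scoring.

#' Decision-tree induction parameters
#'
#' @param mode `"tam"` scores candidate splits with the
#'   Maclaurin-polynomial gain ratio (log-free); `"exact"` uses
#'   logarithmic entropies (classic C4.5).
#' @param max_depth Maximum tree depth (root = depth 1); default 25.
#' @param min_samples_split Minimum records a node needs to be considered
#'   for splitting; default 2.
#' @param n_points Number of equal-division candidate thresholds for
#'   continuous attributes; default 10.
#' @param midpoints Use classic midpoint candidate thresholds instead of
#'   equal-division points (off by default).
#' @return An object of class `tree_params`.
#' @export
tree_params <- function(mode = c("tam", "exact"), max_depth = 25L,
                        min_samples_split = 2L, n_points = 10L,
                        midpoints = FALSE) {
  mode <- match.arg(mode)
  max_depth <- as.integer(max_depth)
  min_samples_split <- as.integer(min_samples_split)
  if (max_depth < 1L) stop("`max_depth` must be at least 1", call. = FALSE)
  if (min_samples_split < 2L) {
    stop("`min_samples_split` must be at least 2", call. = FALSE)
  }
  structure(list(mode = mode, max_depth = max_depth,
                 min_samples_split = min_samples_split,
                 n_points = as.integer(n_points), midpoints = midpoints),
            class = "tree_params")
}

node_distribution <- function(labels, classes) {
  cnt <- as.numeric(table(factor(labels, levels = classes)))
  p <- cnt / sum(cnt)
  names(p) <- classes
  p
}

make_leaf <- function(labels, classes, dist = NULL) {
  if (is.null(dist)) dist <- node_distribution(labels, classes)
  list(kind = "leaf",
       class_distribution = dist,
       majority_class = classes[which.max(dist)],
       n = length(labels))
}

# Score one attribute at a node. Returns a split candidate with the
# attribute name attached, or an invalid candidate.
score_attribute <- function(a, col, labels, classes, params) {
  score <- if (params$mode == "tam") approx_gain_ratio else exact_gain_ratio
  if (a$kind == "continuous") {
    cand <- discretize_continuous(col, labels, n_points = params$n_points,
                                  mode = params$mode, class_levels = classes,
                                  midpoints = params$midpoints)
  } else {
    tab <- table(col, factor(labels, levels = classes))
    branches <- unclass(tab)[rowSums(tab) > 0, , drop = FALSE]
    cand <- if (nrow(branches) < 2L) invalid_candidate()
            else score(as.numeric(table(factor(labels, levels = classes))),
                       branches)
    cand$threshold <- NA_real_
  }
  cand$attribute <- a$name
  cand
}

build_node <- function(df, labels, schema, params, avail, depth) {
  classes <- schema$classes
  n <- length(labels)
  pure <- length(unique(as.character(labels))) == 1L
  if (pure || n < params$min_samples_split || depth >= params$max_depth ||
      length(avail) == 0L) {
    return(make_leaf(labels, classes))
  }
  cands <- lapply(avail, function(nm) {
    score_attribute(schema$attributes[[nm]], df[[nm]], labels, classes, params)
  })
  ok <- vapply(cands, function(cc) {
    isTRUE(cc$valid) && cc$gain > ZERO_TOL
  }, logical(1))
  cands <- cands[ok]
  if (length(cands) == 0L) return(make_leaf(labels, classes))

  # keep candidates whose gain ratio reaches the mean over valid
  # candidates, then take the largest; ties break lexicographically by
  # attribute name, then by the smaller threshold
  ratios <- vapply(cands, `[[`, numeric(1), "gain_ratio")
  keep <- cands[ratios >= mean(ratios) - ZERO_TOL]
  ord <- order(-vapply(keep, `[[`, numeric(1), "gain_ratio"),
               vapply(keep, `[[`, character(1), "attribute"),
               vapply(keep, `[[`, numeric(1), "threshold"))
  best <- keep[[ord[1L]]]
  a <- schema$attributes[[best$attribute]]
  dist <- node_distribution(labels, classes)

  if (a$kind == "continuous") {
    left <- df[[a$name]] <= best$threshold
    children <- list(
      "<=" = build_node(df[left, , drop = FALSE], labels[left], schema,
                        params, avail, depth + 1L),
      ">"  = build_node(df[!left, , drop = FALSE], labels[!left], schema,
                        params, avail, depth + 1L)
    )
    node_kind <- "continuous_split"
    thr <- best$threshold
  } else {
    sub_avail <- setdiff(avail, a$name)  # categorical attributes are consumed
    children <- lapply(a$levels, function(lv) {
      idx <- df[[a$name]] == lv
      if (!any(idx)) {
        # level absent at this node: leaf carrying the parent distribution
        make_leaf(labels[0], classes, dist = dist)
      } else {
        build_node(df[idx, , drop = FALSE], labels[idx], schema, params,
                   sub_avail, depth + 1L)
      }
    })
    names(children) <- a$levels
    node_kind <- "categorical_split"
    thr <- NULL
  }
  list(kind = node_kind, attribute = a$name, threshold = thr,
       children = children, class_distribution = dist,
       majority_class = classes[which.max(dist)], n = n)
}

#' Fit a C4.5 / TAM-C4.5 decision tree
#'
#' Recursive induction: at each node every available attribute is scored
#' (categorical attributes by their multiway partition into levels,
#' continuous attributes by the best equal-division-point binary split),
#' candidates whose gain ratio is at least the mean over valid candidates
#' are retained, and the split with the largest gain ratio among them is
#' applied. Recursion stops at class purity, the depth or node-size
#' limits, or when no candidate has positive gain. Categorical
#' attributes are consumed along a path; continuous attributes may be
#' reused with different thresholds. No pruning is applied.
#'
#' @param train A non-empty [mh_dataset()].
#' @param params A [tree_params()] object.
#' @return An object of class `c45_tree` with elements `root` (nested
#'   node list), `schema`, `params`.
#' @export
#' @examples
#' sch <- mh_schema(list(attribute_spec("x", "continuous")), "cls", c("A", "B"))
#' d <- mh_dataset(data.frame(x = 1:4, cls = c("A", "A", "B", "B")), sch)
#' fit <- c45_tree(d, tree_params(mode = "exact", n_points = 3))
#' predict(fit, d, type = "class")
c45_tree <- function(train, params = tree_params()) {
  stopifnot(inherits(train, "mh_dataset"), inherits(params, "tree_params"))
  if (n_records(train) == 0L) stop("empty training set", call. = FALSE)
  root <- build_node(dataset_features(train), dataset_labels(train),
                     train$schema, params, avail = attr_names(train$schema),
                     depth = 1L)
  structure(list(root = root, schema = train$schema, params = params),
            class = "c45_tree")
}

count_tree_nodes <- function(node) {
  if (node$kind == "leaf") return(1L)
  1L + sum(vapply(node$children, count_tree_nodes, integer(1)))
}

tree_depth <- function(node) {
  if (node$kind == "leaf") return(1L)
  1L + max(vapply(node$children, tree_depth, integer(1)))
}

#' @export
print.c45_tree <- function(x, ...) {
  cat("<c45_tree> mode=", x$params$mode, ", ",
      count_tree_nodes(x$root), " nodes, depth ", tree_depth(x$root),
      "\n", sep = "")
  invisible(x)
}

route_record <- function(node, record) {
  while (node$kind != "leaf") {
    v <- record[[node$attribute]]
    if (node$kind == "continuous_split") {
      node <- if (v <= node$threshold) node$children[["<="]]
              else node$children[[">"]]
    } else {
      child <- node$children[[as.character(v)]]
      # unseen category level: stop routing, answer with this node's
      # distribution
      if (is.null(child)) return(node$class_distribution)
      node <- child
    }
  }
  node$class_distribution
}

#' Predict from a fitted decision tree
#'
#' Routes each record from the root to a leaf, testing one attribute per
#' level; continuous splits send values `<=` threshold left. A record
#' carrying a category level with no branch stops at the current node and
#' receives that node's class distribution.
#'
#' @param object A fitted [c45_tree()].
#' @param newdata An [mh_dataset()] or data frame conforming to the
#'   training schema.
#' @param type `"prob"` for a matrix of class probabilities (rows sum to
#'   1), `"class"` for the argmax label.
#' @param ... Unused.
#' @return A numeric matrix (type `"prob"`) or factor (type `"class"`).
#' @export
predict.c45_tree <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "mh_dataset")) {
    df <- dataset_features(newdata)
  } else {
    df <- mh_dataset_features_from_frame(newdata, object$schema)
  }
  classes <- object$schema$classes
  probs <- t(vapply(seq_len(nrow(df)), function(i) {
    route_record(object$root, df[i, , drop = FALSE])
  }, numeric(length(classes))))
  colnames(probs) <- classes
  if (type == "class") {
    factor(classes[max.col(probs, ties.method = "first")], levels = classes)
  } else {
    probs
  }
}

# Validate a bare data frame of features against a schema (no class
# column required).
mh_dataset_features_from_frame <- function(df, schema) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (a in schema$attributes) {
    if (!a$name %in% names(df)) {
      stop("record lacks attribute `", a$name, "`", call. = FALSE)
    }
    if (a$kind == "continuous") {
      v <- suppressWarnings(as.numeric(df[[a$name]]))
      if (anyNA(v)) stop("non-numeric value for `", a$name, "`", call. = FALSE)
      df[[a$name]] <- v
    } else {
      df[[a$name]] <- as.character(df[[a$name]])
    }
  }
  df[attr_names(schema)]
}

node_to_list <- function(node) {
  out <- list(kind = node$kind,
              class_distribution = as.list(node$class_distribution),
              majority_class = node$majority_class,
              n = node$n)
  if (node$kind != "leaf") {
    out$attribute <- node$attribute
    if (node$kind == "continuous_split") out$threshold <- node$threshold
    out$children <- lapply(node$children, node_to_list)
  }
  out
}

node_from_list <- function(x) {
  for (f in c("kind", "class_distribution", "majority_class")) {
    if (is.null(x[[f]])) stop("malformed tree JSON: missing `", f, "`",
                              call. = FALSE)
  }
  dist <- unlist(x$class_distribution)
  n <- if (is.null(x$n)) NA_integer_ else as.integer(x$n)
  if (x$kind == "leaf") {
    return(list(kind = "leaf", class_distribution = dist,
                majority_class = x$majority_class, n = n))
  }
  list(kind = x$kind, attribute = x$attribute,
       threshold = if (x$kind == "continuous_split")
         as.numeric(x$threshold) else NULL,
       children = lapply(x$children, node_from_list),
       class_distribution = dist,
       majority_class = x$majority_class, n = n)
}

#' Serialize a decision tree to JSON
#'
#' @param tree A fitted [c45_tree()].
#' @return A JSON string encoding mode, schema and the node structure;
#'   numeric values keep full double precision.
#' @export
serialize_tree <- function(tree) {
  stopifnot(inherits(tree, "c45_tree"))
  payload <- list(model = "c45_tree",
                  mode = tree$params$mode,
                  params = unclass(tree$params),
                  schema = schema_to_list(tree$schema),
                  root = node_to_list(tree$root))
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA))
}

#' Deserialize a decision tree from JSON
#'
#' @param text JSON produced by [serialize_tree()].
#' @return A [c45_tree()] whose predictions match the original tree.
#' @export
deserialize_tree <- function(text) {
  payload <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                      error = function(e) {
                        stop("malformed tree JSON: ", conditionMessage(e),
                             call. = FALSE)
                      })
  if (is.null(payload$root) || !identical(payload$model, "c45_tree")) {
    stop("malformed tree JSON: not a serialized c45_tree", call. = FALSE)
  }
  p <- payload$params
  params <- tree_params(mode = p$mode, max_depth = p$max_depth,
                        min_samples_split = p$min_samples_split,
                        n_points = p$n_points,
                        midpoints = isTRUE(p$midpoints))
  structure(list(root = node_from_list(payload$root),
                 schema = schema_from_list(payload$schema),
                 params = params),
            class = "c45_tree")
}
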
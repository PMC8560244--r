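#' Attribute specification
#'
#' Describes one column of a dataset: its name and whether it is a
#' categorical attribute (with a fixed, ordered set of levels) or a
#' continuous one.
#'
#' @param name Column name, a single non-empty string.
#' @param kind Either `"categorical"` or `"continuous"`.
#' @param levels Character vector of category labels. Required (non-empty)
#'   for categorical attributes; must be absent for continuous ones.
#'
#' @return An object of class `attribute_spec`.
#' @export
#' @examples
#' attribute_spec("mood", "categorical", levels = c("low", "mid", "high"))
#' attribute_spec("posts_per_day", "continuous")
attribute_spec <- function(name, kind = c("categorical", "continuous"),
                           levels = NULL) {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("`name` must be a single non-empty string", call. = FALSE)
  }
  if (kind == "categorical") {
    if (is.null(levels) || length(levels) == 0L) {
      stop("categorical attribute `", name, "` needs non-empty `levels`",
           call. = FALSE)
    }
    levels <- as.character(levels)
    if (anyDuplicated(levels)) {
      stop("duplicate levels in attribute `", name, "`", call. = FALSE)
    }
  } else if (!is.null(levels)) {
    stop("continuous attribute `", name, "` must not have `levels`",
         call. = FALSE)
  }
  structure(list(name = name, kind = kind, levels = levels),
            class = "attribute_spec")
}

#' Dataset schema
#'
#' Binds a list of [attribute_spec()] objects to the name of the class
#' column and the ordered set of class labels.
#'
#' @param attributes List of [attribute_spec()] objects with unique names.
#' @param class_column Name of the class-label column.
#' @param classes Ordered character vector of class labels (at least one).
#'
#' @return An object of class `mh_schema`.
#' @export
mh_schema <- function(attributes, class_column, classes) {
  if (!is.list(attributes) ||
      !all(vapply(attributes, inherits, logical(1), "attribute_spec"))) {
    stop("`attributes` must be a list of attribute_spec objects",
         call. = FALSE)
  }
  nms <- vapply(attributes, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("attribute names must be unique", call. = FALSE)
  if (class_column %in% nms) {
    stop("class column `", class_column, "` collides with an attribute name",
         call. = FALSE)
  }
  classes <- as.character(classes)
  if (length(classes) < 1L || anyDuplicated(classes)) {
    stop("`classes` must be a non-empty set of unique labels", call. = FALSE)
  }
  names(attributes) <- nms
  structure(list(attributes = attributes, class_column = class_column,
                 classes = classes),
            class = "mh_schema")
}

attr_names <- function(schema) {
  vapply(schema$attributes, `[[`, character(1), "name")
}

#' Labeled dataset
#'
#' The common currency between all fitting and evaluation functions: a
#' data frame of typed attribute columns plus a class-label column,
#' validated against an [mh_schema()].
#'
#' Categorical columns are stored as factors carrying the full level set
#' from the schema (so levels absent from a subset survive splitting);
#' continuous columns are numeric; the class column is a factor over
#' `schema$classes`. Missing values are rejected.
#'
#' @param data A data frame containing every schema attribute plus the
#'   class column.
#' @param schema An [mh_schema()].
#'
#' @return An object of class `mh_dataset`: a list with elements `data`
#'   (the validated data frame) and `schema`.
#' @export
mh_dataset <- function(data, schema) {
  stopifnot(inherits(schema, "mh_schema"))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  cc <- schema$class_column
  if (!cc %in% names(data)) {
    stop("schema error: class column `", cc, "` missing from data",
         call. = FALSE)
  }
  out <- list()
  for (a in schema$attributes) {
    if (!a$name %in% names(data)) {
      stop("schema error: attribute column `", a$name, "` missing from data",
           call. = FALSE)
    }
    col <- data[[a$name]]
    if (a$kind == "continuous") {
      if (is.factor(col)) col <- as.character(col)
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num))
      if (length(bad)) {
        stop("parse error: non-numeric value in continuous column `", a$name,
             "` at row ", bad[1L], call. = FALSE)
      }
      out[[a$name]] <- num
    } else {
      col <- as.character(col)
      bad <- which(!(col %in% a$levels) | is.na(col))
      if (length(bad)) {
        stop("parse error: value `", col[bad[1L]], "` in categorical column `",
             a$name, "` at row ", bad[1L], " is not a declared level",
             call. = FALSE)
      }
      out[[a$name]] <- factor(col, levels = a$levels)
    }
  }
  lab <- as.character(data[[cc]])
  bad <- which(!(lab %in% schema$classes) | is.na(lab))
  if (length(bad)) {
    stop("parse error: class label `", lab[bad[1L]], "` at row ", bad[1L],
         " is not in the declared classes", call. = FALSE)
  }
  out[[cc]] <- factor(lab, levels = schema$classes)
  structure(list(data = as.data.frame(out, stringsAsFactors = FALSE),
                 schema = schema),
            class = "mh_dataset")
}

#' @export
print.mh_dataset <- function(x, ...) {
  k <- vapply(x$schema$attributes, `[[`, character(1), "kind")
  cat("<mh_dataset> ", nrow(x$data), " records, ",
      sum(k == "categorical"), " categorical + ",
      sum(k == "continuous"), " continuous attributes, ",
      length(x$schema$classes), " classes (",
      paste(x$schema$classes, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Number of records in a dataset
#' @param data An [mh_dataset()].
#' @return Integer record count.
#' @export
n_records <- function(data) {
  stopifnot(inherits(data, "mh_dataset"))
  nrow(data$data)
}

#' Class labels of a dataset
#' @param data An [mh_dataset()].
#' @return Factor of class labels over `schema$classes`.
#' @export
dataset_labels <- function(data) {
  stopifnot(inherits(data, "mh_dataset"))
  data$data[[data$schema$class_column]]
}

#' Feature columns of a dataset
#' @param data An [mh_dataset()].
#' @return Data frame of the attribute columns only, in schema order.
#' @export
dataset_features <- function(data) {
  stopifnot(inherits(data, "mh_dataset"))
  data$data[attr_names(data$schema)]
}

subset_dataset <- function(data, idx) {
  structure(list(data = data$data[idx, , drop = FALSE], schema = data$schema),
            class = "mh_dataset")
}

schema_to_list <- function(schema) {
  list(
    class_column = schema$class_column,
    classes = as.list(schema$classes),
    attributes = lapply(schema$attributes, function(a) {
      x <- list(name = a$name, kind = a$kind)
      if (a$kind == "categorical") x$levels <- as.list(a$levels)
      x
    })
  )
}

schema_from_list <- function(x) {
  for (f in c("class_column", "classes", "attributes")) {
    if (is.null(x[[f]])) stop("schema error: missing `", f, "`", call. = FALSE)
  }
  attrs <- lapply(x$attributes, function(a) {
    attribute_spec(a$name, a$kind, levels = unlist(a$levels))
  })
  mh_schema(attrs, x$class_column, unlist(x$classes))
}

#' Read a schema file
#'
#' @param schema_path Path to a JSON schema file with fields
#'   `class_column`, `classes` and `attributes`.
#' @return An [mh_schema()].
#' @export
read_schema <- function(schema_path) {
  schema_from_list(jsonlite::read_json(schema_path))
}

#' Write a schema file
#' @param schema An [mh_schema()].
#' @param schema_path Output path.
#' @return `schema_path`, invisibly.
#' @export
write_schema <- function(schema, schema_path) {
  jsonlite::write_json(schema_to_list(schema), schema_path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(schema_path)
}

#' Load a dataset from a CSV file and its JSON schema sidecar
#'
#' The CSV must have a header row containing every attribute named in the
#' schema plus the class column; values are parsed per attribute kind.
#'
#' @param csv_path Path to an RFC-4180 CSV file with a header row.
#' @param schema_path Path to the JSON schema sidecar (see [read_schema()]).
#' @return An [mh_dataset()].
#' @export
read_dataset <- function(csv_path, schema_path) {
  schema <- read_schema(schema_path)
  raw <- utils::read.csv(csv_path, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  mh_dataset(raw, schema)
}

#' Write a dataset to a CSV file and JSON schema sidecar
#'
#' @param data An [mh_dataset()].
#' @param csv_path Output CSV path.
#' @param schema_path Output JSON schema path.
#' @return `csv_path`, invisibly.
#' @export
write_dataset <- function(data, csv_path, schema_path) {
  stopifnot(inherits(data, "mh_dataset"))
  df <- data$data
  for (j in seq_along(df)) if (is.factor(df[[j]])) df[[j]] <- as.character(df[[j]])
  utils::write.csv(df, csv_path, row.names = FALSE, quote = TRUE)
  write_schema(data$schema, schema_path)
  invisible(csv_path)
}

#' Partition a dataset into train and test sets
#'
#' Records are shuffled by `seed`, divided into `n_parts` near-equal
#' contiguous folds (remainder records are distributed one per fold
#' starting from the first), and the first `n_train` folds are
#' concatenated as the training set, the rest as the test set. The split
#' emulates the common protocol of dividing data into ten equal parts and
#' using six for training and four for testing.
#'
#' @param data An [mh_dataset()].
#' @param n_parts Number of folds (default 10).
#' @param n_train Number of folds assigned to training (default 6);
#'   must be smaller than `n_parts`.
#' @param seed Integer seed controlling the shuffle.
#' @return A list with elements `train` and `test`, both [mh_dataset()]
#'   objects; their union is the input and they are disjoint.
#' @export
split_train_test <- function(data, n_parts = 10L, n_train = 6L, seed = 42L) {
  stopifnot(inherits(data, "mh_dataset"))
  n_parts <- as.integer(n_parts); n_train <- as.integer(n_train)
  if (n_train >= n_parts) {
    stop("`n_train` must be smaller than `n_parts`", call. = FALSE)
  }
  if (n_train < 1L) stop("`n_train` must be at least 1", call. = FALSE)
  n <- n_records(data)
  if (n < n_parts) {
    stop("dataset has fewer records than `n_parts`", call. = FALSE)
  }
  perm <- with_seed(seed, sample.int(n))
  base <- n %/% n_parts
  extra <- n %% n_parts
  sizes <- rep(base, n_parts) + c(rep(1L, extra), rep(0L, n_parts - extra))
  n_tr <- sum(sizes[seq_len(n_train)])
  list(train = subset_dataset(data, perm[seq_len(n_tr)]),
       test  = subset_dataset(data, perm[seq.int(n_tr + 1L, n)]))
}

#' Per-class record counts
#'
#' Tallies records per class label in `schema$classes` order. These
#' counts are the inputs to the entropy and gain-ratio computations.
#'
#' @param data A non-empty [mh_dataset()].
#' @return Named integer vector of per-class counts with an attribute
#'   `total` holding their sum.
#' @export
class_counts <- function(data) {
  stopifnot(inherits(data, "mh_dataset"))
  if (n_records(data) == 0L) stop("empty dataset", call. = FALSE)
  cnt <- table(dataset_labels(data))
  out <- as.integer(cnt)
  names(out) <- names(cnt)
  attr(out, "total") <- sum(out)
  out
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
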
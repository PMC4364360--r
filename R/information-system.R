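#' Declare one attribute of a tabular dataset
#'
#' An attribute schema records how a column of a clinical table is to be
#' interpreted: as a categorical symbol, or as a numeric measurement that
#' must be discretized against ordered cut-points before rough-set
#' analysis. Exactly one attribute per dataset carries `role = "decision"`
#' (the class label); all others are condition attributes.
#'
#' @param name Column name, as it appears in the CSV header.
#' @param kind `"categorical"` or `"numeric"`.
#' @param role `"condition"` or `"decision"`.
#' @param cut_points Strictly increasing numeric vector of bin edges for
#'   numeric attributes. A value is mapped to the label of the greatest
#'   cut-point less than or equal to it; values below the first edge are
#'   clamped to the first label.
#' @return An object of class `attribute_schema`.
#' @examples
#' attribute_schema("bilirubin", "numeric",
#'   cut_points = c(0.39, 0.80, 1.20, 2.00, 3.00, 4.00))
#' @export
attribute_schema <- function(name, kind = c("categorical", "numeric"),
                             role = c("condition", "decision"),
                             cut_points = NULL) {
  kind <- match.arg(kind)
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.null(cut_points)) {
    cut_points <- as.numeric(cut_points)
    if (any(!is.finite(cut_points)) || is.unsorted(cut_points, strictly = TRUE)) {
      stop("cut_points must be finite and strictly increasing for attribute '",
           name, "'")
    }
  }
  structure(list(name = name, kind = kind, role = role,
                 cut_points = cut_points),
            class = "attribute_schema")
}

#' @export
print.attribute_schema <- function(x, ...) {
  cat(sprintf("<attribute> %s (%s, %s)", x$name, x$kind, x$role))
  if (!is.null(x$cut_points)) {
    cat(" cuts:", paste(x$cut_points, collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

validate_schema_set <- function(schema) {
  stopifnot(is.list(schema), length(schema) >= 2L)
  ok <- vapply(schema, inherits, logical(1), "attribute_schema")
  if (!all(ok)) stop("schema must be a list of attribute_schema objects")
  nms <- vapply(schema, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate attribute names in schema: ",
                               paste(nms[duplicated(nms)], collapse = ", "))
  roles <- vapply(schema, `[[`, character(1), "role")
  if (sum(roles == "decision") != 1L) {
    stop("schema must declare exactly one decision attribute")
  }
  invisible(schema)
}

condition_names <- function(schema) {
  vapply(Filter(function(a) a$role == "condition", schema),
         `[[`, character(1), "name")
}

decision_name <- function(schema) {
  vapply(Filter(function(a) a$role == "decision", schema),
         `[[`, character(1), "name")
}

#' Read an attribute schema from a YAML file
#'
#' The file holds a list of maps with keys `name`, `kind`, `role` and
#' (optionally) `cut_points`, in column order.
#'
#' @param path Path to a YAML schema file.
#' @return A list of [attribute_schema] objects.
#' @seealso [write_schema()]
#' @export
read_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$attributes)) raw <- raw$attributes
  schema <- lapply(raw, function(a) {
    attribute_schema(name = a$name,
                     kind = a$kind %||% "categorical",
                     role = a$role %||% "condition",
                     cut_points = a$cut_points)
  })
  validate_schema_set(schema)
}

#' Write an attribute schema to a YAML file
#'
#' @param schema List of [attribute_schema] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  validate_schema_set(schema)
  out <- lapply(schema, function(a) {
    x <- list(name = a$name, kind = a$kind, role = a$role)
    if (!is.null(a$cut_points)) x$cut_points <- a$cut_points
    x
  })
  yaml::write_yaml(list(attributes = out), path)
  invisible(path)
}

#' Construct an information system
#'
#' An information system is the rough-set view of a classified table:
#' a finite universe of objects described by categorical condition
#' attributes plus one decision attribute (the class label). Cells may
#' hold a missing-value sentinel; decision values may not.
#'
#' @param values Character matrix, objects in rows and condition
#'   attributes in columns (column names required).
#' @param decision Character vector of class labels, one per object.
#' @param object_ids Optional object labels; defaults to `"P1"`,
#'   `"P2"`, ... in row order.
#' @param schema Optional list of [attribute_schema] objects; a plain
#'   all-categorical schema is synthesized when omitted.
#' @param decision_name Name of the decision attribute when `schema` is
#'   omitted.
#' @param missing Sentinel token marking a missing cell (default `"?"`,
#'   the UCI convention).
#' @return An object of class `information_system` with fields
#'   `object_ids`, `values`, `decision`, `schema`, `missing`.
#' @examples
#' v <- cbind(a = c("1", "2", "1"), b = c("x", "x", "y"))
#' information_system(v, decision = c("yes", "no", "yes"))
#' @export
information_system <- function(values, decision, object_ids = NULL,
                               schema = NULL, decision_name = "class",
                               missing = "?") {
  values <- as.matrix(values)
  storage.mode(values) <- "character"
  if (is.null(colnames(values))) stop("values must have column names")
  if (anyDuplicated(colnames(values))) stop("attribute names must be unique")
  decision <- as.character(decision)
  if (length(decision) != nrow(values)) {
    stop("decision length (", length(decision), ") != number of objects (",
         nrow(values), ")")
  }
  if (any(is.na(decision) | decision == missing)) {
    stop("decision values may not be missing")
  }
  if (is.null(object_ids)) {
    object_ids <- paste0("P", seq_len(nrow(values)))
  }
  object_ids <- as.character(object_ids)
  if (length(object_ids) != nrow(values) || anyDuplicated(object_ids)) {
    stop("object_ids must be unique and match the number of rows")
  }
  rownames(values) <- object_ids
  if (is.null(schema)) {
    schema <- c(lapply(colnames(values), attribute_schema,
                       kind = "categorical", role = "condition"),
                list(attribute_schema(decision_name, "categorical",
                                      role = "decision")))
  }
  validate_schema_set(schema)
  if (!setequal(condition_names(schema), colnames(values))) {
    stop("schema condition attributes do not match value columns")
  }
  values[is.na(values)] <- missing
  structure(list(object_ids = object_ids,
                 values = values[, condition_names(schema), drop = FALSE],
                 decision = stats::setNames(decision, object_ids),
                 schema = schema,
                 missing = missing),
            class = "information_system")
}

#' @export
print.information_system <- function(x, ...) {
  cat(sprintf("<information_system> %d objects x %d condition attributes\n",
              n_objects(x), length(attribute_names(x))))
  cat("  conditions:", paste(attribute_names(x), collapse = ", "), "\n")
  cat("  decision:  ", decision_name(x$schema),
      sprintf("(%s)", paste(sort(unique(x$decision)), collapse = "/")), "\n")
  nmiss <- sum(x$values == x$missing)
  if (nmiss > 0) cat("  missing cells:", nmiss, "\n")
  invisible(x)
}

#' @rdname information_system
#' @param x An `information_system`.
#' @export
n_objects <- function(x) length(x$object_ids)

#' @rdname information_system
#' @export
attribute_names <- function(x) colnames(x$values)

#' @rdname information_system
#' @export
has_missing <- function(x) any(x$values == x$missing)

#' Read a classified CSV table into an information system
#'
#' Reads an RFC-4180 CSV with a header row, checks it against the schema,
#' and coerces every cell to a categorical symbol. Rows whose decision
#' value is missing are dropped (their count is recorded in the
#' `"dropped_missing_decision"` attribute of the result). Numeric
#' condition attributes are kept as their literal string representation
#' until [discretize()] is applied.
#'
#' @param path CSV file path.
#' @param schema List of [attribute_schema] objects covering every column
#'   used; extra CSV columns are ignored with a message.
#' @param missing Missing-value sentinel in the file (default `"?"`).
#' @param id_column Optional name of a column holding object identifiers.
#' @return An [information_system].
#' @export
read_table <- function(path, schema, missing = "?", id_column = NULL) {
  validate_schema_set(schema)
  df <- utils::read.csv(path, header = TRUE, colClasses = "character",
                        check.names = FALSE, na.strings = NULL)
  if (nrow(df) == 0L) stop("empty dataset: ", path)
  need <- c(condition_names(schema), decision_name(schema))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("unknown column(s) absent from CSV: ",
         paste(missing_cols, collapse = ", "))
  }
  for (a in schema) {
    if (a$kind == "numeric") {
      col <- df[[a$name]]
      bad <- col != missing & is.na(suppressWarnings(as.numeric(col)))
      if (any(bad)) {
        stop("non-numeric value '", col[which(bad)[1]],
             "' in numeric column '", a$name, "'")
      }
    }
  }
  dn <- decision_name(schema)
  drop <- df[[dn]] == missing | is.na(df[[dn]]) | df[[dn]] == ""
  if (any(drop)) {
    message(sum(drop), " row(s) dropped for missing decision value")
    df <- df[!drop, , drop = FALSE]
    if (nrow(df) == 0L) stop("empty dataset after dropping rows with missing decision")
  }
  ids <- if (!is.null(id_column)) {
    if (!id_column %in% names(df)) stop("unknown column: ", id_column)
    df[[id_column]]
  } else {
    NULL
  }
  out <- information_system(as.matrix(df[, condition_names(schema), drop = FALSE]),
                            decision = df[[dn]], object_ids = ids,
                            schema = schema, missing = missing)
  attr(out, "dropped_missing_decision") <- sum(drop)
  out
}

#' Write an information system back to CSV
#'
#' Inverse of [read_table()]: condition columns in schema order followed
#' by the decision column, missing cells as the sentinel.
#'
#' @param x An [information_system].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  df <- as.data.frame(x$values, stringsAsFactors = FALSE)
  df[[decision_name(x$schema)]] <- unname(x$decision)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Discretize numeric attributes against schema cut-points
#'
#' Every numeric condition value is replaced by the label of the greatest
#' cut-point less than or equal to it; values below the first cut-point
#' clamp to the first label. Categorical attributes pass through
#' unchanged, as do missing cells. The returned schema marks discretized
#' attributes categorical, so the operation is idempotent.
#'
#' @param x An [information_system].
#' @return An [information_system] whose condition values are all
#'   categorical symbols.
#' @examples
#' sch <- list(
#'   attribute_schema("bili", "numeric",
#'                    cut_points = c(0.39, 0.8, 1.2, 2, 3, 4)),
#'   attribute_schema("class", role = "decision"))
#' v <- cbind(bili = c("1.5", "0.2", "4.4"))
#' discretize(information_system(v, c("a", "b", "a"), schema = sch))
#' @export
discretize <- function(x) {
  stopifnot(inherits(x, "information_system"))
  schema <- x$schema
  values <- x$values
  for (i in seq_along(schema)) {
    a <- schema[[i]]
    if (a$role != "condition" || a$kind != "numeric") next
    if (is.null(a$cut_points)) {
      stop("numeric attribute '", a$name, "' has no cut_points")
    }
    labels <- as.character(a$cut_points)
    col <- values[, a$name]
    keep <- col == x$missing
    num <- suppressWarnings(as.numeric(col))
    if (any(is.na(num) & !keep)) {
      stop("non-numeric value in numeric column '", a$name, "'")
    }
    idx <- findInterval(num, a$cut_points)  # 0 when below the first edge
    idx[idx == 0L] <- 1L                    # clamp below range
    new <- labels[idx]
    new[keep] <- x$missing
    values[, a$name] <- new
    schema[[i]] <- attribute_schema(a$name, "categorical", "condition")
  }
  information_system(values, x$decision, object_ids = x$object_ids,
                     schema = schema, missing = x$missing)
}

#' Encode an attribute set as a 0/1 bitmask over a fixed sequence
#'
#' Reduct reports for clinical datasets are conventionally printed as
#' bitmasks over the dataset's canonical attribute order; bit i is 1
#' exactly when the i-th attribute belongs to the set.
#'
#' @param reduct Character vector of attribute names (a subset of
#'   `sequence`).
#' @param sequence Ordered character vector of all attribute names.
#' @return Object of class `reduct_bitmask`: integer 0/1 vector named by
#'   `sequence`.
#' @examples
#' reduct_bitmask(c("Chp", "Vessel"), c("Chp", "ECG", "Vessel"))
#' @export
reduct_bitmask <- function(reduct, sequence) {
  reduct <- as.character(reduct)
  bad <- setdiff(reduct, sequence)
  if (length(bad)) {
    stop("reduct attribute(s) not in sequence: ", paste(bad, collapse = ", "))
  }
  bits <- as.integer(sequence %in% reduct)
  structure(stats::setNames(bits, sequence), class = "reduct_bitmask")
}

#' Decode a reduct bitmask back to an attribute-name set
#'
#' @param bits 0/1 vector (or `reduct_bitmask`).
#' @param sequence Ordered attribute names; defaults to `names(bits)`.
#' @return Character vector of the attributes whose bit is 1.
#' @export
bitmask_to_set <- function(bits, sequence = names(bits)) {
  force(sequence)
  bits <- as.integer(bits)
  if (length(bits) != length(sequence)) {
    stop("bitmask length != sequence length")
  }
  sequence[bits == 1L]
}

#' @export
print.reduct_bitmask <- function(x, ...) {
  cat("[", paste(unclass(x), collapse = " "), "]\n", sep = "")
  invisible(x)
}
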
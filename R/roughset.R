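#' Indiscernibility partition of an attribute subset
#'
#' Two objects are indiscernible with respect to an attribute set P when
#' they agree on every attribute of P. The equivalence classes of this
#' relation partition the universe; the empty attribute set induces the
#' single-block partition.
#'
#' @param x An [information_system] with no missing cells.
#' @param attrs Character vector of condition attribute names (may be
#'   empty).
#' @param universe Optional subset of object ids to partition; defaults
#'   to all objects.
#' @return Object of class `partition`: list with `universe` (character
#'   vector) and `blocks` (list of character vectors, each sorted, the
#'   list ordered by first object appearance).
#' @examples
#' h <- heart_toy()
#' ind_partition(h, "Chp")   # {{P1,P4},{P2},{P3,P5,P6}}
#' @export
ind_partition <- function(x, attrs, universe = NULL) {
  stopifnot(inherits(x, "information_system"))
  attrs <- as.character(attrs)
  bad <- setdiff(attrs, attribute_names(x))
  if (length(bad)) stop("unknown attribute(s): ", paste(bad, collapse = ", "))
  universe <- universe %||% x$object_ids
  stopifnot(all(universe %in% x$object_ids))
  if (has_missing_in(x, universe, attrs)) {
    stop("information system has missing cells; run handle_missing() first")
  }
  if (length(attrs) == 0L) {
    blocks <- if (length(universe)) list(sort(universe)) else list()
    return(new_partition(universe, blocks))
  }
  sig <- apply(x$values[universe, attrs, drop = FALSE], 1L,
               paste, collapse = "\r")
  groups <- split(universe, factor(sig, levels = unique(sig)))
  new_partition(universe, lapply(unname(groups), sort))
}

new_partition <- function(universe, blocks) {
  structure(list(universe = universe, blocks = blocks), class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d objects in %d block(s)\n",
              length(x$universe), length(x$blocks)))
  for (b in x$blocks) cat("  {", paste(b, collapse = ", "), "}\n")
  invisible(x)
}

has_missing_in <- function(x, universe, attrs) {
  length(attrs) > 0L &&
    any(x$values[universe, attrs, drop = FALSE] == x$missing)
}

# block membership index: named integer vector object id -> block number
block_index <- function(p) {
  idx <- integer(0)
  for (i in seq_along(p$blocks)) {
    idx[p$blocks[[i]]] <- i
  }
  idx
}

#' Lower/upper approximations and boundary region of a decision class
#'
#' Under the indiscernibility partition of `attrs`, the lower
#' approximation of a class collects the blocks wholly contained in it
#' (objects certainly in the class), the upper approximation the blocks
#' intersecting it (objects possibly in the class), and the boundary
#' region is their difference — nonempty exactly when the table is
#' inconsistent for that class.
#'
#' @inheritParams ind_partition
#' @param class_label A value occurring in the decision column.
#' @return Object of class `approximation_set` with fields `class_label`,
#'   `lower`, `upper`, `boundary` (sorted character vectors of object
#'   ids).
#' @examples
#' h <- heart_toy()
#' approximations(h, attribute_names(h), "Yes")
#' @export
approximations <- function(x, attrs, class_label, universe = NULL) {
  universe <- universe %||% x$object_ids
  if (!class_label %in% x$decision[universe]) {
    stop("unknown class label: ", class_label)
  }
  p <- ind_partition(x, attrs, universe)
  members <- universe[x$decision[universe] == class_label]
  lower <- character(0)
  upper <- character(0)
  for (b in p$blocks) {
    inter <- intersect(b, members)
    if (length(inter)) upper <- c(upper, b)
    if (length(inter) == length(b)) lower <- c(lower, b)
  }
  structure(list(class_label = class_label,
                 lower = sort(lower), upper = sort(upper),
                 boundary = sort(setdiff(upper, lower))),
            class = "approximation_set")
}

#' @export
print.approximation_set <- function(x, ...) {
  cat(sprintf("<approximation_set> class '%s'\n", x$class_label))
  cat("  lower:    {", paste(x$lower, collapse = ", "), "}\n")
  cat("  upper:    {", paste(x$upper, collapse = ", "), "}\n")
  cat("  boundary: {", paste(x$boundary, collapse = ", "), "}\n")
  invisible(x)
}

#' Positive region of the decision
#'
#' The union over all decision classes of their lower approximations
#' under `IND(attrs)` — the objects that can be classified with
#' certainty. Equals the whole universe exactly when no
#' indiscernibility block is class-mixed (a consistent table).
#'
#' @inheritParams ind_partition
#' @return Sorted character vector of object ids.
#' @examples
#' h <- heart_toy()
#' positive_region(h, attribute_names(h))  # P1..P4; P5,P6 conflict
#' @export
positive_region <- function(x, attrs, universe = NULL) {
  universe <- universe %||% x$object_ids
  p <- ind_partition(x, attrs, universe)
  pure <- Filter(function(b) length(unique(x$decision[b])) == 1L, p$blocks)
  sort(unlist(pure, use.names = FALSE) %||% character(0))
}

#' Count the attribute subsets competing for reducts
#'
#' Excluding the empty set and the full attribute set, `n` attributes
#' yield `2^n - 2` proper nonempty subsets, `choose(n, k)` of each size
#' `k` in `1..n-1`.
#'
#' @param n Number of condition attributes (>= 1).
#' @return Object of class `subset_count`: list with `n`, `total`, and
#'   `per_size` (named numeric vector over sizes `1..n-1`).
#' @examples
#' subset_counts(18)$total     # 262142
#' subset_counts(18)$per_size[["9"]]  # 48620
#' @export
subset_counts <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n)) {
    stop("n must be a positive integer")
  }
  sizes <- seq_len(max(n - 1, 0))
  per_size <- stats::setNames(choose(n, sizes), sizes)
  structure(list(n = n, total = 2^n - 2, per_size = per_size),
            class = "subset_count")
}

#' Pairwise (Rand-type) similarity of two partitions
#'
#' The fraction of unordered object pairs on which the two partitions
#' agree — both placing the pair in one block, or both separating it.
#' Symmetric, in [0, 1], and equal to 1 exactly when the partitions are
#' identical; used to accept approximate reducts.
#'
#' @param p,q Objects of class `partition` over the same universe of at
#'   least two objects.
#' @return A fraction in [0, 1].
#' @examples
#' h <- heart_toy()
#' partition_similarity(ind_partition(h, "Chp"),
#'                      ind_partition(h, attribute_names(h)))  # 12/15
#' @export
partition_similarity <- function(p, q) {
  stopifnot(inherits(p, "partition"), inherits(q, "partition"))
  if (!setequal(p$universe, q$universe)) stop("universe mismatch")
  n <- length(p$universe)
  if (n < 2L) stop("similarity needs at least 2 objects")
  pi <- block_index(p)[p$universe]
  qi <- block_index(q)[p$universe]
  agree <- 0L
  for (i in seq_len(n - 1L)) {
    same_p <- pi[i] == pi[(i + 1L):n]
    same_q <- qi[i] == qi[(i + 1L):n]
    agree <- agree + sum(same_p == same_q)
  }
  agree / (n * (n - 1L) / 2L)
}

#' Dependency degree gamma of the decision on an attribute set
#'
#' |positive region under IND(attrs)| / |universe|; an alternative
#' similarity measure for approximate reducts (ratio to the
#' full-attribute gamma).
#'
#' @inheritParams ind_partition
#' @return Fraction in [0, 1].
#' @export
dependency_degree <- function(x, attrs, universe = NULL) {
  universe <- universe %||% x$object_ids
  length(positive_region(x, attrs, universe)) / length(universe)
}

#' Exhaustive reduct search by indiscernibility comparison
#'
#' Enumerates every proper nonempty subset P of the condition attributes
#' (optionally limited to a size range) and accepts P as a reduct when
#' its indiscernibility partition matches that of the full attribute set
#' A. The comparison universe is the positive region of A: in exact mode
#' acceptance requires `IND(P)` and `IND(A)` restricted to that region to
#' be identical; in approximate mode their pairwise similarity must
#' exceed `threshold`. No minimality filter is applied, so accepted sets
#' are superset-closed in exact mode. The core is the intersection of
#' all accepted sets.
#'
#' @inheritParams ind_partition
#' @param mode `"exact"` or `"approx"`.
#' @param threshold Similarity threshold for approximate mode; a subset
#'   is accepted when similarity is strictly greater (default 0.90).
#' @param size_range Optional integer vector `c(min, max)` limiting
#'   subset sizes.
#' @param semantics `"restricted"` (default) compares indiscernibility
#'   restricted to the positive region of A, the reading under which the
#'   six-patient worked example yields both of its textbook reducts;
#'   `"pos"` instead accepts subsets preserving the positive region over
#'   the whole universe (the classical criterion).
#' @param similarity `"pairwise"` (default, Rand-type pair agreement) or
#'   `"gamma"` (ratio of dependency degrees) for approximate mode.
#' @param max_attrs Hard cap on |A| for exhaustive search without a
#'   `size_range` (default 20).
#' @return Object of class `reduct_report`: list with `mode`,
#'   `threshold`, `semantics`, `reducts` (list of entries with `attrs`,
#'   `size`, `similarity`), `core`, `counts` (a [subset_counts] object),
#'   `attribute_sequence`, `positive_region`.
#' @examples
#' r <- find_reducts(heart_toy())
#' lapply(r$reducts, `[[`, "attrs")  # {Chp,Vessel}, {ECG,Vessel}
#' r$core                            # "Vessel"
#' @export
find_reducts <- function(x, mode = c("exact", "approx"), threshold = 0.90,
                         size_range = NULL,
                         semantics = c("restricted", "pos"),
                         similarity = c("pairwise", "gamma"),
                         max_attrs = 20L) {
  stopifnot(inherits(x, "information_system"))
  mode <- match.arg(mode)
  semantics <- match.arg(semantics)
  similarity <- match.arg(similarity)
  if (has_missing(x)) {
    stop("information system has missing cells; run handle_missing() first")
  }
  A <- attribute_names(x)
  n <- length(A)
  counts <- subset_counts(max(n, 1L))
  if (is.null(size_range)) {
    if (n > max_attrs) {
      stop("exhaustive search over ", n, " attributes exceeds max_attrs = ",
           max_attrs, "; provide a size_range")
    }
    size_range <- c(1L, n - 1L)
  }
  sizes <- seq(max(1L, size_range[1]), min(n - 1L, size_range[2]))

  pos <- positive_region(x, A)
  ref_universe <- if (semantics == "restricted") pos else x$object_ids
  pos_ref <- pos

  reducts <- list()
  if (n >= 2L && length(sizes) && length(ref_universe) >= 2L) {
    full_part <- ind_partition(x, A, ref_universe)
    full_key <- partition_key(full_part)
    gamma_full <- dependency_degree(x, A)
    for (k in sizes) {
      combos <- utils::combn(A, k, simplify = FALSE)
      for (P in combos) {
        if (semantics == "pos") {
          if (mode == "exact") {
            ok <- setequal(positive_region(x, P), pos_ref)
            score <- if (ok) 1.0 else NA_real_
          } else {
            score <- if (gamma_full > 0) {
              dependency_degree(x, P) / gamma_full
            } else 1.0
            ok <- score > threshold
          }
        } else {
          part <- ind_partition(x, P, ref_universe)
          if (mode == "exact") {
            ok <- identical(partition_key(part), full_key)
            score <- if (ok) 1.0 else NA_real_
          } else {
            score <- if (similarity == "pairwise") {
              partition_similarity(part, full_part)
            } else if (gamma_full > 0) {
              dependency_degree(x, P) / gamma_full
            } else 1.0
            ok <- score > threshold
          }
        }
        if (ok) {
          reducts[[length(reducts) + 1L]] <-
            list(attrs = P, size = length(P), similarity = score)
        }
      }
    }
  }
  core <- if (length(reducts)) {
    Reduce(intersect, lapply(reducts, `[[`, "attrs"))
  } else {
    character(0)
  }
  structure(list(mode = mode,
                 threshold = if (mode == "approx") threshold else NA_real_,
                 semantics = semantics,
                 reducts = reducts, core = core,
                 counts = counts,
                 attribute_sequence = A,
                 positive_region = pos),
            class = "reduct_report")
}

# canonical comparable encoding of a partition
partition_key <- function(p) {
  lapply(p$blocks[order(vapply(p$blocks, `[[`, character(1), 1L))], sort)
}

#' @export
print.reduct_report <- function(x, ...) {
  cat(sprintf("<reduct_report> mode=%s%s, %d reduct(s) of %d candidates\n",
              x$mode,
              if (x$mode == "approx") sprintf(" (threshold %.2f)", x$threshold)
              else "",
              length(x$reducts), x$counts$total))
  sizes <- vapply(x$reducts, `[[`, numeric(1), "size")
  if (length(sizes)) {
    tab <- table(sizes)
    cat("  per size:", paste(sprintf("%s:%d", names(tab), tab),
                             collapse = "  "), "\n")
  }
  cat("  core: {", paste(x$core, collapse = ", "), "}\n")
  invisible(x)
}

#' Per-size tally of accepted reducts
#'
#' Summarizes a reduct report as a table of subset size versus number of
#' candidate subsets and number of accepted reducts, the shape in which
#' reduct searches over clinical datasets are conventionally reported.
#'
#' @param report A `reduct_report` from [find_reducts()].
#' @return Data frame with columns `size`, `n_subsets`, `n_reducts`.
#' @export
reduct_size_table <- function(report) {
  stopifnot(inherits(report, "reduct_report"))
  sizes <- as.integer(names(report$counts$per_size))
  tally <- table(factor(vapply(report$reducts, `[[`, numeric(1), "size"),
                        levels = sizes))
  data.frame(size = sizes,
             n_subsets = as.numeric(report$counts$per_size),
             n_reducts = as.integer(tally))
}

#' Serialize a reduct report to JSON
#'
#' Writes the report with both name-set and bitmask encodings of every
#' accepted reduct, the core, the candidate subset counts, and the
#' per-size tally.
#'
#' @param report A `reduct_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_reduct_report <- function(report, path) {
  stopifnot(inherits(report, "reduct_report"))
  seq_ <- report$attribute_sequence
  out <- list(
    mode = report$mode,
    threshold = report$threshold,
    semantics = report$semantics,
    attribute_sequence = seq_,
    positive_region = report$positive_region,
    subset_counts = list(n = report$counts$n, total = report$counts$total,
                         per_size = as.list(report$counts$per_size)),
    per_size_tally = reduct_size_table(report),
    core = list(attrs = report$core,
                bitmask = as.integer(reduct_bitmask(report$core, seq_))),
    reducts = lapply(report$reducts, function(r) {
      list(attrs = r$attrs, size = r$size, similarity = r$similarity,
           bitmask = as.integer(reduct_bitmask(r$attrs, seq_)))
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' The six-patient heart-disease demonstration table
#'
#' A minimal information system of six patients described by chest-pain
#' type (Chp), resting electrocardiogram (ECG) and number of major
#' vessels (Vessel), with a yes/no disease label. Patients P5 and P6
#' share all condition values but disagree on the label, so the table is
#' inconsistent and its positive region is P1–P4. Its exact reducts are
#' \{Chp, Vessel\} and \{ECG, Vessel\}, with core \{Vessel\}.
#'
#' @return An [information_system] with 6 objects and 3 condition
#'   attributes.
#' @examples
#' heart_toy()
#' @export
heart_toy <- function() {
  path <- system.file("extdata", "heart_toy.csv", package = "rsbpnn")
  schema <- read_schema(system.file("extdata", "heart_toy_schema.yaml",
                                    package = "rsbpnn"))
  read_table(path, schema)
}
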
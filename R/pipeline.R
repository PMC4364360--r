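#' End-to-end run: clean, discretize, select reducts, train, evaluate
#'
#' Orchestrates the two-stage workflow on one classified table. Stage
#' one handles missing values and discretizes numeric attributes, then
#' enumerates reducts by the indiscernibility criterion. Stage two — run
#' for each requested reduct plus the all-features baseline — projects
#' the table onto the reduct, and for every train fraction draws a
#' seeded split, cross-validates within the training portion, retrains
#' on the full training portion, and evaluates on the held-out test set.
#'
#' Reduct selection is explicit: pass attribute-name lists (or bitmasks
#' decoded with [bitmask_to_set()]) in `selected_reducts`, or set
#' `top_k_by_cv` to pick the k accepted reducts with the highest
#' training-CV accuracy (a convenience that reuses training data for
#' selection, so its CV scores are optimistic).
#'
#' @param table An [information_system] (possibly with missing cells).
#' @param missing_threshold Passed to [handle_missing()] (default 0.25).
#' @param reduct_mode,reduct_threshold,size_range Passed to
#'   [find_reducts()].
#' @param selected_reducts List of character vectors naming the reducts
#'   to classify with; `NULL` trains on the all-features baseline only.
#' @param top_k_by_cv Optional integer; selects this many accepted
#'   reducts by training-CV accuracy instead of `selected_reducts`.
#' @param train_fractions Numeric vector of train proportions
#'   (default `c(0.8, 0.7, 0.6)`).
#' @param k_folds Cross-validation folds within the training portion
#'   (default 10).
#' @param config A [bpnn_config()].
#' @param positive_label Decision value treated as positive (default:
#'   the label coded 1 after encoding, i.e. the second sorted level).
#' @param seed Master seed; stage seeds are derived from it.
#' @param classify Set `FALSE` to stop after reduct search (stage one
#'   only).
#' @return A list of class `rsbpnn_run` with `clean` (the
#'   [handle_missing()] report), `reducts` (the `reduct_report`),
#'   `metrics_grid` (data frame: reduct x train fraction, with CV and
#'   test accuracy), `best` (row with the highest test accuracy, with
#'   its full [metrics()] and [roc_auc()]), and `seed`.
#' @examples
#' run <- run_pipeline(heart_toy(), classify = FALSE)
#' length(run$reducts$reducts)  # 2
#' @export
run_pipeline <- function(table, missing_threshold = 0.25,
                         reduct_mode = c("exact", "approx"),
                         reduct_threshold = 0.90, size_range = NULL,
                         selected_reducts = NULL, top_k_by_cv = NULL,
                         train_fractions = c(0.8, 0.7, 0.6),
                         k_folds = 10L, config = bpnn_config(),
                         positive_label = NULL, seed = 1L,
                         classify = TRUE) {
  stopifnot(inherits(table, "information_system"))
  reduct_mode <- match.arg(reduct_mode)

  clean <- handle_missing(table, threshold = missing_threshold)
  tab <- discretize(clean$table)

  reducts <- find_reducts(tab, mode = reduct_mode,
                          threshold = reduct_threshold,
                          size_range = size_range)
  out <- list(clean = clean, reducts = reducts, seed = seed)
  class(out) <- "rsbpnn_run"
  if (!classify) return(out)

  A <- attribute_names(tab)
  enc <- encode_features(tab)
  labels <- sort(unique(tab$decision))
  if (length(labels) != 2L) {
    stop("classification stage needs a binary decision, got: ",
         paste(labels, collapse = ", "))
  }
  positive_label <- positive_label %||% labels[2]
  if (!positive_label %in% labels) {
    stop("positive_label '", positive_label, "' not a decision value")
  }
  y <- as.integer(tab$decision == positive_label)

  sel <- selected_reducts
  if (!is.null(sel)) {
    sel <- lapply(sel, function(r) {
      bad <- setdiff(r, A)
      if (length(bad)) stop("unknown attribute: ", paste(bad, collapse = ", "))
      r
    })
    names(sel) <- names(selected_reducts) %||%
      paste0("R", seq_along(sel))
  } else if (!is.null(top_k_by_cv) && length(reducts$reducts)) {
    cand <- lapply(reducts$reducts, `[[`, "attrs")
    cv <- vapply(seq_along(cand), function(i) {
      cv_bpnn(enc[, cand[[i]], drop = FALSE], y, config, k = k_folds,
              seed = seed + i)$mean_accuracy
    }, numeric(1))
    keep <- order(cv, decreasing = TRUE)[seq_len(min(top_k_by_cv,
                                                     length(cand)))]
    sel <- stats::setNames(cand[keep], paste0("R", keep))
  }
  runs <- c(sel, list(`All features` = A))

  grid <- list()
  best <- NULL
  for (rn in names(runs)) {
    feats <- runs[[rn]]
    Xr <- enc[, feats, drop = FALSE]
    for (fr in train_fractions) {
      sp <- split_ids(seq_len(nrow(Xr)), train_fraction = fr, seed = seed)
      cv <- cv_bpnn(Xr[sp$train, , drop = FALSE], y[sp$train], config,
                    k = min(k_folds, length(sp$train)), seed = seed)
      fit <- train_bpnn(Xr[sp$train, , drop = FALSE], y[sp$train], config)
      pred <- predict(fit, Xr[sp$test, , drop = FALSE])
      cm <- confusion(y[sp$test], pred$labels, positive_label = 1)
      ms <- metrics(cm)
      row <- data.frame(reduct = rn, n_attrs = length(feats),
                        train_fraction = fr,
                        cv_accuracy = cv$mean_accuracy,
                        test_accuracy = ms$accuracy,
                        stringsAsFactors = FALSE)
      grid[[length(grid) + 1L]] <- row
      if (is.null(best) || ms$accuracy > best$metrics$accuracy) {
        roc <- if (length(unique(y[sp$test])) == 2L) {
          roc_auc(pred$scores, y[sp$test], positive_label = 1)
        }
        best <- list(reduct = rn, attrs = feats, train_fraction = fr,
                     confusion = cm, metrics = ms, roc = roc, model = fit)
      }
    }
  }
  out$metrics_grid <- do.call(rbind, grid)
  out$best <- best
  out$positive_label <- positive_label
  out
}

#' @export
print.rsbpnn_run <- function(x, ...) {
  cat("<rsbpnn_run>\n")
  print(x$clean)
  print(x$reducts)
  if (!is.null(x$metrics_grid)) {
    cat("metrics grid:\n")
    print(x$metrics_grid, row.names = FALSE)
    cat(sprintf("best: %s at train fraction %.1f, test accuracy %.1f %%\n",
                x$best$reduct, x$best$train_fraction,
                x$best$metrics$accuracy))
  }
  invisible(x)
}

# integer-code the categorical grid for the network: each attribute's
# symbols are mapped to 1..k; numeric-looking symbols keep their own
# numeric value so ordinal structure (e.g. cut-point labels) survives
encode_features <- function(x) {
  stopifnot(inherits(x, "information_system"))
  if (has_missing(x)) stop("encode_features needs a complete table")
  cols <- lapply(attribute_names(x), function(a) {
    col <- x$values[, a]
    num <- suppressWarnings(as.numeric(col))
    if (!any(is.na(num))) num else as.numeric(factor(col, levels = unique(col)))
  })
  out <- do.call(cbind, cols)
  colnames(out) <- attribute_names(x)
  rownames(out) <- x$object_ids
  out
}
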
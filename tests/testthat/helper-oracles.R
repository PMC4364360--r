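# Shared fixtures and independent oracles for the test suite.

# build an information system from a data frame whose last column is the class
is_from_df <- function(df, missing = "?") {
  dn <- names(df)[ncol(df)]
  information_system(as.matrix(df[-ncol(df)]), decision = df[[dn]],
                     decision_name = dn, missing = missing)
}

# random categorical table
random_is <- function(n_obj, n_attr, card = 3, n_class = 2, seed = 1) {
  withr::with_seed(seed, {
    v <- matrix(sample(as.character(seq_len(card)), n_obj * n_attr,
                       replace = TRUE),
                n_obj, n_attr,
                dimnames = list(NULL, paste0("a", seq_len(n_attr))))
    information_system(v, sample(as.character(seq_len(n_class)), n_obj,
                                 replace = TRUE))
  })
}

# Partition oracle: all-pairs discernibility check. Two objects fall in
# the same block iff no attribute in attrs discerns them; blocks built
# by transitive closure over explicit pair comparisons.
oracle_partition <- function(x, attrs, universe = x$object_ids) {
  n <- length(universe)
  parent <- seq_len(n)
  findr <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (length(attrs) > 0 && n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (all(x$values[universe[i], attrs] == x$values[universe[j], attrs])) {
        ri <- findr(i); rj <- findr(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), findr, integer(1))
  blocks <- lapply(unname(split(universe, roots)), sort)
  if (length(attrs) == 0) blocks <- list(sort(universe))
  blocks[order(vapply(blocks, `[[`, character(1), 1))]
}

canon_blocks <- function(p) {
  lapply(p$blocks[order(vapply(p$blocks, `[[`, character(1), 1))], sort)
}

# AUC oracle: fraction of (positive, negative) pairs ranked correctly,
# ties counted one half (Mann-Whitney).
oracle_auc <- function(scores, y, positive = 1) {
  ps <- scores[y == positive]
  ns <- scores[y != positive]
  tot <- 0
  for (p in ps) for (q in ns) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(ps) * length(ns))
}

# central finite-difference gradient of the batch MSE wrt every weight
fd_gradient <- function(model, X, y, eps = 1e-6) {
  f <- function(m) mean((rsbpnn:::bpnn_forward(m, X)$yhat - y)^2)
  out <- list()
  for (nm in c("W1", "b1", "W2", "b2")) {
    g <- model[[nm]]
    for (i in seq_along(g)) {
      mp <- model; mp[[nm]][i] <- mp[[nm]][i] + eps
      mm <- model; mm[[nm]][i] <- mm[[nm]][i] - eps
      g[i] <- (f(mp) - f(mm)) / (2 * eps)
    }
    out[[nm]] <- g
  }
  out
}

# the 13-attribute canonical ordering of the Statlog heart features
heart_sequence <- c("age", "sex", "Chp", "Bp", "Sch", "Fbs", "Ecg",
                    "Mhrt", "Exian", "Opk", "slope", "vessel", "Thal")
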
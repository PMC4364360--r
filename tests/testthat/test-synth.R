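test_that("generated tables carry the declared structure", {
  g <- gen_info_system(synth_spec(n_objects = 30, n_informative = 2,
                                  n_redundant = 1, n_noise = 2, seed = 7))
  expect_equal(n_objects(g$table), 30L)
  expect_setequal(attribute_names(g$table),
                  c("inf1", "inf2", "red1", "noise1", "noise2"))
  expect_equal(g$planted, c("inf1", "inf2"))
  expect_true(g$redundancy_map[["red1"]] %in% g$planted)
  # redundant attribute induces the same partition as its source
  expect_equal(canon_blocks(ind_partition(g$table, "red1")),
               canon_blocks(ind_partition(g$table, g$redundancy_map[["red1"]])))
  # same seed, same dataset
  g2 <- gen_info_system(synth_spec(n_objects = 30, n_informative = 2,
                                   n_redundant = 1, n_noise = 2, seed = 7))
  expect_identical(g2$table$values, g$table$values)
  expect_identical(g2$table$decision, g$table$decision)
})

test_that("consistent tables have a full positive region; flipped labels shrink it", {
  g <- gen_info_system(synth_spec(n_objects = 40, seed = 19))
  expect_setequal(positive_region(g$table, attribute_names(g$table)),
                  g$table$object_ids)
  gi <- gen_info_system(synth_spec(n_objects = 60, n_informative = 1,
                                   n_redundant = 0, n_noise = 1,
                                   cardinality = 2,
                                   inconsistency_rate = 0.2, seed = 19))
  pos <- positive_region(gi$table, attribute_names(gi$table))
  expect_lt(length(pos), n_objects(gi$table))
})

test_that("exact reduct search recovers the planted minimal structure", {
  # decision-preserving (pos) semantics: the minimal accepted subsets
  # are exactly one attribute per informative slot, with redundant
  # recodings interchangeable with their sources
  for (seed in c(7, 1, 2)) {
    g <- gen_info_system(synth_spec(n_objects = 30, n_informative = 2,
                                    n_redundant = 1, n_noise = 2,
                                    seed = seed))
    rep <- find_reducts(g$table, mode = "exact", semantics = "pos")
    sizes <- vapply(rep$reducts, `[[`, numeric(1), "size")
    expect_equal(min(sizes), length(g$planted))
    mins <- lapply(rep$reducts[sizes == min(sizes)], `[[`, "attrs")
    for (m in mins) {
      canonical <- vapply(m, function(a) {
        if (a %in% names(g$redundancy_map)) g$redundancy_map[[a]] else a
      }, character(1))
      expect_setequal(unname(canonical), g$planted)
    }
    # and the planted set itself is among them
    expect_true(any(vapply(mins, setequal, logical(1), g$planted)))
  }
})

test_that("missing-value injection hits the stated rate and spares the decision", {
  g <- gen_info_system(synth_spec(n_objects = 100, n_informative = 2,
                                  n_redundant = 1, n_noise = 2, seed = 23))
  expect_identical(inject_missing(g$table, 0, seed = 1)$values,
                   g$table$values)
  all_miss <- inject_missing(g$table, 1, seed = 1)
  expect_true(all(all_miss$values == all_miss$missing))
  expect_false(any(all_miss$decision == all_miss$missing))
  # 100 x 5 grid at rate 0.1: count within 3 sigma of Binomial(500, 0.1)
  some <- inject_missing(g$table, 0.1, seed = 99)
  n_masked <- sum(some$values == some$missing)
  expect_gte(n_masked, 30)
  expect_lte(n_masked, 70)
  # handle_missing is the identity when nothing is missing
  hm <- handle_missing(g$table)
  expect_equal(hm$table$values, g$table$values)
})

test_that("classification sets are seeded, integer-coded and separation-driven", {
  cl <- gen_classification(n = 100, d = 3, class_separation = 6, seed = 31)
  expect_equal(dim(cl$X), c(100L, 3L))
  expect_true(all(cl$X >= 1 & cl$X <= 10 & cl$X == floor(cl$X)))
  expect_setequal(unique(cl$y), c(0L, 1L))
  expect_identical(gen_classification(n = 100, d = 3, class_separation = 6,
                                      seed = 31), cl)
  # wide separation: a trained network generalizes almost perfectly
  sp <- split_ids(seq_len(100), 0.8, seed = 1)
  fit <- train_bpnn(cl$X[sp$train, ], cl$y[sp$train],
                    bpnn_config(max_epochs = 300, seed = 2))
  acc <- mean(predict(fit, cl$X[sp$test, ])$labels == cl$y[sp$test]) * 100
  expect_gte(acc, 95)
  # zero separation: accuracy within 3 sigma of coin flipping
  cl0 <- gen_classification(n = 100, d = 3, class_separation = 0, seed = 31)
  fit0 <- train_bpnn(cl0$X[sp$train, ], cl0$y[sp$train],
                     bpnn_config(max_epochs = 300, seed = 2))
  acc0 <- mean(predict(fit0, cl0$X[sp$test, ])$labels == cl0$y[sp$test])
  expect_lt(abs(acc0 - 0.5), 3 * sqrt(0.25 / 20) + 1e-9)
})
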
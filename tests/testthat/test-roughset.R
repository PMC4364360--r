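h6 <- heart_toy()
A6 <- attribute_names(h6)

test_that("indiscernibility blocks of the worked example are reproduced", {
  expect_equal(canon_blocks(ind_partition(h6, "Chp")),
               list(c("P1", "P4"), "P2", c("P3", "P5", "P6")))
  expect_equal(canon_blocks(ind_partition(h6, A6)),
               list("P1", "P2", "P3", "P4", c("P5", "P6")))
  # empty attribute set: the single-block partition
  expect_equal(ind_partition(h6, character(0))$blocks, list(paste0("P", 1:6)))
  expect_error(ind_partition(h6, "nope"), "unknown attribute")
})

test_that("partitions agree with the all-pairs discernibility oracle", {
  cases <- expand.grid(n = c(5, 8, 12), k = c(2, 4, 6), seed = 1:3)
  for (i in seq_len(nrow(cases))) {
    x <- random_is(cases$n[i], cases$k[i], seed = cases$seed[i] + 100 * i)
    for (m in 1:cases$k[i]) {
      attrs <- paste0("a", sample(seq_len(cases$k[i]), m))
      expect_equal(canon_blocks(ind_partition(x, attrs)),
                   oracle_partition(x, attrs),
                   info = sprintf("case %d attrs %s", i,
                                  paste(attrs, collapse = ",")))
    }
  }
})

test_that("partition laws hold: disjoint covering blocks, union refines", {
  for (seed in 1:5) {
    x <- random_is(10, 4, seed = seed)
    p <- ind_partition(x, c("a1", "a2"))
    all_ids <- sort(unlist(p$blocks))
    expect_equal(all_ids, sort(x$object_ids))       # covering
    expect_equal(anyDuplicated(all_ids), 0L)        # disjoint
    # IND(P union Q) refines IND(P): each finer block inside one coarser
    q <- ind_partition(x, c("a1", "a2", "a3"))
    for (b in q$blocks) {
      host <- Filter(function(blk) all(b %in% blk), p$blocks)
      expect_length(host, 1)
    }
  }
})

test_that("approximations sandwich the class and match the worked example", {
  yes <- approximations(h6, A6, "Yes")
  expect_equal(yes$lower, c("P1", "P3"))
  expect_equal(yes$upper, c("P1", "P3", "P5", "P6"))
  expect_equal(yes$boundary, c("P5", "P6"))
  no <- approximations(h6, A6, "No")
  expect_equal(no$lower, c("P2", "P4"))
  expect_equal(no$upper, c("P2", "P4", "P5", "P6"))
  expect_error(approximations(h6, A6, "Maybe"), "unknown class")
  # sandwich on random tables: lower <= class members <= upper
  for (seed in 1:5) {
    x <- random_is(12, 3, seed = seed + 40)
    for (cl in unique(x$decision)) {
      ap <- approximations(x, c("a1", "a2"), cl)
      members <- sort(x$object_ids[x$decision == cl])
      expect_true(all(ap$lower %in% members))
      expect_true(all(members %in% ap$upper))
      expect_equal(ap$boundary, sort(setdiff(ap$upper, ap$lower)))
    }
  }
})

test_that("positive region collects exactly the certainly-classifiable objects", {
  expect_equal(positive_region(h6, A6), c("P1", "P2", "P3", "P4"))
  # consistent one-class table: everything is positive
  cons <- information_system(cbind(a = c("1", "2", "3")), rep("x", 3))
  expect_equal(positive_region(cons, "a"), c("P1", "P2", "P3"))
  # constant attribute in a two-class table: one mixed block, empty region
  flat <- information_system(cbind(a = c("1", "1", "1", "1")),
                             c("x", "y", "x", "y"))
  expect_length(positive_region(flat, "a"), 0)
  # positive region is U iff no full-attribute block is class-mixed
  for (seed in 1:5) {
    x <- random_is(10, 3, seed = seed + 60)
    pos <- positive_region(x, attribute_names(x))
    mixed <- Filter(function(b) length(unique(x$decision[b])) > 1,
                    ind_partition(x, attribute_names(x))$blocks)
    expect_equal(setequal(pos, x$object_ids), length(mixed) == 0)
  }
})

test_that("subset counting matches the combinatorial identities", {
  sc <- subset_counts(18)
  expect_equal(sc$total, 262142)
  expect_equal(unname(sc$per_size[["9"]]), 48620)
  expect_equal(sum(sc$per_size), sc$total)
  expect_equal(subset_counts(9)$total, 510)
  expect_equal(subset_counts(13)$total, 8190)
  sc2 <- subset_counts(2)
  expect_equal(sc2$total, 2)
  expect_equal(unname(sc2$per_size), 2)
  expect_equal(subset_counts(1)$total, 0)
  expect_error(subset_counts(0), "positive integer")
})

test_that("partition similarity is the pair-agreement fraction", {
  p_chp <- ind_partition(h6, "Chp")
  p_all <- ind_partition(h6, A6)
  expect_equal(partition_similarity(p_chp, p_all), 12 / 15)
  expect_equal(partition_similarity(p_all, p_chp), 12 / 15)  # symmetric
  expect_equal(partition_similarity(p_all, p_all), 1.0)
  # all-singletons vs one-block on 2 objects -> total disagreement
  two <- information_system(cbind(a = c("1", "2")), c("x", "y"))
  expect_equal(partition_similarity(ind_partition(two, "a"),
                                    ind_partition(two, character(0))), 0)
  # in [0,1] and 1 iff identical, over random pairs
  for (seed in 1:6) {
    x <- random_is(9, 3, seed = seed + 80)
    p <- ind_partition(x, "a1")
    q <- ind_partition(x, c("a1", "a2"))
    s <- partition_similarity(p, q)
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(s == 1, identical(canon_blocks(p), canon_blocks(q)))
  }
  expect_error(partition_similarity(p_chp, ind_partition(two, "a")),
               "universe mismatch")
})

test_that("exact search on the worked example finds its two textbook reducts", {
  rep <- find_reducts(h6, mode = "exact")
  sets <- lapply(rep$reducts, `[[`, "attrs")
  expect_length(sets, 2)
  expect_true(any(vapply(sets, setequal, logical(1), c("Chp", "Vessel"))))
  expect_true(any(vapply(sets, setequal, logical(1), c("ECG", "Vessel"))))
  expect_equal(rep$core, "Vessel")
  expect_equal(vapply(rep$reducts, `[[`, numeric(1), "similarity"),
               c(1, 1))
  expect_equal(rep$counts$total, 6)  # 2^3 - 2 candidates examined
})

test_that("classical pos-preserving mode keeps only region-preserving subsets", {
  rep <- find_reducts(h6, mode = "exact", semantics = "pos")
  sets <- lapply(rep$reducts, `[[`, "attrs")
  # {ECG, Vessel} loses P4 from the positive region, so only one survives
  expect_length(sets, 1)
  expect_setequal(sets[[1]], c("Chp", "Vessel"))
})

test_that("approximate mode converges to exact as the threshold rises", {
  g <- gen_info_system(synth_spec(n_objects = 25, n_informative = 2,
                                  n_redundant = 1, n_noise = 1, seed = 13))
  x <- g$table
  exact <- find_reducts(x, mode = "exact")
  near1 <- find_reducts(x, mode = "approx", threshold = 0.999999)
  expect_equal(lapply(near1$reducts, `[[`, "attrs"),
               lapply(exact$reducts, `[[`, "attrs"))
  # lowering the threshold can only admit more subsets
  loose <- find_reducts(x, mode = "approx", threshold = 0.90)
  expect_gte(length(loose$reducts), length(near1$reducts))
  # accepted scores all clear the bar strictly
  expect_true(all(vapply(loose$reducts, `[[`, numeric(1), "similarity") > 0.90))
})

test_that("in exact mode accepted subsets are superset-closed", {
  for (seed in 1:4) {
    x <- random_is(12, 5, seed = seed + 200)
    rep <- find_reducts(x, mode = "exact")
    accepted <- lapply(rep$reducts, `[[`, "attrs")
    is_accepted <- function(s) {
      any(vapply(accepted, setequal, logical(1), s))
    }
    A <- attribute_names(x)
    for (s in accepted) {
      bigger <- setdiff(A, s)
      for (extra in bigger) {
        sup <- c(s, extra)
        if (length(sup) < length(A)) {
          expect_true(is_accepted(sup),
                      info = paste("superset", paste(sup, collapse = "+"),
                                   "seed", seed))
        }
      }
    }
  }
})

test_that("degenerate attribute counts give empty reports", {
  one <- information_system(cbind(a = c("1", "2")), c("x", "y"))
  rep <- find_reducts(one)
  expect_length(rep$reducts, 0)
  expect_equal(rep$counts$total, 0)
  expect_length(rep$core, 0)  # core of an empty reduct list is empty
  expect_error(find_reducts(random_is(5, 6, seed = 1), max_attrs = 4),
               "size_range")
})

test_that("missing cells are refused by partitioning and reduct search", {
  g <- inject_missing(gen_info_system(synth_spec(n_objects = 10,
                                                 seed = 2))$table,
                      0.3, seed = 1)
  expect_error(find_reducts(g), "missing")
  expect_error(ind_partition(g, attribute_names(g)[1:2]), "missing")
})

test_that("reduct reports serialize with bitmasks and per-size tallies", {
  rep <- find_reducts(h6)
  tab <- reduct_size_table(rep)
  expect_equal(tab$size, 1:2)
  expect_equal(tab$n_subsets, c(3, 3))
  expect_equal(tab$n_reducts, c(0L, 2L))
  f <- withr::local_tempfile(fileext = ".json")
  write_reduct_report(rep, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$subset_counts$total, 6)
  expect_equal(back$core$attrs, "Vessel")
  expect_equal(back$reducts$bitmask[[1]],
               as.integer(reduct_bitmask(rep$reducts[[1]]$attrs, A6)))
})
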
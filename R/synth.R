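#' Specification for a synthetic categorical information system
#'
#' Describes a generated table with known ground truth: the decision is
#' a seeded random function of `n_informative` attributes; each of
#' `n_redundant` attributes is a bijective recoding of one informative
#' attribute (so its indiscernibility partition is identical to its
#' source); `n_noise` attributes are independent. An
#' `inconsistency_rate` fraction of objects gets its label flipped,
#' creating class-mixed indiscernibility blocks (a nonempty boundary
#' region), and `missing_rate` drives [inject_missing()].
#'
#' @param n_objects Number of objects.
#' @param n_informative Attributes the decision truly depends on (>= 1).
#' @param n_redundant Bijective recodings of informative attributes.
#' @param n_noise Independent nuisance attributes.
#' @param cardinality Values per attribute (default 3).
#' @param inconsistency_rate Fraction of objects whose label is flipped
#'   (default 0).
#' @param missing_rate Cell-wise missingness probability for
#'   [inject_missing()] (default 0).
#' @param seed Integer seed.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_objects = 50L, n_informative = 2L,
                       n_redundant = 1L, n_noise = 2L, cardinality = 3L,
                       inconsistency_rate = 0, missing_rate = 0,
                       seed = 1L) {
  stopifnot(n_objects >= 1, n_informative >= 1, n_redundant >= 0,
            n_noise >= 0, cardinality >= 2,
            inconsistency_rate >= 0, inconsistency_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  if (cardinality^n_informative < 2) {
    stop("decision cannot vary: cardinality^n_informative < 2")
  }
  structure(list(n_objects = as.integer(n_objects),
                 n_informative = as.integer(n_informative),
                 n_redundant = as.integer(n_redundant),
                 n_noise = as.integer(n_noise),
                 cardinality = as.integer(cardinality),
                 inconsistency_rate = inconsistency_rate,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate an information system with a planted minimal reduct
#'
#' The informative attributes (`inf1`, `inf2`, ...) jointly determine
#' the class through a seeded random lookup table over their value
#' tuples (guaranteeing no dependence on the noise attributes `noise*`);
#' redundant attributes (`red*`) are bijective recodings of informative
#' ones, hence interchangeable with their sources in any reduct. With
#' `inconsistency_rate = 0` the table is consistent, so the positive
#' region is the whole universe and exact reduct search recovers the
#' planted structure as its minimal-size accepted subsets.
#'
#' @param spec A [synth_spec()].
#' @return List with `table` (an [information_system]), `planted`
#'   (character vector, the informative attribute names), and
#'   `redundancy_map` (named character vector: redundant attribute ->
#'   informative source).
#' @examples
#' g <- gen_info_system(synth_spec(n_objects = 30, seed = 7))
#' g$planted
#' @export
gen_info_system <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    n <- spec$n_objects
    card <- spec$cardinality
    vals <- as.character(seq_len(card))

    inf_names <- paste0("inf", seq_len(spec$n_informative))
    inf <- matrix(sample(vals, n * spec$n_informative, replace = TRUE),
                  n, spec$n_informative, dimnames = list(NULL, inf_names))

    # decision = random lookup table over informative value tuples,
    # redrawn until it actually varies
    keys <- apply(inf, 1L, paste, collapse = "\r")
    all_keys <- unique(keys)
    repeat {
      lut <- stats::setNames(sample(c("0", "1"), length(all_keys),
                                    replace = TRUE), all_keys)
      if (length(unique(lut[keys])) > 1L || length(all_keys) == 1L) break
    }
    decision <- unname(lut[keys])

    red_names <- character(0)
    red <- NULL
    redundancy_map <- character(0)
    if (spec$n_redundant > 0) {
      red_names <- paste0("red", seq_len(spec$n_redundant))
      src <- sample(inf_names, spec$n_redundant, replace = TRUE)
      redundancy_map <- stats::setNames(src, red_names)
      red <- vapply(src, function(s) {
        recode <- stats::setNames(sample(vals), vals)  # random bijection
        unname(recode[inf[, s]])
      }, character(n))
      colnames(red) <- red_names
    }

    noise_names <- character(0)
    noise <- NULL
    if (spec$n_noise > 0) {
      noise_names <- paste0("noise", seq_len(spec$n_noise))
      noise <- matrix(sample(vals, n * spec$n_noise, replace = TRUE),
                      n, spec$n_noise, dimnames = list(NULL, noise_names))
    }

    if (spec$inconsistency_rate > 0) {
      n_flip <- round_half_up(spec$inconsistency_rate * n)
      flip <- sample(n, min(n_flip, n))
      decision[flip] <- ifelse(decision[flip] == "1", "0", "1")
    }

    values <- cbind(inf, red, noise)
    list(table = information_system(values, decision),
         planted = inf_names,
         redundancy_map = redundancy_map)
  })
}

#' Mask condition cells at random
#'
#' Sets each condition cell independently to the missing sentinel with
#' the given probability; the decision column is never masked.
#'
#' @param x An [information_system].
#' @param rate Missingness probability in [0, 1].
#' @param seed Integer seed.
#' @return An [information_system] with injected missing cells.
#' @export
inject_missing <- function(x, rate, seed = 1L) {
  stopifnot(inherits(x, "information_system"), rate >= 0, rate <= 1)
  values <- x$values
  mask <- with_seed(seed, {
    matrix(stats::runif(length(values)) < rate, nrow(values), ncol(values))
  })
  values[mask] <- x$missing
  information_system(values, x$decision, object_ids = x$object_ids,
                     schema = x$schema, missing = x$missing)
}

#' Generate a two-cluster integer-coded classification set
#'
#' Two seeded Gaussian clusters rounded onto the 1-10 integer coding
#' typical of cytology-style clinical features, centred
#' `class_separation` coding units apart along every dimension. Large
#' separation gives a linearly separable problem; zero separation makes
#' the labels unlearnable.
#'
#' @param n Number of samples (>= 4; split evenly between classes).
#' @param d Number of features (>= 1).
#' @param class_separation Distance between cluster centres in coding
#'   units (default 6).
#' @param sd Within-cluster standard deviation (default 1).
#' @param seed Integer seed.
#' @return List with `X` (n x d integer matrix, values 1-10) and `y`
#'   (0/1 labels).
#' @export
gen_classification <- function(n = 100L, d = 2L, class_separation = 6,
                               sd = 1, seed = 1L) {
  stopifnot(n >= 4L, d >= 1L, class_separation >= 0, sd > 0)
  with_seed(seed, {
    n0 <- floor(n / 2)
    n1 <- n - n0
    centre0 <- (11 - class_separation) / 2
    centre1 <- centre0 + class_separation
    X <- rbind(
      matrix(stats::rnorm(n0 * d, centre0, sd), n0, d),
      matrix(stats::rnorm(n1 * d, centre1, sd), n1, d)
    )
    X <- matrix(pmin(pmax(round(X), 1), 10), n, d,
                dimnames = list(NULL, paste0("f", seq_len(d))))
    y <- c(rep(0L, n0), rep(1L, n1))
    perm <- sample(n)
    list(X = X[perm, , drop = FALSE], y = y[perm])
  })
}
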
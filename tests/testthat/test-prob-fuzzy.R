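# independent naive evaluation of activation / consequent / discriminant
brute_activation <- function(rules, X) {
  k <- nrow(rules$centers)
  A <- matrix(NA_real_, nrow(X), k)
  for (i in seq_len(nrow(X))) {
    for (j in seq_len(k)) {
      A[i, j] <- prod(exp(-(as.numeric(X[i, ]) - rules$centers[j, ])^2 /
                            (2 * rules$spreads[j, ]^2)))
    }
  }
  A
}
brute_consequents <- function(rules, X, y) {
  A <- brute_activation(rules, X)
  t(apply(A, 2, function(a) {
    c(normal = sum(a[!y]) / sum(a), abnormal = sum(a[y]) / sum(a))
  }))
}
brute_scores <- function(rules, cons, X) {
  A <- brute_activation(rules, X)
  apply(A * rep(cons[, "abnormal"], each = nrow(A)), 1, sum) / rowSums(A)
}
rand_rules <- function(k, p) {
  list(features = paste0("f", seq_len(p)),
       centers = matrix(rnorm(k * p), k, p,
                        dimnames = list(NULL, paste0("f", seq_len(p)))),
       spreads = matrix(runif(k * p, 0.3, 2), k, p,
                        dimnames = list(NULL, paste0("f", seq_len(p)))))
}

test_that("rule activation is the product of Gaussian memberships", {
  rules <- list(features = c("a", "b"),
                centers = matrix(c(1, 2), 1, 2,
                                 dimnames = list(NULL, c("a", "b"))),
                spreads = matrix(c(0.5, 2), 1, 2,
                                 dimnames = list(NULL, c("a", "b"))))
  # at every center the product peaks at 1
  expect_equal(rule_activation(rules, data.frame(a = 1, b = 2))[1, 1], 1)
  # one spread away on each feature: exp(-1/2)^2
  expect_equal(rule_activation(rules, data.frame(a = 1.5, b = 4))[1, 1],
               exp(-0.5)^2, tolerance = 1e-12)
  expect_equal(exp(-0.5)^2, 0.3679, tolerance = 1e-4)
  # far in the tail the degree stays strictly positive
  expect_gt(rule_activation(rules, data.frame(a = 20, b = -40))[1, 1], 0)
  expect_error(rule_activation(rules, data.frame(a = 1)), "b")
})

test_that("consequents are class-restricted activation shares", {
  # single feature, center 0, spread 1: choose x so activations are
  # 0.9 and 0.1 (abnormal) and 0.5 (normal)
  act_inv <- function(a) sqrt(-2 * log(a))
  X <- data.frame(f = act_inv(c(0.9, 0.1, 0.5)))
  y <- c(TRUE, TRUE, FALSE)
  rules <- list(features = "f",
                centers = matrix(0, 1, 1, dimnames = list(NULL, "f")),
                spreads = matrix(1, 1, 1, dimnames = list(NULL, "f")))
  fitted <- fit_consequents(rules, X, y)
  expect_equal(unname(fitted$consequents[1, "abnormal"]), 1.0 / 1.5,
               tolerance = 1e-12)
  expect_equal(unname(fitted$consequents[1, "normal"]), 0.5 / 1.5,
               tolerance = 1e-12)
  # single-class training set: consequent 1 for that class
  f2 <- fit_consequents(rules, X, c(TRUE, TRUE, TRUE))
  expect_equal(unname(f2$consequents[1, "abnormal"]), 1)
  # scale invariance: halving all spreads rescales activations jointly
  # (the ratio of sums is unchanged only under common scaling of A)
  A <- rule_activation(rules, X)
  expect_equal(sum(2 * A[y, 1]) / sum(2 * A[, 1]), sum(A[y, 1]) / sum(A[, 1]))
})

test_that("scores are activation-weighted consequent averages summing to 1", {
  set.seed(10)
  rules <- rand_rules(2, 1)
  rules$consequents <- cbind(normal = c(0.1, 0.9), abnormal = c(0.9, 0.1))
  rules$priors <- c(normal = 0.5, abnormal = 0.5)
  rb <- structure(rules, class = "fuzzy_rulebase")
  # single rule: scores equal its consequents
  rb1 <- rb
  rb1$centers <- rb$centers[1, , drop = FALSE]
  rb1$spreads <- rb$spreads[1, , drop = FALSE]
  rb1$consequents <- rb$consequents[1, , drop = FALSE]
  s1 <- predict_scores(rb1, data.frame(f1 = 3))
  expect_equal(s1$abnormal, 0.9)
  # hand-weighted average: activations (0.8, 0.2), consequents (0.9, 0.1)
  rb2 <- rb
  rb2$centers[] <- 0
  rb2$spreads[] <- 1
  x <- sqrt(-2 * log(0.8))
  # second rule spread chosen so its activation is 0.2 at the same x
  rb2$spreads[2, 1] <- sqrt(-x^2 / (2 * log(0.2)))
  s2 <- predict_scores(rb2, data.frame(f1 = x))
  expect_equal(s2$abnormal, (0.8 * 0.9 + 0.2 * 0.1) / 1.0, tolerance = 1e-10)
  expect_equal(s2$abnormal, 0.74, tolerance = 1e-10)
  # identical consequents: any activation mix returns them unchanged
  rb3 <- rb
  rb3$consequents <- cbind(normal = c(0.3, 0.3), abnormal = c(0.7, 0.7))
  s3 <- predict_scores(rb3, data.frame(f1 = rnorm(20)))
  expect_equal(s3$abnormal, rep(0.7, 20), tolerance = 1e-12)
  # normalization across random vectors
  set.seed(11)
  s4 <- predict_scores(rb, data.frame(f1 = rnorm(100, sd = 5)))
  expect_true(all(abs(s4$normal + s4$abnormal - 1) < 1e-9))
})

test_that("scoring matches brute-force evaluation of the fuzzy equations", {
  set.seed(42)
  for (rep in 1:20) {
    k <- sample(1:5, 1)
    p <- sample(1:4, 1)
    n <- sample(10:50, 1)
    rules <- rand_rules(k, p)
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, rules$features))
    y <- runif(n) < 0.5
    if (length(unique(y)) < 2) y[1:2] <- c(TRUE, FALSE)
    fitted <- fit_consequents(rules, as.data.frame(X), y)
    expect_equal(unname(fitted$consequents),
                 unname(brute_consequents(rules, X, y)), tolerance = 1e-10)
    rb <- structure(fitted, class = "fuzzy_rulebase")
    got <- predict_scores(rb, as.data.frame(X))$abnormal
    want <- brute_scores(rules, fitted$consequents, X)
    # samples activating no rule (total activation < 1e-12) take the prior
    live <- rowSums(brute_activation(rules, X)) >= 1e-12
    expect_equal(got[live], unname(want)[live], tolerance = 1e-10)
    if (any(!live)) {
      expect_equal(got[!live],
                   rep(unname(fitted$priors[["abnormal"]]), sum(!live)))
    }
    expect_true(all(rowSums(cbind(got, 1 - got)) - 1 < 1e-12))
  }
})

test_that("rule induction recovers well-separated clusters", {
  set.seed(5)
  X <- data.frame(x = c(rnorm(150, -3, 0.3), rnorm(150, 3, 0.3)),
                  y = c(rnorm(150, 0, 0.3), rnorm(150, 5, 0.3)))
  rules <- induce_rules(X, k_rules = 2, seed = 7)
  got <- rules$centers[order(rules$centers[, "x"]), ]
  expect_lt(max(abs(got[1, ] - c(-3, 0))), 0.1)
  expect_lt(max(abs(got[2, ] - c(3, 5))), 0.1)
  # k = 1 degenerates to the overall mean / sd
  r1 <- induce_rules(X, k_rules = 1)
  expect_equal(unname(r1$centers[1, ]), unname(colMeans(X)))
  expect_equal(unname(r1$spreads[1, ]), unname(vapply(X, sd, numeric(1))))
  # duplicate-only samples: spread floored, never zero
  dup <- data.frame(a = rep(2, 10), b = rep(5, 10))
  rd <- induce_rules(dup, k_rules = 3)
  expect_true(all(rd$spreads > 0))
  expect_error(induce_rules(dup, k_rules = 11), "exceeds")
})

test_that("wrapper selection keeps informative features and rejects noise", {
  set.seed(8)
  n <- 600
  informative <- c(rnorm(n / 2, -1.5), rnorm(n / 2, 1.5))
  noise <- rnorm(n)
  X <- data.frame(noise = noise, informative = informative)
  y <- rep(c(FALSE, TRUE), each = n / 2)
  o <- sample(n)
  X <- X[o, ]
  y <- y[o]
  g <- rep(1:60, each = 10)
  sel <- wrapper_select(X, y, g, seed = 2)
  expect_true("informative" %in% sel)
  expect_false("noise" %in% sel)
  # all-noise candidates: the forced first step keeps at most one feature
  Xn <- data.frame(n1 = rnorm(n), n2 = rnorm(n))
  seln <- wrapper_select(Xn, y, g, seed = 2)
  expect_lte(length(seln), 1)
  # epsilon = Inf stops right after the forced first step
  self <- wrapper_select(X, y, g, epsilon = Inf, seed = 2)
  expect_length(self, 1)
  expect_equal(self, "informative")
})

test_that("the classifier separates linearly separable data", {
  set.seed(9)
  n <- 500
  X <- data.frame(x1 = c(rnorm(n / 2, -2), rnorm(n / 2, 2)),
                  x2 = c(rnorm(n / 2, 2), rnorm(n / 2, -2)))
  y <- rep(c(FALSE, TRUE), each = n / 2)
  rb <- fit_fuzzy(X, y, k_rules = 3, seed = 4)
  expect_gt(auroc(y, predict_scores(rb, X)$abnormal), 0.95)
})

test_that("permuted labels yield chance-level discrimination", {
  set.seed(12)
  n <- 1000
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  y <- sample(rep(c(TRUE, FALSE), each = n / 2))
  rb <- fit_fuzzy(X, y, k_rules = 3, seed = 4)
  a <- auroc(y, predict_scores(rb, X)$abnormal)
  expect_gt(a, 0.4)
  expect_lt(a, 0.6)
})

test_that("rule bases serialize to JSON and tidy into one row per rule-feature", {
  set.seed(3)
  X <- data.frame(a = rnorm(30), b = rnorm(30))
  rb <- fit_fuzzy(X, runif(30) < 0.5, k_rules = 2, seed = 1)
  td <- generics::tidy(rb)
  expect_equal(nrow(td), 4)  # 2 rules x 2 features
  expect_true(all(td$spread > 0))
  gl <- generics::glance(rb)
  expect_equal(gl$n_rules, 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_rulebase(rb, path)
  parsed <- jsonlite::read_json(path)
  expect_length(parsed$rules, 2)
  expect_equal(unlist(parsed$features), c("a", "b"))
})
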
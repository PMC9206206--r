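annotated <- function(seqs, ...) annotate_sequences(cohort_from_sequences(seqs, ...))

test_that("the pretest table matches hand-enumerated run-length counts", {
  # A: N N A N -> M = 0,1,2,0 ; B: N N N -> M = 0,1,2
  ann <- annotated(list(A = c("N", "N", "A", "N"), B = c("N", "N", "N")))
  tab <- estimate_pretest_table(ann$labs)
  expect_equal(tab$M, 0:2)
  expect_equal(tab$n_total, c(3L, 2L, 2L))
  expect_equal(tab$probability, c(1, 1, 0.5))
  # all-normal training data: probability 1 at every observed M
  tab2 <- estimate_pretest_table(annotated(list(A = c("N", "N", "N")))$labs)
  expect_true(all(tab2$probability == 1))
  # single admission A A: both events at M = 0, both abnormal
  tab3 <- estimate_pretest_table(annotated(list(A = c("A", "A")))$labs)
  expect_equal(tab3$M, 0L)
  expect_equal(tab3$probability, 0)
  expect_error(
    estimate_pretest_table(tibble::tibble(run_length_M = integer(),
                                          is_normal = logical())),
    "empty")
})

test_that("pretest lookup returns exact entries and clamps unseen run lengths", {
  tab <- estimate_pretest_table(tibble::tibble(
    run_length_M = c(rep(0, 10), rep(1, 20)),
    is_normal = c(rep(TRUE, 9), FALSE, rep(TRUE, 19), FALSE)
  ))
  expect_equal(lookup_pretest(tab, 0), 0.9, tolerance = 1e-12)
  expect_equal(lookup_pretest(tab, 1), 0.95, tolerance = 1e-12)
  # run lengths beyond the training maximum clamp to the last estimate
  expect_equal(lookup_pretest(tab, 7), 0.95, tolerance = 1e-12)
  expect_equal(lookup_pretest(tab, c(0, 1, 7)), c(0.9, 0.95, 0.95))
})

test_that("Freedman-Diaconis widths follow 2*IQR/N^(1/3) with tied-data fallback", {
  expect_equal(fd_bin_width(rep(c(0, 10), each = 500)), 2.0)
  x <- rep(c(0, 7.3), each = 100)
  expect_equal(fd_bin_width(x), 14.6 / 200^(1 / 3), tolerance = 1e-10)
  expect_equal(14.6 / 200^(1 / 3), 2.4966, tolerance = 1e-4)
  # IQR = 0: Sturges-style span/(ceiling(log2 N)+1)
  y <- c(rep(5, 62), 0, 10)
  expect_equal(stats::IQR(y), 0)
  expect_equal(fd_bin_width(y), 10 / (ceiling(log2(64)) + 1))
  expect_equal(fd_bin_width(rep(3, 50)), 0)
  expect_error(fd_bin_width(3), "at least 2")
})

test_that("per-bin conditional entropies are binary entropies in bits", {
  expect_equal(binary_entropy(c(0, 0.5, 1)), c(0, 1, 0))
  expect_equal(binary_entropy(0.8), 0.72193, tolerance = 1e-5)
  # three well-separated value clusters landing in distinct FD bins
  vals <- c(rep(1, 100), rep(50, 100), rep(100, 100))
  labs <- c(rep(TRUE, 100), rep(c(TRUE, FALSE), 50), rep(TRUE, 80),
            rep(FALSE, 20))
  et <- estimate_entropy_table(vals, labs, kind = "continuous")
  expect_equal(entropy_feature(et, 1), 0)                       # pure bin
  expect_equal(entropy_feature(et, 50), 1)                      # 50/50 bin
  expect_equal(entropy_feature(et, 100), binary_entropy(0.8), tolerance = 1e-10)
  # outside the training span or in an empty bin -> marginal entropy
  expect_equal(entropy_feature(et, -100), et$marginal_entropy_bits)
  expect_equal(entropy_feature(et, 1e6), et$marginal_entropy_bits)
  expect_equal(entropy_feature(et, 75), et$marginal_entropy_bits)
})

test_that("categorical encoding maps categories to conditional entropy", {
  cats <- c(rep("a", 4), rep("b", 4), rep("c", 4))
  labs <- c(rep(TRUE, 4), c(TRUE, TRUE, FALSE, FALSE), c(TRUE, TRUE, TRUE, FALSE))
  enc <- encode_categorical(cats, labs)
  expect_equal(entropy_feature(enc, "a"), 0)
  expect_equal(entropy_feature(enc, "b"), 1)
  expect_equal(entropy_feature(enc, "c"), binary_entropy(0.75), tolerance = 1e-10)
  expect_equal(binary_entropy(0.75), 0.8113, tolerance = 1e-4)
  # unseen category -> marginal entropy of the pooled labels
  expect_equal(entropy_feature(enc, "zzz"), binary_entropy(mean(labs)))
  expect_equal(entropy_feature(enc, c("a", "zzz")),
               c(0, binary_entropy(mean(labs))))
  # marginal p_normal = 0.9 -> 0.469 bits for unseen values
  enc2 <- encode_categorical(rep("x", 10), c(rep(TRUE, 9), FALSE))
  expect_equal(entropy_feature(enc2, "new"), 0.469, tolerance = 1e-3)
  expect_error(encode_categorical(character(0), logical(0)), "empty")
})

test_that("feature matrices have 10, 11 and 21 columns by approach", {
  ann <- small_sim_cohort(n = 25, seed = 31)
  al <- align_cohort(ann)
  mk <- fit_feature_maker(ann, al, "potassium")
  meta <- c("admission_id", "time_h", "is_normal")
  f1 <- assemble_features(mk, ann, al, "1")
  f2 <- assemble_features(mk, ann, al, "2")
  fp <- assemble_features(mk, ann, al, "1+pretest")
  fe <- assemble_features(mk, ann, al, "1+entropy")
  expect_equal(ncol(f1) - length(meta), 10)
  expect_equal(ncol(f2) - length(meta), 21)
  expect_equal(ncol(fp) - length(meta), 11)
  expect_equal(ncol(fe) - length(meta), 20)
  expect_false(anyNA(f2))
  # entropy features in [0, 1] bits; pretest in [0, 1]
  ent_cols <- grep("^entropy_", names(f2), value = TRUE)
  expect_length(ent_cols, 10)
  expect_true(all(as.matrix(f2[ent_cols]) >= 0 & as.matrix(f2[ent_cols]) <= 1))
  expect_true(all(f2$pretest_probability >= 0 & f2$pretest_probability <= 1))
  # rows are exactly the non-first-of-day events
  expect_equal(nrow(f1), sum(!ann$labs$is_first_of_day))
})

test_that("a day with a single result contributes features but no target row", {
  ann <- annotated(list(A = c("N", "N", "N")), times = list(A = c(1, 5, 30)))
  al <- align_cohort(ann)
  mk <- fit_feature_maker(ann, al, "potassium")
  f1 <- assemble_features(mk, ann, al, "1")
  # day 0 has events at 1 h (first) and 5 h (target); day 1 only its first
  expect_equal(nrow(f1), 1)
  expect_equal(f1$time_h, 5)
  expect_equal(f1$first_lab_of_day_value, normal_value)
})

test_that("held-out feature values use training distributions only", {
  ann <- small_sim_cohort(n = 40, seed = 55)
  al <- align_cohort(ann)
  ids <- unique(ann$admissions$admission_id)
  train_ids <- ids[1:30]
  test_ids <- setdiff(ids, train_ids)
  sub <- function(coh, ids) {
    icupretest:::new_icu_cohort(
      dplyr::filter(coh$admissions, admission_id %in% ids),
      dplyr::filter(coh$vitals, admission_id %in% ids),
      dplyr::filter(coh$labs, admission_id %in% ids))
  }
  mk <- fit_feature_maker(sub(ann, train_ids),
                          dplyr::filter(al, admission_id %in% train_ids),
                          "potassium")
  te <- sub(ann, test_ids)
  fe_before <- assemble_features(mk, te, al, "2")
  # permute held-out labels: fitted tables and held-out features both
  # depend only on training admissions and raw held-out values
  te2 <- te
  te2$labs$is_normal <- sample(te2$labs$is_normal)
  mk2 <- fit_feature_maker(sub(ann, train_ids),
                           dplyr::filter(al, admission_id %in% train_ids),
                           "potassium")
  expect_identical(mk$pretest, mk2$pretest)
  expect_identical(mk$entropy_tables, mk2$entropy_tables)
  fe_after <- assemble_features(mk2, te2, al, "2")
  feats <- setdiff(names(fe_before), c("admission_id", "time_h", "is_normal"))
  # pretest depends on run_length_M (a label function) which we did not
  # recompute; all other features must be unchanged under label permutation
  expect_identical(fe_before[setdiff(feats, "pretest_probability")],
                   fe_after[setdiff(feats, "pretest_probability")])
})

test_that("per-bin entropy matches the marginal when labels are independent", {
  set.seed(77)
  n <- 10000
  vals <- rnorm(n)
  labs <- runif(n) < 0.7  # independent of vals
  et <- estimate_entropy_table(vals, labs, kind = "continuous")
  occupied <- et$bins[et$bins$n_obs > 0, ]
  mean_bin_h <- sum(occupied$entropy_bits * occupied$n_obs) / sum(occupied$n_obs)
  expect_lt(abs(mean_bin_h - et$marginal_entropy_bits), 0.02)
})

test_that("pretest estimation is deterministic given the training fold", {
  ann <- small_sim_cohort(n = 20, seed = 3)
  t1 <- estimate_pretest_table(ann$labs)
  t2 <- estimate_pretest_table(ann$labs[sample(nrow(ann$labs)), ])
  expect_equal(t1, t2)
})
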
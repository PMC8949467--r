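# Small labelled feature table with controllable class separation, built
# directly in feature space so cascade mechanics can be tested quickly.
toy_table <- function(n_per_class = 12, sep = 4, seed = 1, n_feat = 6) {
  set.seed(seed)
  shift <- c(waste = 0, not_ragged = 1, ragged = 2) * sep
  rows <- purrr::imap_dfr(shift, function(s, cls) {
    x <- matrix(rnorm(n_per_class * n_feat, mean = s), n_per_class)
    colnames(x) <- paste0("color.h.f", seq_len(n_feat))
    dplyr::mutate(tibble::as_tibble(x),
                  tile_id = paste0(cls, seq_len(n_per_class)),
                  label = cls, .before = 1)
  })
  rows[sample(nrow(rows)), ]
}

test_that("stratified splits have the right sizes and are reproducible", {
  tab <- toy_table(n_per_class = 25)  # 75 rows
  sp <- split_train_test(tab, train_frac = 0.8, seed = 7)
  expect_length(sp$train, 60)
  expect_length(sp$test, 15)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_len(75))
  # per-class balance preserved exactly for divisible counts
  expect_equal(as.integer(table(tab$label[sp$train])), rep(20L, 3))
  expect_identical(sp, split_train_test(tab, train_frac = 0.8, seed = 7))
  expect_false(identical(sp, split_train_test(tab, train_frac = 0.8, seed = 8)))

  tiny <- tab[c(1, which(tab$label != tab$label[1])), ]
  expect_error(split_train_test(tiny), "at least 2 rows")
})

test_that("a 100-row 50/50 table splits 80/20 within one row per stratum", {
  tab <- toy_table(n_per_class = 50)[1:100, ] |>
    dplyr::mutate(label = rep(c("pos", "neg"), 50))
  sp <- split_train_test(tab, train_frac = 0.8, seed = 3)
  expect_length(sp$train, 80)
  expect_lte(abs(sum(tab$label[sp$train] == "pos") - 40), 1)
})

test_that("degenerate single-point search reduces to plain cross-validation", {
  tab <- toy_table(sep = 3, seed = 2)
  tab2 <- dplyr::filter(tab, label != "waste")
  spec <- learner_spec("random_forest", n_draws = 1,
                       space = list(num_trees = c(200, 200), mtry = c(3, 3),
                                    min_node = c(1, 1)))
  tuned <- tune_learner(tab2, spec, positive = "ragged", k = 5, seed = 9)
  expect_equal(nrow(tuned$cv_metrics), 1)
  expect_equal(tuned$best_draw, 1L)
  expect_equal(tuned$params$num_trees, 200L)
  expect_equal(tuned$params$mtry, 3L)
  # wide separation: near-perfect CV F1
  expect_gte(tuned$cv_metrics$f1, 0.95)
})

test_that("tuned draws always lie inside the declared search space", {
  tab2 <- dplyr::filter(toy_table(sep = 2, seed = 5), label != "waste")
  for (alg in c("random_forest", "gradient_boosting", "svm_rbf")) {
    spec <- learner_spec(alg, n_draws = 3)
    tuned <- tune_learner(tab2, spec, positive = "ragged", k = 4, seed = 11)
    for (nm in names(spec$space)) {
      rng <- spec$space[[nm]]
      if (nm == "mtry") rng[2] <- min(rng[2], 6)
      expect_gte(tuned$params[[nm]], rng[1])
      expect_lte(tuned$params[[nm]], rng[2])
    }
  }
})

test_that("permuted labels drive CV accuracy to the majority-class rate", {
  tab2 <- dplyr::filter(toy_table(n_per_class = 18, sep = 5, seed = 6),
                        label != "ragged")
  set.seed(13)
  tab2$label <- sample(tab2$label)
  spec <- learner_spec("random_forest", n_draws = 2)
  tuned <- tune_learner(tab2, spec, positive = "not_ragged", k = 4, seed = 15)
  expect_lte(tuned$cv_metrics$acc[tuned$best_draw], 0.75)  # majority = 0.5
})

test_that("the trained cascade has two stages, three candidates each", {
  tab <- toy_table(n_per_class = 15, sep = 4, seed = 21)
  cas <- train_cascade(tab, learners = default_learners(n_draws = 2),
                       k = 4, seed = 33)
  expect_s3_class(cas, "rrf_cascade")
  expect_length(cas$stage1$candidates, 3)
  expect_length(cas$stage2$candidates, 3)
  expect_equal(cas$stage1$positive, "tissue")
  expect_equal(cas$stage2$positive, "ragged")
  # selected learner maximizes test AUC at its stage
  for (st in list(cas$stage1, cas$stage2)) {
    aucs <- purrr::map_dbl(st$candidates, "test_auc")
    expect_equal(st$selected, which.max(aucs))
  }
  # widely separated toy classes: both stages near-perfect
  expect_gte(cas$stage1$candidates[[cas$stage1$selected]]$test_auc, 0.95)
  expect_gte(cas$stage2$candidates[[cas$stage2$selected]]$test_auc, 0.95)

  td <- tidy(cas)
  expect_equal(nrow(td), 6)
  expect_equal(sum(td$selected), 2)
  gl <- glance(cas)
  expect_equal(gl$n_train + gl$n_test, nrow(tab))

  expect_error(train_cascade(dplyr::filter(tab, label != "waste")),
               "missing class")
})

test_that("cascade predictions obey the gating and threshold rules", {
  tab <- toy_table(n_per_class = 15, sep = 4, seed = 21)
  cas <- train_cascade(tab, learners = list(learner_spec("random_forest",
                                                         n_draws = 2)),
                       k = 4, seed = 33)
  pr <- predict_cascade(cas, tab)
  expect_named(pr, c("tile_id", "p_tissue", "p_ragged", "label"))
  expect_equal(nrow(pr), nrow(tab))
  # exactly one final label each; stage-2 probability iff stage 1 said tissue
  expect_true(all(pr$label %in% c("waste", "not_ragged", "ragged")))
  expect_equal(is.na(pr$p_ragged), pr$p_tissue < 0.5)
  expect_true(all(pr$label[pr$p_tissue < 0.5] == "waste"))
  keep <- pr$p_tissue >= 0.5
  expect_equal(pr$label[keep] == "ragged", pr$p_ragged[keep] >= 0.5)

  # schema mismatch refused
  bad <- dplyr::rename(tab, color.h.zzz = "color.h.f1")
  expect_error(predict_cascade(cas, bad), "schema")
})

test_that("training is reproducible for a fixed seed", {
  tab <- toy_table(n_per_class = 12, sep = 3, seed = 8)
  c1 <- train_cascade(tab, learners = default_learners(n_draws = 2),
                      k = 3, seed = 55)
  c2 <- train_cascade(tab, learners = default_learners(n_draws = 2),
                      k = 3, seed = 55)
  expect_identical(c1$split, c2$split)
  expect_equal(c1$stage1$candidates[[1]]$tuned$params,
               c2$stage1$candidates[[1]]$tuned$params)
  expect_identical(predict_cascade(c1, tab), predict_cascade(c2, tab))
  expect_equal(tidy(c1), tidy(c2))
})
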
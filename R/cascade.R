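#' Two-stage cascade classification
#'
#' Tiles are classified in two binary steps: stage 1 separates analyzable
#' muscle tissue from waste (artifacts, connective tissue) on all tiles;
#' stage 2 separates ragged from not-ragged fibers among the tissue tiles
#' only. At each stage three learners — random forest, gradient boosting
#' and an RBF-kernel SVM — are tuned by random search under stratified
#' 10-fold cross-validation (best mean F1 wins a draw), retrained on the
#' full 80% training split, and the learner with the highest test-set AUC
#' is selected for the cascade.
#'
#' @name cascade
NULL

#' Declare a learner and its random-search space
#'
#' Search spaces (defaults): random forest — trees 100-1000, features per
#' split 1-134, min node size 1-10; gradient boosting — trees 50-500,
#' learning rate 0.01-0.3 (log-uniform), depth 1-8; RBF SVM — cost
#' 2^-5..2^15 and kernel width 2^-15..2^3 (both log-uniform).
#'
#' @param algorithm One of `"random_forest"`, `"gradient_boosting"`,
#'   `"svm_rbf"`.
#' @param n_draws Number of random-search draws (default 50).
#' @param space Optional named list overriding entries of the default space;
#'   each entry is `c(lower, upper)`.
#' @return An `rrf_learner_spec` list.
#' @export
learner_spec <- function(algorithm = c("random_forest", "gradient_boosting",
                                       "svm_rbf"),
                         n_draws = 50L, space = list()) {
  algorithm <- match.arg(algorithm)
  default_space <- switch(algorithm,
    random_forest = list(num_trees = c(100, 1000), mtry = c(1, 134),
                         min_node = c(1, 10)),
    gradient_boosting = list(nrounds = c(50, 500), eta = c(0.01, 0.3),
                             max_depth = c(1, 8)),
    svm_rbf = list(cost = 2^c(-5, 15), gamma = 2^c(-15, 3))
  )
  structure(list(algorithm = algorithm, n_draws = as.integer(n_draws),
                 space = modifyList(default_space, space)),
            class = "rrf_learner_spec")
}

#' @rdname learner_spec
#' @export
default_learners <- function(n_draws = 50L) {
  purrr::map(c("random_forest", "gradient_boosting", "svm_rbf"),
             learner_spec, n_draws = n_draws)
}

# Parameters sampled log-uniformly rather than uniformly.
.log_uniform_params <- c("eta", "cost", "gamma")
.integer_params <- c("num_trees", "mtry", "min_node", "nrounds", "max_depth")

draw_params <- function(spec, n_features) {
  purrr::imap(spec$space, function(rng, nm) {
    if (nm == "mtry") rng[2] <- min(rng[2], n_features)
    v <- if (nm %in% .log_uniform_params) {
      exp(runif(1, log(rng[1]), log(rng[2])))
    } else {
      runif(1, rng[1], rng[2])
    }
    if (nm %in% .integer_params) as.integer(round(v)) else v
  })
}

# Fits one binary learner on a standardized feature matrix. y is a factor
# with levels c(negative, positive). The SVM is fitted without libsvm's
# internal probability machinery (which is not reproducible across runs);
# probabilities come from a Platt-type logistic calibration of the decision
# values fitted on the training data.
fit_binary <- function(algorithm, params, x, y, fit_seed) {
  positive <- levels(y)[2]
  fit <- switch(algorithm,
    random_forest = ranger::ranger(
      x = x, y = y, probability = TRUE,
      num.trees = params$num_trees,
      mtry = min(params$mtry, ncol(x)),
      min.node.size = params$min_node,
      num.threads = 1L, seed = fit_seed),
    gradient_boosting = xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = params$eta,
                    max_depth = params$max_depth, nthread = 1L,
                    seed = fit_seed),
      data = xgboost::xgb.DMatrix(x, label = as.numeric(y == positive),
                                  nthread = 1L),
      nrounds = params$nrounds, verbose = 0),
    svm_rbf = {
      sv <- e1071::svm(x = x, y = y, kernel = "radial",
                       cost = params$cost, gamma = params$gamma,
                       scale = FALSE)
      dv <- as.numeric(attr(predict(sv, x, decision.values = TRUE),
                            "decision.values"))
      platt <- suppressWarnings(
        stats::glm((y == positive) ~ dv, family = stats::binomial()))
      list(svm = sv, platt = platt)
    },
    abort(sprintf("Unknown algorithm '%s'.", algorithm))
  )
  structure(list(algorithm = algorithm, fit = fit, params = params,
                 levels = levels(y), positive = positive),
            class = "rrf_binary_model")
}

# Probability of the positive class for each row of x.
predict_binary <- function(model, x) {
  switch(model$algorithm,
    random_forest = {
      p <- predict(model$fit, data = x, num.threads = 1L)$predictions
      as.numeric(p[, model$positive])
    },
    gradient_boosting = as.numeric(
      predict(model$fit, newdata = xgboost::xgb.DMatrix(x, nthread = 1L))),
    svm_rbf = {
      dv <- as.numeric(attr(predict(model$fit$svm, x, decision.values = TRUE),
                            "decision.values"))
      as.numeric(predict(model$fit$platt, newdata = data.frame(dv = dv),
                         type = "response"))
    }
  )
}

#' Stratified train/test split
#'
#' Seeded, stratified by label: within each class, `round(train_frac * n)`
#' rows go to the training set, so an 80/20 split of 100 rows gives 80/20.
#'
#' @param table A labelled feature table.
#' @param train_frac Training fraction in (0, 1), default 0.8.
#' @param seed Integer seed.
#' @param stratify Stratify by the `label` column (default TRUE).
#' @return A list with integer row indices `train` and `test`.
#' @export
split_train_test <- function(table, train_frac = 0.8, seed = 1L,
                             stratify = TRUE) {
  stopifnot(train_frac > 0, train_frac < 1)
  labels <- if (stratify) table$label else rep("all", nrow(table))
  if (stratify && any(table(labels) < 2L)) {
    abort("Every class needs at least 2 rows for a stratified split.")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  train <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_tr <- round(train_frac * length(idx))
    n_tr <- max(1L, min(length(idx) - 1L, n_tr))
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(nrow(table)), train))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Stratified fold assignment; redraws (bounded) if any fold's training
# portion would miss a class, which can only happen for very rare classes.
make_cv_folds <- function(labels, k, max_retry = 20L) {
  for (attempt in seq_len(max_retry)) {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(sample(k), length(idx))
    }
    ok <- all(vapply(seq_len(k), function(f) {
      length(unique(labels[fold != f])) == length(unique(labels))
    }, logical(1)))
    if (ok) return(fold)
    warn(sprintf("Fold draw %d left a class out of a training portion; redrawing.",
                 attempt))
  }
  abort("Could not draw cross-validation folds with all classes in every training portion.")
}

#' Tune one learner by random search under k-fold cross-validation
#'
#' Each random-search draw is scored by its mean validation metrics over the
#' k folds; z-score normalization is re-fitted inside each fold's training
#' portion so validation folds never leak into it. The draw with the best
#' mean F1 wins (ties: higher mean accuracy, then draw order). Predicted
#' probabilities at or above 0.5 count as the positive class.
#'
#' @param table Feature table restricted to the training split, with a
#'   two-class `label` column.
#' @param spec An [learner_spec()].
#' @param positive Name of the positive class.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for folds, draws and learner internals.
#' @return A list: `spec` (input), `params` (winning draw), `cv_metrics`
#'   (tibble of per-draw mean metrics), `best_draw`.
#' @export
tune_learner <- function(table, spec, positive, k = 10L, seed = 1L) {
  stopifnot(inherits(spec, "rrf_learner_spec"))
  labels <- table$label
  classes <- unique(labels)
  if (length(classes) != 2L || !positive %in% classes) {
    abort("tune_learner() needs exactly two classes including the positive one.")
  }
  negative <- setdiff(classes, positive)
  feats <- feature_columns(table)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- make_cv_folds(labels, k)
  draws <- purrr::map(seq_len(spec$n_draws), ~draw_params(spec, length(feats)))
  fit_seeds <- sample.int(.Machine$integer.max, spec$n_draws * k)

  y_all <- factor(labels, levels = c(negative, positive))
  # fold-internal normalization: each fold's record is fitted on its own
  # training rows only, then applied to the whole table; identical across
  # draws, so standardized matrices are prepared once per fold
  fold_data <- purrr::map(seq_len(k), function(f) {
    tr <- which(fold != f)
    std <- zscore_apply(table, zscore_fit(table, tr))
    list(tr = tr, va = which(fold == f), x = as.matrix(std[, feats]))
  })
  cv <- purrr::imap_dfr(draws, function(params, d) {
    fold_metrics <- purrr::map_dfr(seq_len(k), function(f) {
      fd <- fold_data[[f]]
      model <- fit_binary(spec$algorithm, params,
                          fd$x[fd$tr, , drop = FALSE],
                          y_all[fd$tr], fit_seeds[(d - 1L) * k + f])
      p <- predict_binary(model, fd$x[fd$va, , drop = FALSE])
      pred <- ifelse(p >= 0.5, positive, negative)
      classification_metrics(confusion_counts(labels[fd$va], pred, positive))
    })
    dplyr::summarise(fold_metrics, dplyr::across(dplyr::everything(), mean)) |>
      dplyr::mutate(draw = d, .before = 1)
  })
  best <- cv |>
    dplyr::arrange(dplyr::desc(.data$f1), dplyr::desc(.data$acc), .data$draw) |>
    dplyr::slice(1)
  list(spec = spec, params = draws[[best$draw]], cv_metrics = cv,
       best_draw = best$draw)
}

# Tunes all learners for one stage, refits each winner on the whole training
# split, evaluates on the test split by ROC/AUC, and keeps the best.
train_stage <- function(table, train_idx, test_idx, positive, learners,
                        k, seed) {
  labels <- table$label
  negative <- setdiff(unique(labels), positive)
  feats <- feature_columns(table)
  norm <- zscore_fit(table, train_idx)
  std <- zscore_apply(table, norm)
  x <- as.matrix(std[, feats])
  y <- factor(labels, levels = c(negative, positive))

  candidates <- purrr::imap(learners, function(spec, i) {
    tuned <- tune_learner(table[train_idx, ], spec, positive,
                          k = k, seed = seed + i)
    model <- fit_binary(spec$algorithm, tuned$params,
                        x[train_idx, , drop = FALSE], y[train_idx],
                        fit_seed = seed + 1000L * i)
    p_test <- predict_binary(model, x[test_idx, , drop = FALSE])
    roc <- roc_curve(p_test, labels[test_idx], positive)
    pred <- ifelse(p_test >= 0.5, positive, negative)
    cm <- confusion_counts(labels[test_idx], pred, positive)
    list(algorithm = spec$algorithm, tuned = tuned, model = model,
         roc = roc, test_auc = auc(roc), confusion = cm,
         test_metrics = classification_metrics(cm),
         cv_f1 = tuned$cv_metrics$f1[tuned$best_draw],
         cv_acc = tuned$cv_metrics$acc[tuned$best_draw])
  })
  aucs <- purrr::map_dbl(candidates, "test_auc")
  sel <- which.max(aucs)
  list(positive = positive, negative = negative, norm = norm,
       candidates = candidates, selected = sel,
       model = candidates[[sel]]$model,
       algorithm = candidates[[sel]]$algorithm)
}

#' Train the two-stage cascade
#'
#' Performs one stratified 80/20 split of the full three-class table (shared
#' by both stages), then trains stage 1 (waste vs. tissue, on all rows, with
#' ragged and not-ragged collapsed to tissue) and stage 2 (ragged vs.
#' not-ragged, on the tissue rows only). At each stage all learners are
#' tuned, refitted and compared by test-set AUC.
#'
#' @param table Feature table whose `label` column contains all of `ragged`,
#'   `not_ragged`, `waste`.
#' @param learners List of [learner_spec()]s (default: all three at 50
#'   draws).
#' @param train_frac Training fraction (default 0.8).
#' @param k Cross-validation folds (default 10).
#' @param seed Integer seed governing the split, folds, search draws and
#'   learner internals.
#' @return An `rrf_cascade` object; see [predict_cascade()], [tidy()],
#'   [glance()].
#' @export
train_cascade <- function(table, learners = default_learners(),
                          train_frac = 0.8, k = 10L, seed = 1L) {
  missing_cls <- setdiff(.rrf_labels, unique(table$label))
  if (length(missing_cls) > 0) {
    abort(paste0("Feature table is missing class(es): ",
                 paste(missing_cls, collapse = ", ")))
  }
  split <- split_train_test(table, train_frac = train_frac, seed = seed)

  # stage 1: waste vs tissue on every tile
  t1 <- table
  t1$label <- ifelse(table$label == "waste", "waste", "tissue")
  stage1 <- train_stage(t1, split$train, split$test, positive = "tissue",
                        learners = learners, k = k, seed = seed + 101L)

  # stage 2: ragged vs not_ragged on tissue tiles only
  tissue <- which(table$label != "waste")
  t2 <- table[tissue, ]
  tr2 <- which(tissue %in% split$train)
  te2 <- which(tissue %in% split$test)
  stage2 <- train_stage(t2, tr2, te2, positive = "ragged",
                        learners = learners, k = k, seed = seed + 202L)

  structure(list(stage1 = stage1, stage2 = stage2, split = split,
                 schema = feature_columns(table), seed = seed,
                 n_train = length(split$train), n_test = length(split$test)),
            class = "rrf_cascade")
}

#' @export
print.rrf_cascade <- function(x, ...) {
  cat("<rrf_cascade> two-stage tile classifier\n")
  cat(sprintf("  stage 1 (waste/tissue):      %s, test AUC %.3f\n",
              x$stage1$algorithm,
              x$stage1$candidates[[x$stage1$selected]]$test_auc))
  cat(sprintf("  stage 2 (ragged/not_ragged): %s, test AUC %.3f\n",
              x$stage2$algorithm,
              x$stage2$candidates[[x$stage2$selected]]$test_auc))
  cat(sprintf("  trained on %d tiles, tested on %d (seed %d)\n",
              x$n_train, x$n_test, x$seed))
  invisible(x)
}

#' Predict tile classes with a trained cascade
#'
#' Stage 1 assigns each tile a tissue probability; below 0.5 the tile is
#' `waste` and stage 2 is skipped (its probability reported as `NA`).
#' Otherwise stage 2's ragged probability decides with the same rule
#' (probability at or above 0.5 maps to the positive class).
#'
#' @param cascade An `rrf_cascade`.
#' @param table A feature table with the same 134 feature columns the
#'   cascade was trained on.
#' @return A tibble with columns `tile_id`, `p_tissue`, `p_ragged`, `label`.
#' @export
predict_cascade <- function(cascade, table) {
  stopifnot(inherits(cascade, "rrf_cascade"))
  feats <- feature_columns(table)
  if (!identical(sort(feats), sort(cascade$schema))) {
    off <- c(setdiff(cascade$schema, feats), setdiff(feats, cascade$schema))
    abort(paste0("Feature schema does not match the trained cascade: ",
                 paste(head(off, 10), collapse = ", ")))
  }
  x1 <- as.matrix(zscore_apply(table, cascade$stage1$norm)[, cascade$schema])
  p_tissue <- predict_binary(cascade$stage1$model, x1)
  p_ragged <- rep(NA_real_, nrow(table))
  tissue <- p_tissue >= 0.5
  if (any(tissue)) {
    x2 <- as.matrix(zscore_apply(table, cascade$stage2$norm)[, cascade$schema])
    p_ragged[tissue] <- predict_binary(cascade$stage2$model,
                                       x2[tissue, , drop = FALSE])
  }
  label <- ifelse(!tissue, "waste",
                  ifelse(p_ragged >= 0.5, "ragged", "not_ragged"))
  tibble(tile_id = table$tile_id %||% seq_len(nrow(table)),
         p_tissue = p_tissue, p_ragged = p_ragged, label = label)
}

#' Per-candidate summary of a trained cascade
#'
#' @param x An `rrf_cascade`.
#' @param ... Unused.
#' @return A tibble with one row per (stage, learner): cross-validated F1
#'   and accuracy of the winning draw, test AUC, test accuracy, and whether
#'   the learner was selected for the cascade.
#' @export
tidy.rrf_cascade <- function(x, ...) {
  purrr::imap_dfr(list(waste_tissue = x$stage1, ragged_not_ragged = x$stage2),
    function(st, nm) {
      purrr::imap_dfr(st$candidates, function(cand, i) {
        tibble(stage = nm, algorithm = cand$algorithm,
               cv_f1 = cand$cv_f1, cv_acc = cand$cv_acc,
               test_auc = cand$test_auc,
               test_acc = cand$test_metrics$acc,
               selected = i == st$selected)
      })
    })
}

#' One-row summary of a trained cascade
#'
#' @param x An `rrf_cascade`.
#' @param ... Unused.
#' @export
glance.rrf_cascade <- function(x, ...) {
  s1 <- x$stage1$candidates[[x$stage1$selected]]
  s2 <- x$stage2$candidates[[x$stage2$selected]]
  tibble(stage1_algorithm = x$stage1$algorithm,
         stage1_test_auc = s1$test_auc,
         stage2_algorithm = x$stage2$algorithm,
         stage2_test_auc = s2$test_auc,
         n_train = x$n_train, n_test = x$n_test, seed = x$seed)
}

#' @rdname tidy.rrf_cascade
#' @param object An `rrf_cascade`.
#' @export
autoplot.rrf_cascade <- function(object, ...) {
  pts <- purrr::imap_dfr(
    list(`stage 1: waste vs tissue` = object$stage1,
         `stage 2: ragged vs not ragged` = object$stage2),
    function(st, nm) {
      purrr::map_dfr(st$candidates, function(cand) {
        as_tibble(cand$roc) |>
          dplyr::mutate(stage = nm,
                        model = sprintf("%s (AUC %.2f)", cand$algorithm,
                                        cand$test_auc))
      })
    })
  ggplot2::ggplot(pts, ggplot2::aes(.data$fpr, .data$tpr, colour = .data$model)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::facet_wrap(~stage) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = NULL, title = "Test-set ROC curves by stage") +
    ggplot2::theme_minimal()
}
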
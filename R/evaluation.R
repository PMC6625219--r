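# Evaluation suite: confusion matrices, the clinical metric panel
# (accuracy, sensitivity, specificity, PPV, NPV, positive likelihood
# ratio, Cohen's kappa), reconstruction of a confusion matrix from
# published summary statistics, and cross-validated model evaluation.
#
# Multiclass convention: overall accuracy and kappa are computed on the
# full K x K table; sensitivity/specificity/PPV/NPV/PLR answer the
# clinical pain-vs-no-pain question, so codes {1, 2} are pooled as the
# positive class ("collapse" convention). Macro one-vs-rest averages are
# available via metrics(..., multiclass = "macro").

#' Confusion matrix from label vectors
#'
#' @param true,predicted Integer state codes in `{0, 1, 2}` (equal
#'   length).
#' @param positive The positive class for binary summaries; default: any
#'   nonzero code (pain).
#' @return A `confusion` object: the `K x K` table (rows = truth,
#'   columns = prediction) over the union of observed codes, with the
#'   positive-class definition attached.
#' @export
confusion <- function(true, predicted, positive = NULL) {
  assert_that(length(true) == length(predicted),
              "label vectors must have equal length")
  assert_that(all(c(true, predicted) %in% 0:2),
              "state codes must be in {0, 1, 2}")
  lev <- sort(unique(c(true, predicted)))
  tab <- table(factor(true, levels = lev), factor(predicted, levels = lev))
  m <- matrix(as.numeric(tab), nrow = length(lev),
              dimnames = list(true = as.character(lev),
                              predicted = as.character(lev)))
  new_confusion(m, positive %||% lev[lev != 0])
}

new_confusion <- function(m, positive) {
  structure(list(table = m, positive = as.character(positive)),
            class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  cat("<confusion> (rows = truth, cols = predicted; positive:",
      paste(x$positive, collapse = ","), ")\n")
  print(x$table)
  invisible(x)
}

# Collapse a K x K table to binary counts against the positive classes.
binary_counts <- function(cm) {
  m <- cm$table
  lev <- rownames(m)
  pos <- lev %in% cm$positive
  list(tp = sum(m[pos, pos]), fn = sum(m[pos, !pos]),
       fp = sum(m[!pos, pos]), tn = sum(m[!pos, !pos]))
}

kappa_from_table <- function(m) {
  n <- sum(m)
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (pe == 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Classification metric panel
#'
#' Computes, from a confusion matrix: overall accuracy; sensitivity
#' `TP/(TP+FN)`; specificity `TN/(TN+FP)`; positive likelihood ratio
#' `sens/(1-spec)`; PPV `TP/(TP+FP)`; NPV `TN/(TN+FN)`; and Cohen's kappa
#' `(p_o - p_e)/(1 - p_e)` with the chance agreement `p_e` from the
#' marginals. Real-valued (reconstructed) counts are accepted. Zero
#' denominators are flagged in `$flags` rather than silently dropped;
#' PLR at specificity 1 is reported as `Inf` with flag `"plr_infinite"`.
#'
#' @param cm A [confusion()] or [reconstruct_from_summary()] result.
#' @param multiclass `"collapse"` (default; pool pain codes for the
#'   binary panel) or `"macro"` (one-vs-rest averages of
#'   sens/spec/PPV/NPV).
#' @return A `metric_report` list: `accuracy`, `sensitivity`,
#'   `specificity`, `plr`, `ppv`, `npv`, `kappa`, `n`, `flags`.
#' @export
metrics <- function(cm, multiclass = c("collapse", "macro")) {
  multiclass <- match.arg(multiclass)
  m <- cm$table
  n <- sum(m)
  assert_that(n > 0, "empty confusion matrix")
  flags <- character()
  acc <- sum(diag(m)) / n
  kap <- kappa_from_table(m)
  if (is.na(kap)) flags <- c(flags, "kappa_undefined")

  one_vs <- function(b) {
    rate <- function(num, den, what) {
      if (den == 0) {
        flags <<- c(flags, paste0(what, "_undefined"))
        return(NaN)
      }
      num / den
    }
    sens <- rate(b$tp, b$tp + b$fn, "sensitivity")
    spec <- rate(b$tn, b$tn + b$fp, "specificity")
    plr <- if (!is.nan(spec) && spec == 1) {
      flags <<- c(flags, "plr_infinite")
      Inf
    } else sens / (1 - spec)
    list(sensitivity = sens, specificity = spec, plr = plr,
         ppv = rate(b$tp, b$tp + b$fp, "ppv"),
         npv = rate(b$tn, b$tn + b$fn, "npv"))
  }

  if (nrow(m) <= 2L || multiclass == "collapse") {
    panel <- one_vs(binary_counts(cm))
  } else {
    lev <- rownames(m)
    per <- lapply(lev, function(l) {
      one_vs(binary_counts(new_confusion(m, l)))
    })
    panel <- lapply(stats::setNames(nm = names(per[[1]])), function(nm)
      mean(vapply(per, `[[`, 0, nm)))
  }
  structure(c(list(accuracy = acc), panel,
              list(kappa = kap, n = n, flags = unique(flags))),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.3f | sens %.3f | spec %.3f | PPV %.3f | NPV %.3f | PLR %.2f | kappa %.2f (n=%g)\n",
    x$accuracy, x$sensitivity, x$specificity, x$ppv, x$npv, x$plr,
    x$kappa, x$n))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Reconstruct a binary confusion matrix from summary statistics
#'
#' Given published sensitivity, specificity, prevalence and sample size,
#' rebuilds the (real-valued) confusion counts:
#' `TP = sens * prev * n`, `TN = spec * (1 - prev) * n`, with FN/FP by
#' complement. Feeding the result to [metrics()] recovers the remaining
#' panel entries (PPV, NPV, PLR, kappa) implied by a published table row.
#'
#' @param sensitivity,specificity,prevalence Values in `[0, 1]`.
#' @param n Total sample size (default 1; counts become proportions).
#' @return A `confusion` with real-valued counts (positive class `"1"`).
#' @export
reconstruct_from_summary <- function(sensitivity, specificity, prevalence,
                                     n = 1) {
  vals <- c(sensitivity, specificity, prevalence)
  assert_that(all(vals >= 0 & vals <= 1),
              "sensitivity, specificity and prevalence must lie in [0, 1]")
  assert_that(n > 0, "n must be positive")
  tp <- sensitivity * prevalence * n
  fn <- (1 - sensitivity) * prevalence * n
  tn <- specificity * (1 - prevalence) * n
  fp <- (1 - specificity) * (1 - prevalence) * n
  m <- matrix(c(tn, fn, fp, tp), 2L, 2L,
              dimnames = list(true = c("0", "1"), predicted = c("0", "1")))
  new_confusion(m, "1")
}

#' Cross-validation plan
#'
#' @param n_folds Number of folds (default 10).
#' @param mode `"trial-blocked"` (default; all cubes of one stimulation
#'   trial stay in one fold, preventing leakage between overlapping
#'   windows), `"sample-shuffled"` (cubes assigned at random), or
#'   `"subject-blocked"`.
#' @param seed Integer seed for fold assignment.
#' @return A `cv_plan`.
#' @export
cv_plan <- function(n_folds = 10L, mode = c("trial-blocked",
                                            "sample-shuffled",
                                            "subject-blocked"),
                    seed = 1L) {
  mode <- match.arg(mode)
  assert_that(n_folds >= 2, "need at least 2 folds")
  structure(list(n_folds = as.integer(n_folds), mode = mode,
                 seed = as.integer(seed)), class = "cv_plan")
}

# Fold id per cube under the plan.
assign_folds <- function(set, plan) {
  n <- n_cubes(set)
  an <- set$anchors
  if (plan$mode == "sample-shuffled") {
    return(with_seed(plan$seed,
                     sample(rep_len(seq_len(plan$n_folds), n))))
  }
  group <- if (plan$mode == "trial-blocked") {
    paste(an$subject, an$trial)
  } else {
    an$subject
  }
  ug <- unique(group)
  if (length(ug) < plan$n_folds) {
    stop_validation(sprintf(
      "%s cross-validation needs >= %d groups, have %d",
      plan$mode, plan$n_folds, length(ug)))
  }
  gf <- with_seed(plan$seed,
                  stats::setNames(rep_len(seq_len(plan$n_folds),
                                          length(ug))[sample.int(length(ug))],
                                  ug))
  as.integer(gf[group])
}

#' Cross-validated model evaluation
#'
#' Trains and evaluates one architecture under a [cv_plan()]. Class
#' weighting and oversampling are applied inside the training folds only;
#' test folds are never resampled. A single train/test split (the
#' no-cross-validation design used for the merged localization data) is
#' available via `holdout_evaluate()`.
#'
#' @param spec A [network_spec()].
#' @param set A `cube_set`.
#' @param plan A [cv_plan()].
#' @param config A [train_config()].
#' @param oversample_train Oversample minority classes in each training
#'   fold (default `FALSE`).
#' @return A `cv_report`: per-fold `metric_report`s, their means
#'   (`$mean`), the plan, and the pooled confusion matrix.
#' @export
cross_validate <- function(spec, set, plan = cv_plan(),
                           config = train_config(),
                           oversample_train = FALSE) {
  folds <- assign_folds(set, plan)
  seeds <- derive_seeds(plan$seed, plan$n_folds)
  binary <- spec$n_classes == 2L
  fold_reports <- vector("list", plan$n_folds)
  pooled_true <- pooled_pred <- integer()
  for (k in seq_len(plan$n_folds)) {
    train_set <- cube_subset(set, which(folds != k))
    test_set <- cube_subset(set, which(folds == k))
    if (oversample_train) {
      train_set <- oversample(train_set, seed = seeds[k], binary = binary)
    }
    model <- build_network(spec, seed = seeds[k])
    cfg <- config
    cfg$seed <- seeds[k]
    model <- train(model, train_set, cfg)
    pred <- predict(model, test_set)
    truth <- cube_labels(test_set, binary = binary)
    fold_reports[[k]] <- metrics(confusion(truth, pred$codes))
    pooled_true <- c(pooled_true, truth)
    pooled_pred <- c(pooled_pred, pred$codes)
  }
  summarize_cv(fold_reports, plan, pooled_true, pooled_pred)
}

summarize_cv <- function(fold_reports, plan, pooled_true, pooled_pred) {
  nm <- c("accuracy", "sensitivity", "specificity", "plr", "ppv", "npv",
          "kappa")
  means <- vapply(nm, function(f) {
    vals <- vapply(fold_reports, `[[`, 0, f)
    mean(vals[is.finite(vals)])
  }, 0)
  structure(list(folds = fold_reports, mean = as.list(means),
                 plan = plan,
                 pooled = metrics(confusion(pooled_true, pooled_pred))),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d folds, %s split\n",
              length(x$folds), x$plan$mode))
  cat("fold means: ")
  cat(sprintf(
    "accuracy %.3f | sens %.3f | spec %.3f | PPV %.3f | NPV %.3f | PLR %.2f | kappa %.2f\n",
    x$mean$accuracy, x$mean$sensitivity, x$mean$specificity, x$mean$ppv,
    x$mean$npv, x$mean$plr, x$mean$kappa))
  invisible(x)
}

#' Single holdout split evaluation
#'
#' Trains on all cubes except one held-out group fraction and evaluates on
#' the rest; the no-cross-validation design. Splitting is trial-blocked.
#'
#' @param spec A [network_spec()].
#' @param set A `cube_set`.
#' @param test_fraction Fraction of trial groups held out (default 0.3).
#' @param seed Split/training seed.
#' @param config A [train_config()].
#' @param oversample_train As in [cross_validate()].
#' @return List with `report` (a `metric_report`), `model`, and the test
#'   cube indices.
#' @export
holdout_evaluate <- function(spec, set, test_fraction = 0.3, seed = 1L,
                             config = train_config(),
                             oversample_train = FALSE) {
  an <- set$anchors
  group <- paste(an$subject, an$trial)
  ug <- unique(group)
  n_test <- max(1L, round(test_fraction * length(ug)))
  test_groups <- with_seed(seed, sample(ug, n_test))
  test_idx <- which(group %in% test_groups)
  train_set <- cube_subset(set, setdiff(seq_len(nrow(an)), test_idx))
  test_set <- cube_subset(set, test_idx)
  binary <- spec$n_classes == 2L
  if (oversample_train) {
    train_set <- oversample(train_set, seed = seed, binary = binary)
  }
  model <- build_network(spec, seed = seed)
  model <- train(model, train_set, config)
  pred <- predict(model, test_set)
  truth <- cube_labels(test_set, binary = binary)
  list(report = metrics(confusion(truth, pred$codes)), model = model,
       test_idx = test_idx)
}

#' Null accuracy of a label-independent predictor
#'
#' Under permuted labels the best a classifier can do is predict the
#' majority class; its accuracy is the majority fraction with binomial
#' sampling noise. Used as the chance reference for the end-to-end
#' decoding checks.
#'
#' @param labels Label vector of the evaluated set.
#' @return List with `p0` (majority fraction), `sd` (binomial SD of the
#'   accuracy over `length(labels)` draws), and `n`.
#' @export
null_accuracy <- function(labels) {
  n <- length(labels)
  p0 <- max(table(labels)) / n
  list(p0 = p0, sd = sqrt(p0 * (1 - p0) / n), n = n)
}
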
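#' Screen features against a binary target
#'
#' Computes, for every feature column, the point-biserial correlation with the
#' 0/1 target (Pearson correlation against the dummy-coded label, with its
#' t-test p-value) and the two-sample Kolmogorov-Smirnov statistic between
#' the two classes (exact null distribution where available). Features are
#' flagged significant at `p < alpha`.
#'
#' @param features data frame of numeric feature columns.
#' @param labels binary vector (logical, 0/1, or two-level factor/character).
#' @param alpha significance level for the flags (default 0.05).
#' @return tibble with one row per feature: `feature`, `r`, `r_p`, `ks`,
#'   `ks_p`, `r_significant`, `ks_significant`.
#' @export
screen_features <- function(features, labels, alpha = 0.05) {
  y <- as_binary01(labels)
  if (length(unique(y)) < 2) abort("labels must contain both classes")
  if (min(table(y)) < 2) abort("need at least 2 observations per class")
  purrr::map_dfr(names(features), function(nm) {
    x <- features[[nm]]
    if (sd(x) == 0) {
      return(tibble(feature = nm, r = 0, r_p = 1, ks = 0, ks_p = 1))
    }
    ct <- cor.test(x, y)
    kt <- suppressWarnings(ks.test(x[y == 0], x[y == 1], exact = TRUE))
    tibble(feature = nm, r = unname(ct$estimate), r_p = ct$p.value,
           ks = unname(kt$statistic), ks_p = kt$p.value)
  }) %>%
    mutate(r_significant = .data$r_p < alpha,
           ks_significant = .data$ks_p < alpha)
}

as_binary01 <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    u <- sort(unique(labels))
    if (!all(u %in% c(0, 1))) abort("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  f <- factor(labels)
  if (nlevels(f) != 2) abort("labels must have exactly two levels")
  as.integer(f) - 1L
}

standardize_cols <- function(df, center = NULL, scale = NULL) {
  center <- center %||% purrr::map_dbl(df, mean)
  scale <- scale %||% purrr::map_dbl(df, sd)
  scale[scale == 0] <- 1
  out <- as_tibble(purrr::imap(df, function(x, nm) (x - center[[nm]]) / scale[[nm]]))
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

# Participant-grouped fold assignment: participants shuffled, dealt round-robin.
grouped_folds <- function(participants, k) {
  ids <- unique(participants)
  if (length(ids) < k) abort(sprintf("need at least %d participants for %d folds", k, k))
  ids <- sample(ids)
  fold_of <- setNames(rep_len(seq_len(k), length(ids)), ids)
  unname(fold_of[as.character(participants)])
}

ridge_logistic <- function(x, y, lambda = 0.01) {
  x <- as.matrix(x)
  if (ncol(x) == 1) {
    # glmnet needs >= 2 columns; pad with a zero column it cannot use
    x <- cbind(x, .pad = 0)
  }
  glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                 lambda = lambda, standardize = FALSE)
}

ridge_predict <- function(fit, x) {
  x <- as.matrix(x)
  if (ncol(x) == 1) x <- cbind(x, .pad = 0)
  predict(fit, x, type = "response")[, 1]
}

ridge_coefs <- function(fit, names) {
  co <- abs(coef(fit)[-1, 1])
  co[names]
}

#' Recursive feature elimination with participant-grouped cross-validation
#'
#' Five repetitions of recursive feature elimination, each over a fresh
#' participant-grouped 10-fold split. Within a repetition, features are
#' standardized per training fold and ranked by the mean absolute coefficient
#' of a ridge-regularized logistic model across folds; the weakest feature is
#' eliminated until one remains, and the retained subset size is the one
#' maximizing mean out-of-fold accuracy (ties broken towards fewer features).
#' The consensus set keeps features selected in at least `consensus_min` of
#' the five repetition subsets.
#'
#' @param features data frame of numeric feature columns.
#' @param labels binary labels (see [screen_features()]).
#' @param participants participant id per row (grouping unit for the folds).
#' @param seed integer seed controlling the fold assignments.
#' @param n_repeats number of repetitions (default 5).
#' @param n_folds folds per repetition (default 10).
#' @param consensus_min minimum number of subsets a feature must appear in
#'   (default 3).
#' @param lambda ridge penalty of the base estimator.
#' @return list with `consensus` (character vector), `subsets` (list of the
#'   per-repetition selections), and `votes` (tibble of per-feature counts).
#' @export
rfe_select <- function(features, labels, participants, seed = 1,
                       n_repeats = 5, n_folds = 10, consensus_min = 3,
                       lambda = 0.01) {
  y <- as_binary01(labels)
  if (length(unique(participants)) < n_folds) {
    abort(sprintf("need at least %d participants for %d-fold grouped CV",
                  n_folds, n_folds))
  }
  subsets <- vector("list", n_repeats)
  for (rep_i in seq_len(n_repeats)) {
    set.seed(seed * 1000L + rep_i)
    folds <- grouped_folds(participants, n_folds)
    active <- names(features)
    best_acc <- -Inf
    best_set <- active
    while (length(active) >= 1) {
      accs <- numeric(n_folds)
      coef_abs <- matrix(0, n_folds, length(active),
                         dimnames = list(NULL, active))
      ok <- logical(n_folds)
      for (f in seq_len(n_folds)) {
        tr <- folds != f
        if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) next
        xtr <- standardize_cols(features[tr, active, drop = FALSE])
        xte <- standardize_cols(features[!tr, active, drop = FALSE],
                                center = attr(xtr, "center"),
                                scale = attr(xtr, "scale"))
        fit <- ridge_logistic(xtr, y[tr], lambda)
        p <- ridge_predict(fit, xte)
        accs[f] <- mean((p >= 0.5) == (y[!tr] == 1))
        coef_abs[f, ] <- ridge_coefs(fit, active)
        ok[f] <- TRUE
      }
      if (!any(ok)) abort("every fold degenerate; supply more participants")
      mean_acc <- mean(accs[ok])
      if (mean_acc >= best_acc) {  # >= prefers the smaller set explored later
        best_acc <- mean_acc
        best_set <- active
      }
      if (length(active) == 1) break
      rank_score <- colMeans(coef_abs[ok, , drop = FALSE])
      active <- setdiff(active, names(which.min(rank_score)))
    }
    subsets[[rep_i]] <- sort(best_set)
  }
  votes <- tibble(feature = names(features)) %>%
    mutate(n_selected = map_int(.data$feature, function(f) {
      sum(map_lgl(subsets, function(s) f %in% s))
    }))
  list(
    consensus = votes$feature[votes$n_selected >= consensus_min],
    subsets = subsets,
    votes = votes
  )
}

vif_values <- function(df) {
  map_dbl(names(df), function(nm) {
    others <- setdiff(names(df), nm)
    if (length(others) == 0) return(1)
    r2 <- summary(lm(df[[nm]] ~ ., data = df[, others, drop = FALSE]))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }) %>% setNames(names(df))
}

#' Variance-inflation-factor reduction by combining collinear features
#'
#' Iteratively computes the VIF of every feature and, while the largest VIF
#' exceeds the threshold, replaces the worst feature and its most-correlated
#' partner by the sum of their standardized values (named `"a+b"`), dropping
#' both originals. Terminates with all VIFs at or below the threshold.
#'
#' @param features data frame of numeric feature columns (at least 2).
#' @param threshold VIF threshold (default 2.5).
#' @return list with `features` (the reduced data frame), `combined` (tibble
#'   of `name`, `constituents`), `vif` (tibble of final VIFs), and
#'   `vif_initial`.
#' @export
vif_reduce <- function(features, threshold = 2.5) {
  if (ncol(features) < 2) abort("vif_reduce needs at least 2 features")
  const <- names(features)[map_dbl(features, sd) == 0]
  if (length(const)) {
    abort(paste0("constant feature(s) cannot enter a VIF analysis: ",
                 paste(const, collapse = ", ")))
  }
  if (nrow(features) <= ncol(features)) {
    abort("need more observations than features for VIF computation")
  }
  df <- as_tibble(features)
  combined <- tibble(name = character(), constituents = list())
  vif0 <- vif_values(df)
  repeat {
    v <- vif_values(df)
    if (max(v) <= threshold) break
    worst <- names(which.max(v))
    cors <- abs(cor(df))[worst, ]
    cors[worst] <- -Inf
    partner <- names(which.max(cors))
    new_name <- paste0(worst, "+", partner)
    parts_w <- combined$constituents[combined$name == worst]
    parts_p <- combined$constituents[combined$name == partner]
    constituents <- c(
      if (length(parts_w)) parts_w[[1]] else worst,
      if (length(parts_p)) parts_p[[1]] else partner
    )
    df[[new_name]] <- as.numeric(scale(df[[worst]])) + as.numeric(scale(df[[partner]]))
    df[[worst]] <- NULL
    df[[partner]] <- NULL
    combined <- bind_rows(
      combined[!combined$name %in% c(worst, partner), ],
      tibble(name = new_name, constituents = list(constituents))
    )
    if (ncol(df) < 2) break
  }
  list(
    features = df,
    combined = combined,
    vif = tibble(feature = names(df), vif = unname(vif_values(df))),
    vif_initial = tibble(feature = names(vif0), vif = unname(vif0))
  )
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

classification_metrics <- function(y, p, threshold = 0.5) {
  pred <- as.integer(p >= threshold)
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  auc <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE, direction = "<")))
  tibble(sensitivity = sens, specificity = spec, f1 = f1,
         accuracy = mean(pred == y), auc = auc)
}

#' Train and evaluate the three reliability classifiers
#'
#' Fits logistic regression, a radial-basis SVM and a random forest under
#' stratified k-fold cross-validation. Standardization is fitted on each
#' training fold and applied to its test fold (set `global_standardize = TRUE`
#' to normalize once on the full table instead); out-of-fold scores are
#' pooled and the metrics - sensitivity, specificity, F1, accuracy, AUC - are
#' computed once on the pooled predictions (class threshold 0.5). Logistic
#' odds ratios come from a full-data refit on standardized features.
#'
#' @param features data frame of numeric features (already collinearity-reduced).
#' @param labels binary labels; the positive class is the second factor level
#'   (or 1 / `TRUE`).
#' @param seed integer seed for the fold assignment.
#' @param n_folds number of folds (default 5).
#' @param models subset of `c("lr", "svm", "rf")`.
#' @param global_standardize normalize on the full table rather than per fold.
#' @return A `classifier_report`: list with `metrics` (tibble, one row per
#'   model), `predictions` (pooled out-of-fold scores), and `lr_coefficients`
#'   (tibble with `term`, `estimate`, `odds_ratio`).
#' @export
train_evaluate <- function(features, labels, seed = 1, n_folds = 5,
                           models = c("lr", "svm", "rf"),
                           global_standardize = FALSE) {
  y <- as_binary01(labels)
  if (length(unique(y)) < 2) abort("labels must contain both classes")
  models <- match.arg(models, several.ok = TRUE)
  set.seed(seed)
  folds <- stratified_folds(y, n_folds)
  if (any(tapply(y, folds, function(v) length(unique(v))) < 2)) {
    abort("a fold contains a single class; use a larger sample")
  }
  glob <- if (global_standardize) standardize_cols(features) else NULL
  preds <- purrr::map_dfr(seq_len(n_folds), function(f) {
    tr <- folds != f
    if (global_standardize) {
      xtr <- glob[tr, , drop = FALSE]
      xte <- glob[!tr, , drop = FALSE]
    } else {
      xtr <- standardize_cols(features[tr, , drop = FALSE])
      xte <- standardize_cols(features[!tr, , drop = FALSE],
                              center = attr(xtr, "center"),
                              scale = attr(xtr, "scale"))
    }
    dtr <- dplyr::bind_cols(xtr, tibble(.y = y[tr]))
    out <- tibble(row = which(!tr), fold = f, y = y[!tr])
    if ("lr" %in% models) {
      fit <- suppressWarnings(glm(.y ~ ., data = dtr, family = binomial()))
      out$lr <- suppressWarnings(predict(fit, xte, type = "response"))
    }
    if ("svm" %in% models) {
      fit <- e1071::svm(x = as.matrix(xtr), y = factor(y[tr], levels = c(0, 1)),
                        kernel = "radial", probability = TRUE)
      pr <- attr(predict(fit, as.matrix(xte), probability = TRUE), "probabilities")
      out$svm <- pr[, "1"]
    }
    if ("rf" %in% models) {
      fit <- randomForest::randomForest(x = as.data.frame(xtr),
                                        y = factor(y[tr], levels = c(0, 1)))
      out$rf <- predict(fit, as.data.frame(xte), type = "prob")[, "1"]
    }
    out
  })
  metrics <- purrr::map_dfr(models, function(mdl) {
    dplyr::bind_cols(tibble(model = mdl),
                     classification_metrics(preds$y, preds[[mdl]]))
  })
  lr_coefficients <- NULL
  if ("lr" %in% models) {
    xall <- standardize_cols(features)
    fit <- suppressWarnings(glm(y ~ ., data = dplyr::bind_cols(xall, tibble(y = y)),
                                family = binomial()))
    lr_coefficients <- tibble(
      term = names(coef(fit)),
      estimate = unname(coef(fit)),
      odds_ratio = odds_ratios(unname(coef(fit)))
    )
  }
  structure(
    list(metrics = metrics, predictions = preds,
         lr_coefficients = lr_coefficients, seed = seed, n_folds = n_folds),
    class = "classifier_report"
  )
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> %d-fold stratified CV (seed %d)\n",
              x$n_folds, x$seed))
  print(x$metrics)
  invisible(x)
}

#' @export
tidy.classifier_report <- function(x, ...) {
  x$lr_coefficients %||% x$metrics
}

#' @export
glance.classifier_report <- function(x, ...) x$metrics

#' Odds ratios from logistic coefficients
#'
#' @param coefficients numeric vector of logistic-regression coefficients.
#' @return `exp(coefficients)`.
#' @export
odds_ratios <- function(coefficients) {
  if (any(!is.finite(coefficients))) abort("coefficients must be finite")
  exp(coefficients)
}
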
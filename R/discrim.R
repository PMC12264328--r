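# Group-discrimination stage: variance/volume-correlation filtering,
# bootstrapped greedy mRMR selection, leave-one-patient-out logistic
# regression, ROC/AUC and the DeLong test for correlated ROC curves.

#' Filter features before selection
#'
#' Drops zero-variance columns and columns whose absolute Pearson correlation
#' with `shape_MeshVolume` exceeds 0.8 (strictly); `shape_MeshVolume` itself is
#' retained.
#'
#' @param table feature table with key columns and feature columns.
#' @return the table with offending feature columns removed.
#' @export
filter_features <- function(table) {
  fc <- feature_cols(table)
  if (!"shape_MeshVolume" %in% fc) {
    abort("feature table must contain shape_MeshVolume", class = "radstab_config_error")
  }
  vols <- table$shape_MeshVolume
  drop <- vapply(fc, function(f) {
    x <- table[[f]]
    if (anyNA(x) || sd(x) == 0) return(f != "shape_MeshVolume" || anyNA(x))
    if (f == "shape_MeshVolume") return(FALSE)
    if (sd(vols) == 0) return(FALSE)
    abs(stats::cor(x, vols)) > 0.8
  }, logical(1))
  table[, c(setdiff(names(table), fc), fc[!drop])]
}

f_statistic <- function(x, y) {
  # one-way ANOVA F of feature x against the two-class label y
  groups <- split(x, y)
  k <- length(groups)
  n <- length(x)
  gm <- mean(x)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ssw == 0) return(Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}

mrmr_greedy <- function(X, y, k) {
  fc <- colnames(X)
  rel <- vapply(fc, function(f) f_statistic(X[, f], y), numeric(1))
  rel[!is.finite(rel)] <- 1e6
  # map the F-statistic through F/(1+F) onto [0, 1] so the difference
  # criterion trades it off against the [0, 1] redundancy term
  rel <- rel / (1 + rel)
  sel <- character(0)
  while (length(sel) < k) {
    remaining <- setdiff(fc, sel)
    score <- vapply(remaining, function(f) {
      # max (not mean) over selected features: a near-duplicate keeps its full
      # redundancy penalty no matter how many uncorrelated features join later
      red <- if (length(sel)) {
        max(vapply(sel, function(s) {
          if (sd(X[, f]) == 0 || sd(X[, s]) == 0) 1 else abs(stats::cor(X[, f], X[, s]))
        }, numeric(1)))
      } else 0
      rel[f] - red
    }, numeric(1))
    sel <- c(sel, remaining[which.max(score)])
  }
  sel
}

#' Bootstrapped minimum-redundancy maximum-relevance feature selection
#'
#' Runs greedy mRMR (F-statistic relevance, maximum absolute Pearson
#' correlation redundancy, difference criterion) on `n_boot` class-stratified bootstrap
#' resamples of the scans and returns the `k` features most frequently
#' selected; ties break by mean selection position, then by name.
#'
#' @param table filtered feature table.
#' @param labels group label per row.
#' @param n_boot bootstrap resamples (default 500).
#' @param k features to select (default 5).
#' @param seed random seed.
#' @return list with `selected` (k names) and `frequency` (tibble of selection
#'   frequencies).
#' @export
mrmr_bootstrap <- function(table, labels, n_boot = 500, k = 5, seed = 1) {
  fc <- feature_cols(table)
  if (length(fc) < k) {
    abort(sprintf("only %d candidate features for k = %d", length(fc), k),
          class = "radstab_selection_error")
  }
  if (length(unique(labels)) != 2) {
    abort("two classes are required", class = "radstab_input_error")
  }
  X <- as.matrix(table[, fc])
  idx_by_class <- split(seq_along(labels), labels)
  tally <- setNames(numeric(length(fc)), fc)
  pos_sum <- setNames(numeric(length(fc)), fc)
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      take <- unlist(lapply(idx_by_class, function(ix) {
        ix[sample.int(length(ix), length(ix), replace = TRUE)]
      }), use.names = FALSE)
      sel <- mrmr_greedy(X[take, , drop = FALSE], labels[take], k)
      tally[sel] <- tally[sel] + 1
      pos_sum[sel] <- pos_sum[sel] + seq_len(k)
    }
  })
  freq <- tibble::tibble(feature = fc, frequency = tally / n_boot,
                         mean_position = ifelse(tally > 0, pos_sum / tally, Inf)) |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$mean_position, .data$feature)
  list(selected = freq$feature[seq_len(k)], frequency = freq)
}

fit_logistic <- function(X, y01) {
  fit <- withCallingHandlers(
    stats::glm(y01 ~ ., data = data.frame(X, y01 = y01), family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  separated <- any(abs(coef(fit)[-1]) > 15, na.rm = TRUE) || !fit$converged
  if (separated) {
    gfit <- suppressWarnings(glmnet::glmnet(as.matrix(X), y01,
                                            family = "binomial", alpha = 0,
                                            lambda = 0.01))
    list(type = "ridge", fit = gfit)
  } else {
    list(type = "glm", fit = fit)
  }
}

predict_logistic <- function(model, X) {
  if (model$type == "glm") {
    as.numeric(predict(model$fit, newdata = data.frame(X), type = "response"))
  } else {
    as.numeric(predict(model$fit, newx = as.matrix(X), type = "response"))
  }
}

#' AUC by the Mann-Whitney statistic
#'
#' @param scores predicted probabilities (higher = positive class).
#' @param labels binary labels (positive = second level or 1).
#' @return area under the ROC curve.
#' @export
auc_mann_whitney <- function(scores, labels) {
  y <- as.integer(as.factor(labels)) - 1L
  pos <- scores[y == 1]; neg <- scores[y == 0]
  if (!length(pos) || !length(neg)) {
    abort("both classes are required for an AUC", class = "radstab_input_error")
  }
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Leave-one-patient-out logistic classification
#'
#' One fold per patient leaves out all of that patient's scans; features are
#' standardized with training-fold statistics only; held-out scans receive
#' predicted probabilities, pooled across folds into a single ROC/AUC.
#'
#' @param table feature table with `subject_id` and `group`.
#' @param selected feature names entering the model.
#' @param positive label treated as the positive class (default `"CKD"`).
#' @return object of class `lopo_report`: tibble of per-scan predictions plus
#'   `auc`, `roc` (tibble of fpr/tpr), `selected`.
#' @export
fit_eval_lopo <- function(table, selected, positive = "CKD") {
  stopifnot(all(selected %in% names(table)))
  y01 <- as.integer(table$group == positive)
  if (length(unique(table$subject_id[y01 == 1])) < 2 ||
      length(unique(table$subject_id[y01 == 0])) < 2) {
    abort(">= 2 patients per class are required", class = "radstab_input_error")
  }
  patients <- unique(table$subject_id)
  preds <- rep(NA_real_, nrow(table))
  for (p in patients) {
    test_ix <- which(table$subject_id == p)
    train_ix <- setdiff(seq_len(nrow(table)), test_ix)
    ytr <- y01[train_ix]
    if (length(unique(ytr)) < 2) {
      warn(sprintf("fold %s skipped: one class absent from training data", p),
           class = "radstab_fold_error")
      next
    }
    Xtr <- as.matrix(table[train_ix, selected])
    mu <- colMeans(Xtr); sg <- apply(Xtr, 2, sd); sg[sg == 0] <- 1
    Xtr <- scale(Xtr, mu, sg)
    Xte <- scale(as.matrix(table[test_ix, selected, drop = FALSE]), mu, sg)
    colnames(Xtr) <- colnames(Xte) <- selected
    model <- fit_logistic(Xtr, ytr)
    preds[test_ix] <- predict_logistic(model, Xte)
  }
  ok <- !is.na(preds)
  auc <- auc_mann_whitney(preds[ok], y01[ok])
  th <- sort(unique(c(-Inf, preds[ok], Inf)), decreasing = TRUE)
  roc <- tibble::tibble(
    fpr = vapply(th, function(t) mean(preds[ok][y01[ok] == 0] >= t), numeric(1)),
    tpr = vapply(th, function(t) mean(preds[ok][y01[ok] == 1] >= t), numeric(1))
  )
  structure(list(
    predictions = tibble::tibble(subject_id = table$subject_id,
                                 group = table$group,
                                 repeat_index = table$repeat_index %||% NA_integer_,
                                 prob = preds, label = y01),
    auc = auc, roc = roc, selected = selected, positive = positive
  ), class = "lopo_report")
}

#' @export
print.lopo_report <- function(x, ...) {
  cat("<lopo_report> AUC =", round(x$auc, 4), "on", nrow(x$predictions),
      "scans;", "features:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' DeLong test for two correlated ROC curves
#'
#' Two-sided comparison of the AUCs of two prediction vectors over the same
#' scans, using the placement-value covariance estimator.
#'
#' @param pred_a,pred_b predicted probabilities on the same scans.
#' @param labels binary labels.
#' @return list with `auc_a`, `auc_b`, `p_value`.
#' @export
delong_test <- function(pred_a, pred_b, labels) {
  y <- as.integer(as.factor(labels)) - 1L
  if (length(unique(y)) < 2) {
    abort("both classes are required for the DeLong test", class = "radstab_input_error")
  }
  stopifnot(length(pred_a) == length(y), length(pred_b) == length(y))
  placements <- function(s) {
    pos <- s[y == 1]; neg <- s[y == 0]
    m <- length(pos); n <- length(neg)
    psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
  }
  A <- placements(pred_a); B <- placements(pred_b)
  m <- length(A$v10); n <- length(A$v01)
  s10 <- stats::cov(cbind(A$v10, B$v10))
  s01 <- stats::cov(cbind(A$v01, B$v01))
  S <- s10 / m + s01 / n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- A$auc - B$auc
  if (var_diff <= .Machine$double.eps) {
    p <- if (abs(d) < 1e-12) 1 else 0
  } else {
    p <- 2 * pnorm(-abs(d) / sqrt(var_diff))
  }
  list(auc_a = A$auc, auc_b = B$auc, p_value = min(1, p))
}
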
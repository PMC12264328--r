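# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_abline
#'   geom_point facet_grid labs scale_fill_brewer coord_equal vars
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Per-feature ICC values and stability classes of a threshold scan
#' @param x a `threshold_scan`.
#' @param ... unused.
#' @return tibble with group, threshold, feature, ICC_S, ICC_A and class.
#' @method tidy threshold_scan
#' @export
tidy.threshold_scan <- function(x, ...) x$icc

#' One-row-per-group summary of a threshold scan
#' @param x a `threshold_scan`.
#' @param ... unused.
#' @return tibble with th_opt and class counts at th_opt.
#' @method glance threshold_scan
#' @export
glance.threshold_scan <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$th_opt), function(g) {
    cnt <- x$counts[x$counts$group == g & x$counts$th == x$th_opt[[g]], ]
    tibble::tibble(group = g, th_opt = x$th_opt[[g]],
                   n1 = sum(cnt$n[cnt$class == 1]), n2 = sum(cnt$n[cnt$class == 2]),
                   n3 = sum(cnt$n[cnt$class == 3]), n4 = sum(cnt$n[cnt$class == 4]))
  }))
}

#' Per-scan predictions of a leave-one-patient-out classifier
#' @param x a `lopo_report`.
#' @param ... unused.
#' @return tibble of per-scan predicted probabilities.
#' @method tidy lopo_report
#' @export
tidy.lopo_report <- function(x, ...) x$predictions

#' One-row summary of a leave-one-patient-out classifier
#' @param x a `lopo_report`.
#' @param ... unused.
#' @return tibble with the AUC, scan count and selected features.
#' @method glance lopo_report
#' @export
glance.lopo_report <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_scans = sum(!is.na(x$predictions$prob)),
                 n_features = length(x$selected),
                 features = paste(x$selected, collapse = ", "))
}

#' Class counts across confidence thresholds
#' @param object a `threshold_scan`.
#' @param ... unused.
#' @return a ggplot: stacked class counts per threshold, faceted by group.
#' @method autoplot threshold_scan
#' @export
autoplot.threshold_scan <- function(object, ...) {
  d <- object$counts
  d$class <- factor(d$class, 1:4, paste("Class", 1:4))
  ggplot(d, aes(x = factor(.data$th), y = .data$n, fill = .data$class)) +
    geom_col() +
    facet_grid(cols = vars(.data$group)) +
    scale_fill_brewer(palette = "RdYlBu", direction = -1) +
    labs(x = "confidence level th (%)", y = "features", fill = NULL)
}

#' ROC curve of a leave-one-patient-out classifier
#' @param object a `lopo_report`.
#' @param ... unused.
#' @return a ggplot of the pooled ROC curve with the chance diagonal.
#' @method autoplot lopo_report
#' @export
autoplot.lopo_report <- function(object, ...) {
  ggplot(object$roc, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    geom_line() +
    coord_equal() +
    labs(x = "false-positive rate", y = "true-positive rate",
         title = sprintf("AUC = %.3f", object$auc))
}
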
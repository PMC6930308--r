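#' Multiclass confusion matrix
#'
#' Rows are true classes, columns assigned classes, in `class_order`.
#'
#' @param true_labels character vector of true classes.
#' @param assigned character vector of assigned classes, same length.
#' @param class_order ordered class names.
#' @return integer matrix of counts with `class_order` dimnames.
#' @export
confusion <- function(true_labels, assigned, class_order) {
  if (length(true_labels) != length(assigned)) {
    stop("true_labels and assigned must have equal length")
  }
  bad <- setdiff(c(true_labels, assigned), class_order)
  if (length(bad)) {
    stop("labels not in class_order: ", paste(unique(bad), collapse = ", "))
  }
  tt <- table(factor(true_labels, levels = class_order),
              factor(assigned, levels = class_order))
  cm <- matrix(as.integer(tt), length(class_order), length(class_order),
               dimnames = list(true = class_order, assigned = class_order))
  cm
}

#' Per-class sensitivity, specificity and accuracy
#'
#' One-vs-rest decomposition of a multiclass confusion matrix. For each
#' class: TP is the diagonal cell, FN the rest of its row, FP the rest of
#' its column, TN everything else; sensitivity = TP/(TP+FN), specificity
#' = TN/(TN+FP), accuracy = (TP+TN)/total. A metric with an empty
#' denominator is reported as `NA` rather than 0.
#'
#' @param cm confusion matrix from [confusion()].
#' @return data frame with one row per class and columns `class`,
#'   `sensitivity`, `specificity`, `accuracy`.
#' @export
per_class_metrics <- function(cm) {
  classes <- rownames(cm)
  total <- sum(cm)
  out <- lapply(seq_along(classes), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    data.frame(
      class = classes[i],
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      accuracy = if (total > 0) (tp + tn) / total else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Assemble a per-class classification report
#'
#' Combines cross-validation and test-set evaluations of one model into
#' the long format used by the final tables: one row per class and
#' evaluation.
#'
#' @param cv_cm,test_cm confusion matrices for the pooled
#'   cross-validation assignments and the test-set predictions.
#' @param model_label short model identifier (e.g. "full_spectrum").
#' @param n_lv latent variables used.
#' @param n_variables number of wavenumbers in the model.
#' @return data frame with columns `model`, `class`, `evaluation`,
#'   `sensitivity`, `specificity`, `accuracy_percent`, `n_lv`,
#'   `n_variables`.
#' @export
class_report <- function(cv_cm, test_cm, model_label, n_lv, n_variables) {
  fmt <- function(cm, evaluation) {
    m <- per_class_metrics(cm)
    data.frame(model = model_label, class = m$class, evaluation = evaluation,
               sensitivity = m$sensitivity, specificity = m$specificity,
               accuracy_percent = 100 * m$accuracy,
               n_lv = n_lv, n_variables = n_variables,
               stringsAsFactors = FALSE)
  }
  rbind(fmt(cv_cm, "cross_validation"), fmt(test_cm, "test_set"))
}

#' Render classification reports as CSV and aligned text
#'
#' Writes the combined report table (metrics rounded: sensitivities and
#' specificities to three decimals, accuracies to one decimal percent)
#' and returns the formatted text lines.
#'
#' @param report data frame from [class_report()] (possibly several
#'   models' rows bound together).
#' @param csv_path optional path for the CSV rendition.
#' @return character vector of aligned text lines, invisibly when
#'   `csv_path` is given.
#' @export
render_report <- function(report, csv_path = NULL) {
  out <- report
  out$sensitivity <- round(out$sensitivity, 3)
  out$specificity <- round(out$specificity, 3)
  out$accuracy_percent <- round(out$accuracy_percent, 1)
  if (!is.null(csv_path)) {
    utils::write.csv(out, csv_path, row.names = FALSE)
  }
  lines <- c(
    sprintf("%-15s %-12s %-17s %11s %11s %9s", "Model", "Class",
            "Evaluation", "Sensitivity", "Specificity", "Accuracy"),
    sprintf("%-15s %-12s %-17s %11.3f %11.3f %8.1f%%",
            out$model, out$class, out$evaluation,
            out$sensitivity, out$specificity, out$accuracy_percent)
  )
  if (is.null(csv_path)) lines else invisible(lines)
}
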
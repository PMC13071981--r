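# ggplot2 visualisations for the main result types.

#' @export
autoplot.ihc_km <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time, y = .data$surv,
                               colour = .data$stratum)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::geom_point(data = object[object$n_censor > 0, ],
                        shape = 3, size = 2, show.legend = FALSE) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Relapse-free survival",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier plot of survival by stratum
#'
#' @param times,events,group As in [km_estimate()].
#' @return A ggplot object.
#' @export
plot_km <- function(times, events, group = NULL) {
  autoplot(km_estimate(times, events, group))
}

#' @export
autoplot.ihc_roc <- function(object, ...) {
  ops <- object$operating_points
  at <- ops[ops$cutoff == object$cutoff, ]
  ggplot2::ggplot(ops, ggplot2::aes(x = 1 - .data$specificity,
                                    y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(data = at, colour = "red", shape = 4, size = 3) +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("AUC %.3f [%.3f, %.3f]", object$auc,
                      object$auc_lower, object$auc_upper)) +
    ggplot2::theme_minimal()
}

#' Signature score frequency distribution plot
#'
#' Bar chart of the composite score distribution among included patients.
#'
#' @param signature A [signature_scores()] result.
#' @return A ggplot object.
#' @export
plot_signature_distribution <- function(signature) {
  dist <- signature_distribution(signature)
  ggplot2::ggplot(dist, ggplot2::aes(x = factor(.data$score), y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Signature score", y = "Patients") +
    ggplot2::theme_minimal()
}

#' Biomarker score distributions by molecular subtype
#'
#' Box plots of one biomarker's patient-level scores across subtypes.
#'
#' @param patients Patient tibble with `subtype` and the score column.
#' @param biomarker Biomarker readout name (see [biomarker_names()]).
#' @return A ggplot object.
#' @export
plot_scores_by_subtype <- function(patients, biomarker) {
  col <- tolower(biomarker)
  if (!col %in% names(patients)) {
    abort(paste0("No score column `", col, "` in the patient table."))
  }
  ggplot2::ggplot(patients[!is.na(patients[[col]]), ],
                  ggplot2::aes(x = .data$subtype, y = .data[[col]])) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = biomarker) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
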
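#' Plot growth trajectories of a dataset
#'
#' Hypocotyl length and stem diameter against day after emergence, one
#' line per treatment (colour) averaging over replicates.
#'
#' @param data Growth dataset tibble (see [generate_design_dataset()]).
#' @return A ggplot object.
#' @export
plot_growth_dataset <- function(data) {
  long <- data %>%
    tidyr::pivot_longer(c("hypocotyl_mm", "stem_mm"),
                        names_to = "trait", values_to = "mm") %>%
    group_by(.data$treatment_id, .data$trait, .data$day) %>%
    summarise(mm = mean(.data$mm), .groups = "drop")
  ggplot(long, aes(x = .data$day, y = .data$mm,
                   colour = .data$treatment_id)) +
    geom_line(alpha = 0.8) +
    facet_wrap(vars(.data$trait), scales = "free_y") +
    labs(x = "day after emergence", y = "trait (mm)", colour = "treatment") +
    theme_minimal()
}

#' Predicted-versus-observed plot for a fitted growth model
#'
#' Scatter of model predictions against held-out observations per trait,
#' with the perfect-fit diagonal.
#'
#' @param object A `growth_fit`.
#' @param test Held-out growth dataset.
#' @return A ggplot object.
#' @export
plot_predictions <- function(object, test) {
  pred <- predict(object, test)
  d <- bind_rows(
    tibble(trait = "hypocotyl_mm", observed = test$hypocotyl_mm,
           predicted = pred$hypocotyl_mm),
    tibble(trait = "stem_mm", observed = test$stem_mm,
           predicted = pred$stem_mm)
  )
  ggplot(d, aes(x = .data$observed, y = .data$predicted)) +
    geom_point(alpha = 0.5) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    facet_wrap(vars(.data$trait), scales = "free") +
    labs(x = "observed (mm)", y = "predicted (mm)") +
    theme_minimal()
}

#' @describeIn design_recipe Convergence trace of the evolutionary
#'   search (best error per generation).
#' @param object,x A `recipe_solution`.
#' @param ... Unused.
#' @export
#' @method autoplot recipe_solution
autoplot.recipe_solution <- function(object, ...) {
  ggplot(object$trace, aes(x = .data$generation, y = .data$best)) +
    geom_line() +
    geom_hline(yintercept = 0.3, linetype = "dashed") +
    labs(x = "generation", y = "best Euclidean error (mm)") +
    theme_minimal()
}

#' @describeIn run_closed_loop Daily tracking plot: measured, predicted
#'   and true trait values against day, with the target level.
#' @param object,x A `control_state`.
#' @param ... Unused.
#' @export
#' @method autoplot control_state
autoplot.control_state <- function(object, ...) {
  log <- object$log
  d <- bind_rows(
    tibble(day = log$day, trait = "hypocotyl_mm",
           measured = log$measured_hypocotyl_mm,
           predicted = log$predicted_hypocotyl_mm,
           true = log$true_hypocotyl_mm,
           target = object$target[1]),
    tibble(day = log$day, trait = "stem_mm",
           measured = log$measured_stem_mm,
           predicted = log$predicted_stem_mm,
           true = log$true_stem_mm,
           target = object$target[2])
  ) %>%
    tidyr::pivot_longer(c("measured", "predicted", "true"),
                        names_to = "series", values_to = "mm")
  ggplot(d, aes(x = .data$day, y = .data$mm, colour = .data$series)) +
    geom_line() +
    geom_hline(aes(yintercept = .data$target), linetype = "dashed") +
    facet_wrap(vars(.data$trait), scales = "free_y") +
    labs(x = "day after emergence", y = "trait (mm)", colour = NULL) +
    theme_minimal()
}

#' Plot weight vectors side by side
#'
#' Bar chart of one or more weight vectors (e.g. AHP, entropy and
#' combined) over the indicators.
#'
#' @param ... Weight tibbles (see [weight_vector()]).
#' @return A ggplot object.
#' @export
plot_weights <- function(...) {
  d <- bind_rows(...)
  ggplot(d, aes(x = .data$indicator, y = .data$weight,
                fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    labs(x = NULL, y = "weight", fill = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
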
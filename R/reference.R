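# Published operating points of the clinical feasibility study whose
# protocol this package emulates (evoked dental pain, 12 subjects for
# detection; 2 merged subjects for left/right localization). These are
# inputs for the metric-identity machinery: PLR, kappa and NPV are
# *derivable* from sensitivity, specificity and prevalence, so the panel
# can be recomputed and checked against the printed cells.

#' Published classifier operating points
#'
#' Reference performance table of the clinical feasibility study this
#' package's synthetic protocol emulates: one row per network setup, for
#' the pain/no-pain detection task (evaluated over 180,580 cubes at pain
#' prevalence 23,900/180,580) and the 3-class left/right localization
#' task (30,820 cubes, pooled pain prevalence 4,000/30,820). `accuracy`
#' is in percent; the other columns are proportions except `plr` and
#' `kappa`.
#'
#' @return Data frame with columns `task`, `setup`, `accuracy`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `plr`, `kappa`, plus
#'   attributes `prevalence_detection`, `n_detection`,
#'   `prevalence_localization`, `n_localization`.
#' @export
reference_operating_points <- function() {
  det <- data.frame(
    task = "detection",
    setup = c("CNN-7", "CNN-5", "ANN", "ANN+2portion",
              "ANN+2portion+oversample",
              "ANN+2portion+oversample(HbO)", "RNN+2portion+oversample",
              "LSTM+2portion+oversample"),
    accuracy = c(79.62, 79.25, 79.17, 80.37, 75.93, 77.19, 76.31, 77.29),
    sensitivity = c(0.144, 0.153, 0.192, 0.326, 0.409, 0.379, 0.332, 0.319),
    specificity = c(0.896, 0.891, 0.884, 0.861, 0.801, 0.819, 0.815, 0.828),
    ppv = c(0.169, 0.183, 0.205, 0.266, 0.242, 0.245, 0.211, 0.220),
    npv = c(0.872, 0.872, 0.877, 0.893, 0.898, 0.895, 0.888, 0.887),
    plr = c(1.39, 1.40, 1.65, 2.35, 2.06, 2.10, 1.80, 1.86),
    kappa = c(0.04, 0.05, 0.08, 0.17, 0.16, 0.16, 0.11, 0.12),
    stringsAsFactors = FALSE
  )
  loc <- data.frame(
    task = "localization",
    setup = c("ANN", "CNN-5", "CNN-6", "CNN-7"),
    accuracy = c(70.88, 65.37, 74.23, 73.23),
    sensitivity = c(0.443, 0.375, 0.279, 0.540),
    specificity = c(0.777, 0.723, 0.862, 0.782),
    ppv = c(0.339, 0.250, 0.342, 0.389),
    npv = c(0.844, 0.824, 0.823, 0.868),
    plr = c(1.99, 1.35, 2.02, 2.48),
    kappa = c(0.20, 0.08, 0.15, 0.28),
    stringsAsFactors = FALSE
  )
  structure(rbind(det, loc),
            prevalence_detection = 23900 / 180580,
            n_detection = 180580,
            prevalence_localization = 4000 / 30820,
            n_localization = 30820)
}

#' Recompute the derivable cells of the published performance tables
#'
#' For every reference row, reconstructs the confusion matrix from the
#' printed sensitivity, specificity and the task prevalence
#' ([reconstruct_from_summary()]), recomputes PLR, NPV and kappa with
#' [metrics()], and compares them to the printed cells. A row is flagged
#' self-consistent when its recomputed PLR agrees with the printed one
#' within the printing precision (`tol`).
#'
#' @param rows Reference table (default [reference_operating_points()]).
#' @return The table augmented with `plr_recomputed`, `npv_recomputed`,
#'   `kappa_recomputed`, the absolute PLR difference, and
#'   `self_consistent` (recomputed PLR rounds to the printed cell).
#' @export
check_operating_points <- function(rows = reference_operating_points()) {
  prev <- ifelse(rows$task == "detection",
                 attr(rows, "prevalence_detection"),
                 attr(rows, "prevalence_localization"))
  rec <- lapply(seq_len(nrow(rows)), function(i) {
    cm <- reconstruct_from_summary(rows$sensitivity[i],
                                   rows$specificity[i], prev[i])
    metrics(cm)
  })
  rows$plr_recomputed <- vapply(rec, `[[`, 0, "plr")
  rows$npv_recomputed <- vapply(rec, `[[`, 0, "npv")
  rows$kappa_recomputed <- vapply(rec, `[[`, 0, "kappa")
  rows$plr_diff <- abs(rows$plr_recomputed - rows$plr)
  rows$self_consistent <-
    abs(round(rows$plr_recomputed, 2) - rows$plr) < 1e-9
  rows
}
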
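#' Published screening-study contingency table
#'
#' The 3x3 intention-to-diagnose table of app versus bedside confrontation
#' results for visual-field deficit from the validation study of the
#' screening battery (rows = confrontation, columns = app; third row and
#' column are the patients who were untestable or did not complete testing).
#' Shipped as a CSV under `inst/extdata` and used throughout the examples:
#' its complete-case core has 45 usable patients and, with the app column as
#' the reference axis, reproduces the published accuracy row (sensitivity
#' 0.71, specificity 0.83, PPV 0.79, NPV 0.77).
#'
#' @return A [contingency_3x3()].
#' @examples
#' tab <- screening_field_table()
#' itd_measures(tab, reference_axis = "columns", policy = "complete-case")
#' @export
screening_field_table <- function() {
  path <- system.file("extdata", "app_vs_confrontation_fields_3x3.csv",
                      package = "strokesight", mustWork = TRUE)
  read_contingency_csv(path, labels = c("confrontation", "app"))
}
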
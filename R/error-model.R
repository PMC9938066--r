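#' Polynomial assay-error model
#'
#' Standard deviation of a concentration measurement as a polynomial in
#' the model-predicted concentration:
#' `sigma(y) = c0 + c1 y + c2 y^2 + c3 y^3` (mg/L). The coefficients are
#' assay-specific inputs; the defaults describe a typical assay with a
#' 0.1 mg/L floor and 10% proportional error.
#'
#' @param c0,c1,c2,c3 Polynomial coefficients.
#' @return An object of class `error_model`.
#' @export
error_model <- function(c0 = 0.1, c1 = 0.1, c2 = 0, c3 = 0) {
  coef <- c(c0 = c0, c1 = c1, c2 = c2, c3 = c3)
  stopifnot(is.numeric(coef), all(is.finite(coef)))
  structure(list(coef = coef), class = "error_model")
}

#' Assay standard deviation at predicted concentrations
#'
#' @param em An [error_model()].
#' @param y Predicted concentrations (mg/L).
#' @return Standard deviations (mg/L), same length as `y`. Non-positive
#'   values are returned as-is; downstream likelihood code treats them as
#'   an invalid model/error combination.
#' @export
error_sd <- function(em, y) {
  stopifnot(inherits(em, "error_model"))
  cf <- em$coef
  cf[[1]] + cf[[2]] * y + cf[[3]] * y^2 + cf[[4]] * y^3
}
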
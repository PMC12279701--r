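#' Fourth-root prevalence transform and its inverse
#'
#' Need prevalences are heavily right-skewed across countries; a fourth-root
#' transform makes their distribution close to normal, which is the scale on
#' which the mixed model (\code{\link{prevalence_lmm}}) is fit. The inverse
#' transform (fourth power) maps model-scale summaries back to prevalences.
#'
#' Both maps are strictly monotone on \code{[0, 1]}, so ordered summaries on
#' the transformed scale (for example credible-interval bounds) stay ordered
#' after back-transformation.
#'
#' @param p Numeric vector of prevalences in \code{[0, 1]}.
#' @param y Numeric vector of transformed prevalences (must be nonnegative).
#'
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' transform_prevalence(0.0625) # 0.5
#' inverse_transform_prevalence(transform_prevalence(0.3))
transform_prevalence <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    abort_at("`p` must be numeric in [0, 1]")
  p^(1 / 4)
}

#' @rdname transform_prevalence
#' @export
inverse_transform_prevalence <- function(y) {
  if (!is.numeric(y) || anyNA(y) || any(y < 0))
    abort_at("`y` must be numeric and nonnegative")
  y^4
}
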
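#' Consistency-check configuration
#'
#' @param alpha Significance level the significance conclusion is judged
#'   against. Default 0.05, the tool's conventional default.
#' @param one_tailed_detection Apply the one-tailed rescue when the
#'   document mentions directional testing (see
#'   [detect_one_tailed_context()]). Default `TRUE`.
#' @param zero_p_always_inconsistent Treat `p = .000` as an APA-style
#'   violation that can never be satisfied (the correct form is
#'   `p < .001`). Default `TRUE`.
#' @return A list of class `check_config`.
#' @export
#' @examples
#' check_config(alpha = 0.01)
check_config <- function(alpha = 0.05, one_tailed_detection = TRUE,
                         zero_p_always_inconsistent = TRUE) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1,
            is.logical(one_tailed_detection), is.logical(zero_p_always_inconsistent))
  structure(
    list(
      alpha = alpha,
      one_tailed_detection = isTRUE(one_tailed_detection),
      zero_p_always_inconsistent = isTRUE(zero_p_always_inconsistent)
    ),
    class = "check_config"
  )
}
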
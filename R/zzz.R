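#' @keywords internal
#' @importFrom rlang .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
"_PACKAGE"

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

.onLoad <- function(libname, pkgname) {
  register_backend("toy-threshold", toy_detector, version = "1.0",
                   default_score_threshold = 0.5)
}
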
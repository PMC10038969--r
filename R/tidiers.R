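#' Turn a betadrivers result into a tidy tibble
#'
#' `tidy()` returns one row per estimated component (fractions, test
#' results); `glance()` returns a one-row model summary. These follow the
#' broom convention so results drop straight into dplyr pipelines.
#'
#' @param x A result object (`dbrda_fit`, `varpart_result`,
#'   `mantel_result`, `hostplant_null`).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")
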
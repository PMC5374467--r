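#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx oneway.test rnorm runif sd spline t.test
#' @importFrom utils head
NULL

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_invalid("`%s` must be a positive finite scalar", name)
  invisible(x)
}

# short fingerprint of an R object, used to tag models and outputs with the
# configuration that produced them
config_hash <- function(x) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12, force = TRUE)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(txt), f)
  unname(tools::md5sum(f))
}
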
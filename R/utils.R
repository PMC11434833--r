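stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

assert_num <- function(x, name, positive = FALSE, nonneg = FALSE,
                       finite = TRUE, len = NULL) {
  if (!is.numeric(x)) stopf("'%s' must be numeric", name)
  if (!is.null(len) && length(x) != len)
    stopf("'%s' must have length %d", name, len)
  if (finite && any(!is.finite(x))) stopf("'%s' must be finite", name)
  if (positive && any(x <= 0)) stopf("'%s' must be strictly positive", name)
  if (nonneg && any(x < 0)) stopf("'%s' must be non-negative", name)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
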
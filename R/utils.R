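#' @keywords internal
"_PACKAGE"

#' @importFrom stats lm coef anova predict median quantile rnorm runif sd
#'   var qt pt pf shapiro.test Box.test complete.cases setNames aggregate
#' @importFrom utils read.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_sorb <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "sorbfit_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# derive a reproducible child seed from a master seed and a stream label;
# kept below 2^31 so it is a valid R integer
child_seed <- function(seed, stream) {
  stopifnot(is_scalar_number(seed))
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(seed) * 7919 + h * 104729 + 17) %% 2147483647)
}

fmt_num <- function(x) {
  out <- vapply(x, function(v) sprintf("%.17g", v), character(1))
  out
}
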
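#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbinom runif median mad pnorm p.adjust quantile loess
#'   loess.control predict setNames sd
#' @importFrom utils write.table read.delim modifyList
NULL

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream; seed = NULL means "use the current stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Stage seeds derived from one master seed; offsets keep values < 2^31.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

# configuration errors carry their own class so the CLI can exit 2, not 3
stop_config <- function(...)
  stop(errorCondition(paste0(...),
                      class = c("bsaqtl_config_error", "error", "condition")))

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == trunc(x)
}
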
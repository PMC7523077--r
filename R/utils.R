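#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cor.test p.adjust pt sd t.test var
#' @importFrom utils read.delim write.table combn
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

# stop() wrapper that never truncates the offending ids
mc_stop <- function(...) stop(..., call. = FALSE)

mc_warn <- function(...) warning(..., call. = FALSE)

# all messages go through here so drivers can sink them uniformly
mc_log <- function(...) message(...)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x > 0 && x == round(x)
}

# unordered pair key, stable under (u,v) vs (v,u)
pair_key <- function(u, v) {
  paste(pmin(u, v), pmax(u, v), sep = "\r")
}
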
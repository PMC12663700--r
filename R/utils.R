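# Shared internal helpers.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; tabulated percentage shares in
#' survey reporting conventionally round half away from zero (so 21.75 ->
#' 21.8). Used for all displayed percentage shares.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Deterministic 32-bit stream seed for a (site, variable, channel) triple.
# Polynomial string hash of the ids keeps streams stable when variables are
# added or reordered elsewhere in the codebook.
stream_seed <- function(master, site_id, var_id, channel = 0L) {
  h <- function(s) {
    v <- utf8ToInt(as.character(s))
    acc <- 0
    for (ch in v) acc <- (acc * 131 + ch) %% 2147483629
    acc
  }
  val <- (as.numeric(master) * 2654435761 + h(site_id) * 40503 +
            h(var_id) * 2654435769 + channel * 97) %% 2147483629
  as.integer(val)
}

# Stop with a classed condition so callers/tests can distinguish validation
# failures from programming errors.
stop_msvdq <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "msvdq_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
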
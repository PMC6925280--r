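# internal assertion helpers; all user-facing errors are classed so callers
# (and the CLI) can distinguish validation/format problems from R errors

stop_classed <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "metagrs_error")))
}

stop_validation <- function(fmt, ...) stop_classed("metagrs_validation_error", fmt, ...)
stop_format <- function(fmt, ...) stop_classed("metagrs_format_error", fmt, ...)

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          open_lower = FALSE, open_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_lower) x > lower else x >= lower) &&
    (if (open_upper) x < upper else x <= upper)
  if (!ok) {
    stop_validation("`%s` must be a single finite number in %s%s, %s%s (got %s)",
                    name, if (open_lower) "(" else "[", format(lower),
                    format(upper), if (open_upper) ")" else "]",
                    paste(format(x), collapse = ","))
  }
  invisible(x)
}

assert_flag <- function(x, name) {
  if (!(is.logical(x) && length(x) == 1L && !is.na(x))) {
    stop_validation("`%s` must be TRUE or FALSE", name)
  }
  invisible(x)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_format("%s is missing required column(s): %s",
                what, paste(missing, collapse = ", "))
  }
  invisible(df)
}

# seeded evaluation that restores the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a bounded substream seed from a master seed and a stream label
#'
#' All pipeline randomness flows from one master seed via named
#' substreams; the derived value is always a valid 32-bit integer seed.
#'
#' @param seed Integer master seed.
#' @param stream Character label of the substream.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483587L)
}
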
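# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Compound identity used when merging herb catalogs: case-fold and strip
# surrounding whitespace, so the same compound listed under both herbs joins.
normalize_compound_id <- function(x) trimws(tolower(as.character(x)))

# Gene symbols are compared case-insensitively (upper case is the convention).
normalize_symbol <- function(x) toupper(trimws(as.character(x)))

stop_validation <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    stop_validation("'%s' must be a single integer >= %d (got %s)",
                    name, min, paste(format(x), collapse = ","))
  }
  as.integer(x)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop_validation("'%s' must lie in [0, 1]", name)
  }
  as.numeric(x)
}
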
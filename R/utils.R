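# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# stream.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

abort_io <- function(message, ...) {
  abort(message, class = "pathrisk_error_io", ...)
}

abort_schema <- function(message, ...) {
  abort(message, class = "pathrisk_error_schema", ...)
}

abort_closed_world <- function(message, ...) {
  abort(message, class = "pathrisk_error_closed_world", ...)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)

# Labels flow into cluster-key strings and node ids; keep them free of the
# delimiter characters those encodings reserve.
check_label <- function(x, what) {
  bad <- grepl("[|{}=,]", x)
  if (any(bad)) {
    abort_schema(sprintf(
      "%s contains reserved characters (| { } = ,): %s",
      what, paste(x[bad], collapse = ", ")
    ))
  }
  invisible(x)
}
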
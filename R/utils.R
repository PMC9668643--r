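#' @keywords internal
"_PACKAGE"

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so generators behave as pure functions of
# their arguments.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stream-specific child seed from a base seed, kept within 32-bit
# integer range.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 48271 + stream * 1009) %% 2147483647
}

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    stop_input("configuration error: '%s' must be an integer >= %d (got %s)",
               name, min, paste(format(x), collapse = ","))
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (strict_min && x <= min) || (!strict_min && x < min) || x > max) {
    stop_input("configuration error: '%s' out of range (got %s)",
               name, paste(format(x), collapse = ","))
  }
  as.numeric(x)
}

# Polynomial rolling hash (mod the Mersenne prime 2^31 - 1) of a character
# scalar; used to stamp output files with a short configuration fingerprint.
config_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\x1f")))
  h <- 0
  for (b in bytes) {
    h <- (h * 131 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

# All tabular outputs carry a comment header with seed + config fingerprint so
# runs are auditable; readers skip lines starting with '#'.
write_table_with_header <- function(df, path, header = NULL, sep = ",") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
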
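# Internal helpers shared across modules.

#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Coerce the many ways callers express a binary activity outcome (factor with
# levels containing "active"/"inactive", logical, 0/1 numeric, character) into
# an integer 0/1 vector with 1 = active (the positive class throughout).
as_binary01 <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    ok <- y %in% c("active", "inactive")
    if (!all(ok)) {
      abort(sprintf("unrecognised class label(s): %s",
                    paste(unique(y[!ok]), collapse = ", ")))
    }
    return(as.integer(y == "active"))
  }
  if (is.logical(y)) return(as.integer(y))
  if (is.numeric(y)) {
    if (!all(y %in% c(0, 1))) abort("numeric labels must be 0/1")
    return(as.integer(y))
  }
  abort("cannot interpret labels as a binary activity vector")
}

# 32-bit FNV-1a hash of a string, reduced modulo `buckets`. Arithmetic is done
# in double precision; all intermediates stay below 2^53 so the hash is exact
# and platform-independent.
fnv1a_bucket <- function(x, buckets) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor2(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  as.integer(h %% buckets) + 1L
}

# bitwXor for doubles that may exceed .Machine$integer.max: split into two
# 16-bit halves, xor each with base R's integer xor.
bitwXor2 <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  hi * 65536 + lo
}

# Deterministic child seed derived from a user seed and a stage tag; keeps the
# result inside the 32-bit signed integer range R requires.
child_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) * 48271 + fnv1a_bucket(tag, 2147483) * 977) %%
               2147483647)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
}
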
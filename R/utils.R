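# Internal helpers shared across the pipeline.

#' Derive a reproducible sub-seed from a root seed and a stream label
#'
#' Every source of randomness in the pipeline draws from its own named
#' substream so that any single group, ensemble or repeat can be reproduced
#' in isolation. The label is hashed (FNV-1a over the UTF-8 bytes) and mixed
#' with the root seed; the result is always a valid 31-bit integer seed.
#'
#' @param seed integer root seed.
#' @param ... components of the stream label (coerced to character and
#'   joined with "/"), e.g. `derive_seed(1, "groups", replicate, cell_id)`.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  label <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- 2166136261
  for (byte in utf8ToInt(label)) {
    # xor into the low byte, then 32-bit modular multiply by the FNV prime;
    # both kept exact in double precision (all intermediates < 2^41)
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), byte)
    h <- ((h %% 65536) * 16777619 +
            (((h %/% 65536) * 16777619) %% 65536) * 65536) %% 4294967296
  }
  as.integer((h + as.double(seed) * 2654435761) %% 2147483647)
}

#' @noRd
with_seed <- function(seed, code) {
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
  set.seed(seed)
  force(code)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
abort_missing_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
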
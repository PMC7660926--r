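## Small internal utilities: scoped RNG and stable seed derivation.

#' Evaluate an expression with a locally-seeded RNG
#'
#' Saves and restores `.Random.seed` so package internals never disturb the
#' caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a master seed and a run context
#'
#' Stable 31-bit polynomial string hash; reproducible across sessions and
#' platforms and safe for `set.seed()` (always in `[1, 2^31 - 2]`).
#'
#' @param master_seed integer master seed.
#' @param ... labels and indices identifying the child stream (coerced to
#'   character and concatenated).
#' @return a single integer seed.
#' @export
#' @examples
#' derive_seed(1, "delK508", 3, 1)
derive_seed <- function(master_seed, ...) {
  key <- paste(c(as.character(as.integer(master_seed)),
                 vapply(list(...), as.character, character(1))),
               collapse = "|")
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 131 + code) %% m
  as.integer(h %% (m - 2L) + 1L)
}

#' Stable 32-bit hex digest of a character scalar (polynomial rolling hash)
#' @noRd
string_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  for (code in utf8ToInt(x)) h <- (h * 131 + code) %% 2147483647
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic TSV body lines for a data.frame (fixed numeric format)
#' @noRd
tsv_body <- function(df) {
  do.call(paste, c(lapply(df, function(col) {
    if (is.numeric(col) && !is.integer(col))
      ifelse(is.na(col), "NA", formatC(col, format = "g", digits = 15))
    else as.character(col)
  }), sep = "\t"))
}

#' Write a data.frame as a byte-deterministic TSV (LF endings)
#' @noRd
write_tsv_det <- function(df, path, header_lines = character()) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(header_lines)) writeLines(header_lines, con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) writeLines(tsv_body(df), con)
  invisible(path)
}
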
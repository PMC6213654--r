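#' @keywords internal
"_PACKAGE"

#' @importFrom stats median rnbinom rmultinom rlnorm runif dhyper chisq.test
#'   setNames p.adjust
#' @importFrom utils write.table
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

# round-half-up at `digits` decimals (base round() is round-half-even)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All generators go through this so that
# simulation output is a pure function of (arguments, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# strict scalar checks used by the format readers and config validation
assert_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    stopf("%s must be a non-empty string", what)
  }
  invisible(x)
}

assert_count <- function(x, what, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    stopf("%s must be an integer >= %s", what, min)
  }
  invisible(as.integer(x))
}

#' Reverse complement on the DNA alphabet
#'
#' @param x Character vector of sequences over `{A,C,G,T,N}`.
#' @return Reverse complement(s).
#' @export
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN",
         vapply(strsplit(x, "", fixed = TRUE),
                function(ch) paste(rev(ch), collapse = ""), character(1)))
}

# tab-separated writer shared by all output tables: UTF-8, "." decimal mark,
# no quoting, no row names
write_tsv <- function(df, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
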
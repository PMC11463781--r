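# Lightweight line-oriented logging. Messages go through message() so callers
# can suppressMessages(); sinkLog() additionally appends to a file when the
# option is set (used by the pipeline runner).

.logLine <- function(...) {
  txt <- paste0(...)
  path <- getOption("crisprEssentials.log", NULL)
  if (!is.null(path)) cat(txt, "\n", file = path, append = TRUE, sep = "")
  message(txt)
  invisible(txt)
}

# Mode of a character vector with an explicit tie-break label. NA values must
# be removed by the caller. Labels are binary at every aggregation level, so a
# tie can only be an even split between the two classes.
.modeLabel <- function(x, tieBreak) {
  tab <- table(x)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1L) tieBreak else top
}

# Seeded RNG scope: evaluates expr with the given seed, restoring the caller's
# RNG state afterwards so package internals never clobber user randomness.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a stream seed from a run seed, kept inside 32-bit integer range.
.deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(offset)) %% 2147483647)
}
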
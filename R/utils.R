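# Internal helpers shared across modules.

# log(sum(exp(x))) without overflow; x may contain -Inf.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

stop_sigreverse <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "sigreverse_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == trunc(x)
}

# Read non-blank, non-comment ('#') lines from a text file.
read_clean_lines <- function(path) {
  if (!file.exists(path)) {
    stop_sigreverse(sprintf("cannot read '%s': no such file", path), "sigreverse_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

# Pick one element; safe for length-1 vectors (unlike sample()).
sample1 <- function(x) x[sample.int(length(x), 1L)]

# Run expr with a private RNG stream seeded by `seed`, restoring the caller's
# RNG state afterwards, so generators are deterministic without clobbering
# the session RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
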
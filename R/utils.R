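#' @keywords internal
"_PACKAGE"

# Deterministic derivation of per-stage seeds from one master seed.
# Keeps results below 2^31 so they remain valid R integers.
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(master) * 69621 + h * 1013) %% 2147483629L)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is left untouched.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed %% 2147483629))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x > 0 && x == floor(x)
}

is_fraction <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

# Read a whitespace/tab-delimited interval file (BED-like). Returns a
# data.frame with the first `ncol` columns named as requested. Malformed
# lines are reported via warning and skipped.
read_intervals <- function(path, col_names, numeric_cols = c(2L, 3L)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), "#")]
  if (length(lines) == 0L)
    return(stats::setNames(
      as.data.frame(rep(list(character(0)), length(col_names))), col_names))
  parts <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(parts)
  bad <- nf < length(col_names)
  if (any(bad)) {
    warning(sprintf("%d malformed line(s) skipped in %s", sum(bad), path))
    parts <- parts[!bad]
  }
  if (length(parts) == 0L)
    return(stats::setNames(
      as.data.frame(rep(list(character(0)), length(col_names))), col_names))
  m <- do.call(rbind, lapply(parts, `[`, seq_along(col_names)))
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- col_names
  for (j in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (anyNA(v)) {
      warning(sprintf("%d line(s) with non-numeric field %d skipped in %s",
                      sum(is.na(v)), j, path))
      df <- df[!is.na(v), , drop = FALSE]
      v <- v[!is.na(v)]
      # re-coerce earlier numeric columns after row drop
      for (jj in numeric_cols[numeric_cols < j])
        df[[jj]] <- as.numeric(df[[jj]])
    }
    df[[j]] <- suppressWarnings(as.numeric(df[[j]]))
  }
  rownames(df) <- NULL
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}
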
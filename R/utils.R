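# Internal helpers shared across modules.

# Classed validation failures so callers can distinguish error causes.
lnc_abort <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "lncnet_error", "error", "condition")))
}

lnc_warn <- function(msg, ...) warning(sprintf(msg, ...), call. = FALSE)

# Evaluate `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so generation is a pure function of the seed.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Format numbers for TSV output: 15 significant digits, locale-independent.
fmt_num <- function(x) {
  out <- sprintf("%.15g", x)
  out[is.na(x)] <- "NA"
  out
}

# Deterministic TSV writer (no quoting surprises, LF endings).
write_tsv <- function(df, path, comment_lines = character()) {
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comment_lines))
    writeLines(paste0("# ", comment_lines), con, sep = "\n")
  is_num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[is_num] <- lapply(df[is_num], fmt_num)
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df)) do.call(paste, c(unname(df), sep = "\t")))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

read_tsv_checked <- function(path, required_cols) {
  if (!file.exists(path))
    lnc_abort("lncnet_io_error", "file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(required_cols, names(df))
  if (length(miss))
    lnc_abort("lncnet_io_error", "%s: missing column(s): %s",
              path, paste(miss, collapse = ", "))
  df
}

# Leading "# key=value" metadata lines of a file.
read_meta_lines <- function(path) {
  con <- file(path, open = "r", encoding = "UTF-8")
  on.exit(close(con))
  meta <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln) || !startsWith(ln, "#")) break
    meta <- c(meta, sub("^#\\s*", "", ln))
  }
  kv <- strsplit(meta, "=", fixed = TRUE)
  stats::setNames(vapply(kv, function(x) trimws(paste(x[-1], collapse = "=")),
                         character(1)),
                  vapply(kv, function(x) trimws(x[[1]]), character(1)))
}
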
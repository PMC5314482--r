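#' @importFrom rlang abort warn %||%
#' @import tibble
NULL

# Classed condition helper: every domain error carries a subclass so callers
# (and the CLI) can map it to an exit code without parsing messages.
stop_repo <- function(class, message, ...) {
  abort(message, class = c(paste0("datarepo_", class), "datarepo_error"), ...)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

assert_string <- function(x, what, allow_empty = FALSE) {
  if (!is_string(x) || (!allow_empty && !nzchar(x))) {
    stop_repo("bad_argument", sprintf("`%s` must be a non-empty string", what))
  }
  invisible(x)
}

# ISO-8601 UTC, second resolution; index equality ignores sub-second anyway.
utc_now <- function() {
  format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

md5_file <- function(path) {
  unname(tools::md5sum(path))
}

md5_text <- function(text) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(charToRaw(text), tmp)
  md5_file(tmp)
}

# Filenames under data/ are derived from item names; the index's payload_path
# stays authoritative. `#` is deliberately unrepresentable here so version
# suffixes can never collide with a sanitized user name.
sanitize_name <- function(name) {
  s <- gsub("[^A-Za-z0-9._-]", "_", name)
  if (!nzchar(s)) s <- "item"
  s
}

# Atomic file replacement: write to a sibling temp file, then rename.
write_file_atomic <- function(bytes, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  con <- file(tmp, "wb")
  ok <- FALSE
  tryCatch({
    writeBin(bytes, con)
    close(con)
    ok <- TRUE
  }, error = function(e) {
    try(close(con), silent = TRUE)
    unlink(tmp)
    stop_repo("io", sprintf("failed to write '%s': %s", path, conditionMessage(e)))
  })
  if (ok && !file.rename(tmp, path)) {
    unlink(tmp)
    stop_repo("io", sprintf("failed to replace '%s'", path))
  }
  invisible(path)
}

read_file_bytes <- function(path) {
  readBin(path, what = "raw", n = file.info(path)$size)
}
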
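#' Copy items between repositories
#'
#' Payload bytes are copied verbatim (checksums are preserved) and metadata
#' is copied with the payload path re-rooted into the destination's `data/`
#' directory. Relations are copied as-is; references to items not copied
#' will show up as dangling in the destination's provenance graph rather
#' than being dropped.
#'
#' @param src,dest Repository handles.
#' @param names Items to copy.
#' @param replace Collision policy in the destination (`"forbid"` default;
#'   `"overwrite"` replaces). Under `"forbid"` a collision aborts before
#'   anything is copied.
#' @return Number of items copied, invisibly.
#' @export
repo_copy <- function(src, dest, names, replace = c("forbid", "overwrite")) {
  check_repo(src)
  check_repo(dest)
  replace <- match.arg(replace)
  for (nm in names) check_exists(src, nm)
  if (identical(replace, "forbid")) {
    clash <- names[vapply(names, repo_has, TRUE, repo = dest)]
    if (length(clash)) {
      stop_repo("collision",
                sprintf("item%s already in destination: %s",
                        if (length(clash) == 1) "" else "s",
                        paste(clash, collapse = ", ")))
    }
  }
  for (nm in names) {
    rec <- get_record(src, nm)
    src_path <- payload_abspath(src, rec)
    if (!file.exists(src_path)) {
      stop_repo("integrity", sprintf("payload for '%s' is missing in source", nm))
    }
    if (repo_has(dest, nm)) {
      new_path <- dest$items[[nm]]$payload_path
    } else {
      ext <- if (identical(rec$serializer, "file")) "" else ".bin"
      new_path <- alloc_payload_path(dest, nm, ext)
    }
    write_file_atomic(read_file_bytes(src_path), file.path(dest$root, new_path))
    rec$payload_path <- new_path
    dest$items[[nm]] <- rec
  }
  persist_index(dest)
  dangling <- repo_graph(dest)$dangling
  if (nrow(dangling)) {
    warn(sprintf("destination has %d dangling reference%s (e.g. %s -> %s)",
                 nrow(dangling), if (nrow(dangling) == 1) "" else "s",
                 dangling$from[1], dangling$missing[1]))
  }
  invisible(length(names))
}

#' Export item contents to plain files
#'
#' Writes one file per item into `dest_dir`: values in the repository's
#' serialized form (extension `.bin`), attachments in their original format
#' under their original name. Combine with [repo_related()] to export a
#' self-contained set.
#'
#' @param repo A repository handle.
#' @param names Items to export.
#' @param dest_dir Destination directory (created if absent).
#' @return Character vector of written file paths, named by item.
#' @export
repo_export <- function(repo, names, dest_dir) {
  check_repo(repo)
  for (nm in names) check_exists(repo, nm)
  if (!dir.exists(dest_dir) && !dir.create(dest_dir, recursive = TRUE)) {
    stop_repo("io", sprintf("cannot create directory '%s'", dest_dir))
  }
  out <- character(length(names))
  for (i in seq_along(names)) {
    rec <- get_record(repo, names[i])
    src <- payload_abspath(repo, rec)
    if (!file.exists(src)) {
      stop_repo("integrity", sprintf("payload for '%s' is missing", names[i]))
    }
    fname <- if (identical(rec$serializer, "file")) {
      basename(rec$payload_path)
    } else {
      paste0(sanitize_name(rec$name), ".bin")
    }
    dst <- file.path(dest_dir, fname)
    write_file_atomic(read_file_bytes(src), dst)
    out[i] <- dst
  }
  names(out) <- names
  out
}

#' Assign download URLs from a base URL
#'
#' Prepares a repository for distribution: each selected item's `url` is set
#' to `base_url` + `/` + its URL-encoded payload filename, so the repository
#' directory can be published as-is and the index alone distributed — items
#' are then retrievable with [repo_pull()].
#'
#' @param repo A repository handle.
#' @param names Items to annotate; defaults to every item.
#' @param base_url Base URL (trailing slash optional).
#' @param exclude Item names to leave untouched (they keep any prior URL).
#' @return Number of items updated, invisibly.
#' @export
repo_set_base_url <- function(repo, base_url, names = NULL,
                              exclude = character()) {
  check_repo(repo)
  assert_string(base_url, "base_url")
  names <- names %||% names(repo$items) %||% character()
  for (nm in names) check_exists(repo, nm)
  base <- sub("/+$", "", base_url)
  updated <- 0L
  for (nm in setdiff(names, exclude)) {
    rec <- repo$items[[nm]]
    rec$url <- paste0(base, "/", utils::URLencode(basename(rec$payload_path),
                                                  reserved = TRUE))
    rec$modified_at <- utc_now()
    set_record(repo, rec)
    updated <- updated + 1L
  }
  if (updated > 0) persist_index(repo)
  invisible(updated)
}

#' Refresh an item's payload from its URL
#'
#' Downloads the item's content from its `url` annotation and replaces the
#' payload, recomputing checksum and size (the previous checksum is
#' reported). With `verify = TRUE` the fetched bytes must instead match the
#' stored checksum — the distribution use-case, where the index is shared
#' and payloads are pulled to fill it in. A failed fetch leaves payload and
#' record untouched.
#'
#' @param repo A repository handle.
#' @param name Item with a `url` annotation.
#' @param fetcher A `function(url)` returning raw bytes. The default uses
#'   base R connections; tests inject a mock so nothing touches the network.
#' @param verify Require the fetched bytes to match the stored checksum?
#' @return The updated record, invisibly.
#' @export
repo_pull <- function(repo, name, fetcher = default_fetcher, verify = FALSE) {
  check_repo(repo)
  rec <- get_record(repo, name)
  if (is.null(rec$url)) {
    stop_repo("no_url", sprintf("item '%s' has no url annotated", name))
  }
  bytes <- tryCatch(fetcher(rec$url), error = function(e) {
    stop_repo("fetch", sprintf("failed to fetch '%s': %s", rec$url, conditionMessage(e)))
  })
  if (!is.raw(bytes)) {
    stop_repo("fetch", sprintf("fetcher for '%s' did not return raw bytes", rec$url))
  }
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(bytes, tmp)
  new_sum <- md5_file(tmp)
  if (verify && !identical(new_sum, rec$checksum)) {
    stop_repo("integrity",
              sprintf("pulled content for '%s' does not match stored MD5 (expected %s, got %s)",
                      name, rec$checksum, new_sum))
  }
  old_sum <- rec$checksum
  write_file_atomic(bytes, payload_abspath(repo, rec))
  rec$checksum <- new_sum
  rec$size_bytes <- as.double(length(bytes))
  rec$modified_at <- utc_now()
  set_record(repo, rec)
  persist_index(repo)
  if (!identical(old_sum, new_sum)) {
    message(sprintf("'%s': payload replaced (MD5 %s -> %s)", name, old_sum, new_sum))
  }
  invisible(rec)
}

default_fetcher <- function(url) {
  con <- url(url, "rb")
  on.exit(close(con))
  out <- raw()
  repeat {
    chunk <- readBin(con, what = "raw", n = 65536L)
    if (length(chunk) == 0) break
    out <- c(out, chunk)
  }
  out
}

#' Check the MD5 consistency of every stored item
#'
#' Recomputes each payload's MD5 and compares it with the index. Problems
#' are data, not errors: the result lists, per item, `"ok"`, `"missing"`
#' (payload file absent — e.g. an index shared without its payloads) or
#' `"mismatch"` (content differs from the recorded checksum).
#'
#' @param repo A repository handle.
#' @return A tibble with columns `name` and `status`.
#' @export
repo_check <- function(repo) {
  check_repo(repo)
  status <- vapply(repo$items, function(rec) {
    path <- payload_abspath(repo, rec)
    if (!file.exists(path)) return("missing")
    if (!identical(md5_file(path), rec$checksum)) return("mismatch")
    "ok"
  }, "", USE.NAMES = FALSE)
  tibble::tibble(name = names(repo$items) %||% character(), status = status)
}
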
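#' Store a value in the repository
#'
#' Replaces a bare `saveRDS()` with an annotated store: the value is
#' serialized under `data/`, its MD5 checksum, size and dimensions recorded,
#' and the record appended to the single index file. A non-empty description
#' and at least one tag are mandatory — annotations, not directory layout,
#' are how items are found again.
#'
#' Replacement policies when `name` already exists:
#' * `"forbid"` (default): error, nothing changes.
#' * `"overwrite"`: the record keeps its identity (creation date, payload
#'   file); payload, checksum, size and annotations are rewritten.
#' * `"addversion"`: the existing item is preserved under `name#N` (smallest
#'   free N), flagged `versioned` and `hidden`; the new value becomes the
#'   current `name`. `#` cannot occur in sanitized payload filenames, so
#'   version names never collide with user names on disk.
#'
#' @param repo A repository handle.
#' @param value Any serializable R value.
#' @param name Unique item name within the repository.
#' @param description Free-text description (mandatory, non-empty).
#' @param tags Character vector of tags (mandatory, at least one).
#' @param depends Names of items this item depends on (must exist).
#' @param source Name of the stored source-file item that generates this item
#'   (default: the session default set by [repo_options()]).
#' @param project Name of the project item this item belongs to (default: the
#'   session default).
#' @param url Optional provenance/download URL.
#' @param replace Replacement policy; default is the session default
#'   (initially `"forbid"`).
#' @return The new item record, invisibly.
#' @examples
#' rp <- repo_init(tempfile("repo"))
#' repo_put(rp, iris, "iris", "Fisher's iris measurements", tags = "dataset")
#' head(repo_get(rp, "iris"))
#' @export
repo_put <- function(repo, value, name, description, tags,
                     depends = character(), source = NULL, project = NULL,
                     url = NULL, replace = NULL) {
  check_repo(repo)
  assert_string(name, "name")
  assert_annotations(description, tags)
  source <- source %||% repo$options$default_source
  project <- project %||% repo$options$default_project
  replace <- match.arg(replace %||% repo$options$replace,
                       c("forbid", "overwrite", "addversion"))
  check_relations(repo, name, depends, source, attached_to = NULL, project = project)

  # serialize first: a failing serializer must leave the index untouched
  bytes <- serialize(value, NULL)
  store_payload_record(
    repo, bytes,
    name = name, description = description, tags = tags,
    depends = depends, source = source, project = project, url = url,
    kind_flags = character(), dims = value_dims(value),
    serializer = "rds", ext = ".bin", replace = replace
  )
}

#' Store a generic file as an attachment
#'
#' Copies the file's bytes verbatim into the repository. Attachments hold
#' data in its original format (figures, spreadsheets, source files) and are
#' hidden from default listings; `to` links the attachment to the item it
#' belongs with (e.g. a plot to the data it depicts — attachments can chain
#' to other attachments).
#'
#' @param repo A repository handle.
#' @param path Readable file to store.
#' @param description,tags Mandatory annotations, as in [repo_put()].
#' @param to Optional name of the item this file is attached to.
#' @param name Item name; defaults to the file's base name.
#' @inheritParams repo_put
#' @return The new item record, invisibly.
#' @export
repo_attach <- function(repo, path, description, tags, to = NULL,
                        name = basename(path), source = NULL, project = NULL,
                        url = NULL, replace = NULL) {
  check_repo(repo)
  if (!is_string(path) || !file.exists(path)) {
    stop_repo("io", sprintf("cannot read file '%s'", path))
  }
  assert_string(name, "name")
  assert_annotations(description, tags)
  source <- source %||% repo$options$default_source
  project <- project %||% repo$options$default_project
  replace <- match.arg(replace %||% repo$options$replace,
                       c("forbid", "overwrite", "addversion"))
  check_relations(repo, name, character(), source, attached_to = to, project = project)

  store_payload_record(
    repo, read_file_bytes(path),
    name = name, description = description, tags = tags,
    depends = character(), source = source, project = project, url = url,
    attached_to = to, kind_flags = c("attachment", "hidden"), dims = integer(),
    serializer = "file", ext = "", replace = replace
  )
}

#' Retrieve an item's value
#'
#' Loads and deserializes the payload. For attachments the raw bytes are
#' returned. The payload's MD5 is verified against the index before
#' deserialization; a missing or tampered payload raises an integrity error
#' stating expected and actual digests.
#'
#' @param repo A repository handle.
#' @param name Item name (versioned names like `"a#1"` work too).
#' @return The stored value (raw vector for attachments).
#' @export
repo_get <- function(repo, name) {
  check_repo(repo)
  rec <- get_record(repo, name)
  path <- payload_abspath(repo, rec)
  if (!file.exists(path)) {
    stop_repo("integrity",
              sprintf("payload for '%s' is missing (expected at %s)", name, rec$payload_path))
  }
  actual <- md5_file(path)
  if (!identical(actual, rec$checksum)) {
    stop_repo("integrity",
              sprintf("payload for '%s' fails its integrity check (expected MD5 %s, got %s)",
                      name, rec$checksum, actual))
  }
  read_payload(path, rec$serializer)
}

#' Update an existing item's annotations (or payload)
#'
#' Only the supplied fields change. Passing `NA` clears an optional field
#' (`source`, `attached_to`, `project`, `url`). Supplying `value` rewrites
#' the payload through the item's serializer. `modified_at` is refreshed and
#' the index persisted.
#'
#' @param repo A repository handle.
#' @param name Item to update.
#' @param description,tags,depends,source,attached_to,project,url New values
#'   for the corresponding annotation fields; omitted fields are untouched.
#' @param value If given, a new payload value.
#' @return The updated record, invisibly.
#' @export
repo_set <- function(repo, name, description = NULL, tags = NULL,
                     depends = NULL, source = NULL, attached_to = NULL,
                     project = NULL, url = NULL, value) {
  check_repo(repo)
  rec <- get_record(repo, name)
  clear_or <- function(new, old) {
    if (is.null(new)) old
    else if (length(new) == 1 && is.na(new)) NULL
    else new
  }
  if (!is.null(description)) {
    assert_string(description, "description")
    rec$description <- description
  }
  if (!is.null(tags)) {
    if (!rec_has_flag(rec, "stash")) assert_tags(tags)
    rec$tags <- unique(as.character(tags))
  }
  if (!is.null(depends)) {
    if (length(depends) == 1 && all(is.na(depends))) depends <- character()
    rec$depends <- as.character(depends)
  }
  rec$source <- clear_or(source, rec$source)
  rec$attached_to <- clear_or(attached_to, rec$attached_to)
  rec$project <- clear_or(project, rec$project)
  rec$url <- clear_or(url, rec$url)
  check_relations(repo, name, rec$depends, rec$source,
                  attached_to = rec$attached_to, project = rec$project)
  if (!missing(value)) {
    bytes <- if (identical(rec$serializer, "file")) {
      if (!is.raw(value)) stop_repo("bad_argument", "attachment payloads are raw bytes")
      value
    } else {
      serialize(value, NULL)
    }
    write_file_atomic(bytes, payload_abspath(repo, rec))
    rec$checksum <- md5_file(payload_abspath(repo, rec))
    rec$size_bytes <- as.double(length(bytes))
    rec$dims <- if (identical(rec$serializer, "file")) integer() else value_dims(value)
  }
  rec$modified_at <- utc_now()
  set_record(repo, rec)
  persist_index(repo)
  invisible(rec)
}

#' Remove an item
#'
#' Deletes the record from the index and the payload file from disk. Items
#' that referred to the removed name keep their references; graph
#' construction reports them as dangling rather than dropping them silently.
#'
#' @param repo A repository handle.
#' @param name Item to remove.
#' @export
repo_rm <- function(repo, name) {
  check_repo(repo)
  rec <- get_record(repo, name)
  path <- payload_abspath(repo, rec)
  if (file.exists(path)) unlink(path)
  repo$items[[name]] <- NULL
  persist_index(repo)
  invisible(NULL)
}

#' Quick storage with unspecified metadata
#'
#' `repo_stash()` stores a value with an auto-generated description, no tags
#' and the `stash` + `hidden` flags — for intermediates worth keeping but not
#' worth annotating. `repo_stash_clear()` removes all stash items at once.
#'
#' @param repo A repository handle.
#' @param value Value to store.
#' @param name Item name. Overwriting a previous stash of the same name is
#'   allowed; colliding with a regular item is an error.
#' @return The record (stash) / the number of items removed (stash_clear).
#' @export
repo_stash <- function(repo, value, name) {
  check_repo(repo)
  assert_string(name, "name")
  if (repo_has(repo, name) && !rec_has_flag(repo$items[[name]], "stash")) {
    stop_repo("collision",
              sprintf("'%s' exists and is not a stash item", name))
  }
  bytes <- serialize(value, NULL)
  store_payload_record(
    repo, bytes,
    name = name, description = "stashed item (no metadata)", tags = character(),
    depends = character(), source = NULL, project = NULL, url = NULL,
    kind_flags = c("stash", "hidden"), dims = value_dims(value),
    serializer = "rds", ext = ".bin", replace = "overwrite",
    skip_annotation_check = TRUE
  )
}

#' @rdname repo_stash
#' @export
repo_stash_clear <- function(repo) {
  check_repo(repo)
  stashed <- names(repo$items)[vapply(repo$items, rec_has_flag, TRUE, "stash")]
  for (nm in stashed) {
    path <- payload_abspath(repo, repo$items[[nm]])
    if (file.exists(path)) unlink(path)
    repo$items[[nm]] <- NULL
  }
  persist_index(repo)
  length(stashed)
}

#' Summarize an item, a project, or the whole repository
#'
#' Without `name`, reports the repository root, item count and total payload
#' size. For a regular item, reports all its annotations plus payload
#' details: dimensions, creation date, size, relative payload path and MD5
#' checksum. For a project item, additionally lists the member items, the R
#' version and the libraries captured when the project was created.
#'
#' @param repo A repository handle.
#' @param name Optional item name.
#' @return A report object with a `print()` method; fields are accessible as
#'   a list.
#' @export
repo_info <- function(repo, name = NULL) {
  check_repo(repo)
  if (is.null(name)) {
    out <- list(
      root = repo$root,
      n_items = length(repo$items),
      total_bytes = sum(vapply(repo$items, `[[`, 0, "size_bytes"))
    )
    return(structure(out, class = "repo_info"))
  }
  rec <- get_record(repo, name)
  out <- rec
  if (rec_has_flag(rec, "project")) {
    members <- names(repo$items)[vapply(repo$items, function(r) {
      identical(r$project, name)
    }, TRUE)]
    payload <- tryCatch(repo_get(repo, name), error = function(e) NULL)
    out$members <- members
    out$rversion <- payload$rversion
    out$libraries <- payload$libraries
  }
  structure(out, class = "repo_item_info")
}

#' @export
print.repo_info <- function(x, ...) {
  cat(sprintf("Repository: %s\n  items: %d\n  total size: %s\n",
              x$root, x$n_items, format_bytes(x$total_bytes)))
  invisible(x)
}

#' @export
print.repo_item_info <- function(x, ...) {
  field <- function(label, value) {
    if (length(value) && !is.null(value)) {
      cat(sprintf("  %-12s %s\n", paste0(label, ":"), paste(value, collapse = ", ")))
    }
  }
  cat(sprintf("%s\n", x$name))
  field("description", x$description)
  field("tags", x$tags)
  field("dimensions", x$dims)
  field("created", x$created_at)
  field("size", format_bytes(x$size_bytes))
  field("path", x$payload_path)
  field("MD5", x$checksum)
  field("depends", x$depends)
  field("source", x$source)
  field("attached to", x$attached_to)
  field("project", x$project)
  field("URL", x$url)
  field("flags", x$kind_flags)
  if (!is.null(x$members)) {
    field("members", x$members)
    field("R version", x$rversion)
    field("libraries", x$libraries)
  }
  invisible(x)
}

#' Per-item disk usage
#'
#' One row per indexed item with its payload size and fraction of the total,
#' sorted by decreasing size — the tabular equivalent of a disk-usage pie
#' chart (see [autoplot.repo_stats()]).
#'
#' @param repo A repository handle.
#' @return A tibble with columns `name`, `size_bytes`, `fraction`.
#' @export
repo_stats <- function(repo) {
  check_repo(repo)
  out <- tibble::tibble(
    name = names(repo$items) %||% character(),
    size_bytes = vapply(repo$items, `[[`, 0, "size_bytes", USE.NAMES = FALSE)
  )
  if (nrow(out) == 0) {
    out <- tibble::add_column(out, fraction = double())
  } else {
    out$fraction <- out$size_bytes / sum(out$size_bytes)
    out <- dplyr::arrange(out, dplyr::desc(.data$size_bytes))
  }
  class(out) <- c("repo_stats", class(out))
  out
}

#' Create a project item
#'
#' A project item collects pipeline-wise information: its payload captures
#' the running R version and the currently loaded libraries, and member
#' items are resolved at query time from their `project` annotation (set
#' per-call or via [repo_options()]).
#'
#' @param repo A repository handle.
#' @param name Project item name (must be unused).
#' @param description Mandatory description.
#' @param tags Tags; defaults to `"project"`.
#' @return The new record, invisibly.
#' @export
repo_project <- function(repo, name, description, tags = "project") {
  check_repo(repo)
  assert_string(name, "name")
  if (repo_has(repo, name)) {
    stop_repo("collision", sprintf("item '%s' already exists", name))
  }
  assert_annotations(description, tags)
  payload <- list(rversion = R.version.string,
                  libraries = sort(loadedNamespaces()))
  bytes <- serialize(payload, NULL)
  store_payload_record(
    repo, bytes,
    name = name, description = description, tags = tags,
    depends = character(), source = NULL, project = NULL, url = NULL,
    kind_flags = "project", dims = integer(),
    serializer = "rds", ext = ".bin", replace = "forbid"
  )
}

# --- internals --------------------------------------------------------------

assert_tags <- function(tags) {
  if (!is.character(tags) || length(tags) == 0 || any(!nzchar(tags)) || anyNA(tags)) {
    stop_repo("bad_argument", "`tags` must be a character vector with at least one non-empty tag")
  }
  invisible(tags)
}

assert_annotations <- function(description, tags) {
  assert_string(description, "description")
  assert_tags(tags)
}

# Relation hygiene shared by put/attach/set: referenced items must exist now,
# self-dependencies and duplicated depends entries are rejected outright.
check_relations <- function(repo, name, depends, source, attached_to, project) {
  if (anyDuplicated(depends)) {
    stop_repo("bad_argument",
              sprintf("duplicate names in `depends` for '%s'", name))
  }
  if (name %in% depends) {
    stop_repo("bad_argument", sprintf("'%s' cannot depend on itself", name))
  }
  for (dep in depends) check_exists(repo, dep, "item in `depends`")
  if (!is.null(source)) {
    if (identical(source, name)) {
      stop_repo("bad_argument", sprintf("'%s' cannot be its own source", name))
    }
    check_exists(repo, source, "`source` item")
  }
  if (!is.null(attached_to)) {
    if (identical(attached_to, name)) {
      stop_repo("bad_argument", sprintf("'%s' cannot be attached to itself", name))
    }
    check_exists(repo, attached_to, "`to` item")
  }
  if (!is.null(project)) check_exists(repo, project, "`project` item")
  invisible(NULL)
}

# Smallest positive version number not yet used for `name`.
next_version_number <- function(repo, name) {
  n <- 1L
  while (paste0(name, "#", n) %in% names(repo$items)) n <- n + 1L
  n
}

# Shared tail of put/attach/stash/project: handles the replacement policy,
# writes the payload, builds the record and persists the index. `bytes` must
# already be fully materialized so that failures cannot tear the index.
store_payload_record <- function(repo, bytes, name, description, tags,
                                 depends, source, project, url,
                                 kind_flags, dims, serializer, ext,
                                 replace, attached_to = NULL,
                                 skip_annotation_check = FALSE) {
  existing <- if (repo_has(repo, name)) repo$items[[name]] else NULL
  if (!is.null(existing) && identical(replace, "forbid")) {
    stop_repo("collision",
              sprintf("item '%s' already exists (replace is 'forbid')", name))
  }

  now <- utc_now()
  if (!is.null(existing) && identical(replace, "overwrite")) {
    payload_path <- existing$payload_path
    created_at <- existing$created_at
  } else {
    if (!is.null(existing) && identical(replace, "addversion")) {
      n <- next_version_number(repo, name)
      vname <- paste0(name, "#", n)
      old <- existing
      old$name <- vname
      old$kind_flags <- unique(c(old$kind_flags, "versioned", "hidden"))
      old$version_of <- list(base = name, n = n)
      # re-key: superseded record takes the versioned name, slot freed
      repo$items[[name]] <- NULL
      repo$items[[vname]] <- old
    }
    payload_path <- alloc_payload_path(repo, name, ext)
    created_at <- now
  }

  abspath <- file.path(repo$root, payload_path)
  write_file_atomic(bytes, abspath)
  rec <- new_record(
    name = name,
    description = description,
    tags = if (skip_annotation_check) as.character(tags) else tags,
    payload_path = payload_path,
    checksum = md5_file(abspath),
    size_bytes = length(bytes),
    dims = dims,
    created_at = created_at,
    modified_at = now,
    source = source,
    depends = depends,
    attached_to = attached_to,
    project = project,
    url = url,
    kind_flags = kind_flags,
    serializer = serializer
  )
  # drop + re-add so overwrite keeps position only if it already existed
  if (!is.null(existing) && identical(replace, "overwrite")) {
    repo$items[[name]] <- rec
  } else {
    repo$items[[name]] <- NULL
    repo$items[[name]] <- rec
  }
  persist_index(repo)
  invisible(rec)
}

read_payload <- function(path, serializer) {
  switch(serializer,
    rds = unserialize(read_file_bytes(path)),
    file = read_file_bytes(path),
    stop_repo("format", sprintf("unknown serializer '%s'", serializer))
  )
}
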
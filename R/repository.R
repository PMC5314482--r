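#' Create a new, empty repository
#'
#' A repository is a self-contained directory: payload files under `data/`
#' and all metadata in a single index file (`repo_index.json`) at the root.
#' Every path stored in the index is relative to the root, so the directory
#' can be moved, cloned or published without rewriting anything.
#'
#' @param root Directory path. Created if absent; must not already contain a
#'   repository index.
#' @return A repository handle (an environment of class `"repo"`).
#' @examples
#' rp <- repo_init(tempfile("repo"))
#' repo_list(rp)
#' @seealso [repo_open()], [repo_put()], [repo_list()]
#' @export
repo_init <- function(root) {
  assert_string(root, "root")
  if (file.exists(file.path(root, INDEX_FILENAME))) {
    stop_repo("already_repository",
              sprintf("'%s' is already a repository (index file present)", root))
  }
  if (!dir.exists(root) && !dir.create(root, recursive = TRUE)) {
    stop_repo("io", sprintf("cannot create directory '%s'", root))
  }
  dir.create(file.path(root, "data"), showWarnings = FALSE)
  handle <- new_handle(normalizePath(root), items = list())
  persist_index(handle)
  handle
}

#' Open an existing repository
#'
#' Loads the index; payload files are not touched until an item is actually
#' retrieved (lazy payload access).
#'
#' @param root Directory containing a repository index.
#' @return A repository handle.
#' @export
repo_open <- function(root) {
  assert_string(root, "root")
  idx_path <- file.path(root, INDEX_FILENAME)
  if (!file.exists(idx_path)) {
    stop_repo("not_repository", sprintf("'%s' is not a repository (no index file)", root))
  }
  items <- deserialize_index(read_file_bytes(idx_path))
  new_handle(normalizePath(root), items = items)
}

new_handle <- function(root, items) {
  h <- new.env(parent = emptyenv())
  h$root <- root
  h$items <- items
  h$options <- list(replace = "forbid", default_source = NULL, default_project = NULL)
  class(h) <- "repo"
  h
}

#' Repository root path
#'
#' @param repo A repository handle.
#' @return Absolute path of the repository root as opened.
#' @export
repo_root <- function(repo) {
  check_repo(repo)
  repo$root
}

#' Is an item present?
#'
#' Looks up a name in the index, including hidden and versioned items.
#'
#' @param repo A repository handle.
#' @param name Item name.
#' @export
repo_has <- function(repo, name) {
  check_repo(repo)
  is_string(name) && name %in% names(repo$items)
}

#' Session defaults for subsequent stores
#'
#' Sets defaults applied by [repo_put()] and [repo_attach()] when the
#' corresponding argument is not given: the replacement policy and the
#' default `source` / `project` relations. Mirrors the usual workflow of
#' annotating a whole analysis session against one source file and one
#' project item.
#'
#' @param repo A repository handle.
#' @param replace One of `"forbid"` (default), `"overwrite"`, `"addversion"`.
#' @param default_source,default_project Item names, or `NA` to clear.
#' @return The handle, invisibly.
#' @export
repo_options <- function(repo, replace = NULL, default_source = NULL,
                         default_project = NULL) {
  check_repo(repo)
  if (!is.null(replace)) {
    repo$options$replace <- match.arg(replace, c("forbid", "overwrite", "addversion"))
  }
  for (f in c("default_source", "default_project")) {
    v <- get(f)
    if (!is.null(v)) {
      if (is_string(v)) {
        check_exists(repo, v)
        repo$options[[f]] <- v
      } else {
        repo$options[[f]] <- NULL
      }
    }
  }
  invisible(repo)
}

#' @export
print.repo <- function(x, ...) {
  n <- length(x$items)
  total <- sum(vapply(x$items, `[[`, 0, "size_bytes"))
  cat(sprintf("<repository> %s\n  %d item%s, %s\n",
              x$root, n, if (n == 1) "" else "s", format_bytes(total)))
  invisible(x)
}

format_bytes <- function(b) {
  units <- c("B", "kB", "MB", "GB")
  i <- 1L
  while (b >= 1024 && i < length(units)) {
    b <- b / 1024
    i <- i + 1L
  }
  sprintf(if (i == 1L) "%.0f %s" else "%.1f %s", b, units[i])
}

# --- internal accessors -----------------------------------------------------

check_repo <- function(repo) {
  if (!inherits(repo, "repo")) {
    stop_repo("bad_argument", "`repo` must be a repository handle (see repo_init/repo_open)")
  }
  invisible(repo)
}

check_exists <- function(repo, name, what = "item") {
  if (!is_string(name) || !name %in% names(repo$items)) {
    stop_repo("unknown_item", sprintf("unknown %s: '%s'", what, name))
  }
  invisible(name)
}

get_record <- function(repo, name) {
  check_exists(repo, name)
  repo$items[[name]]
}

set_record <- function(repo, rec) {
  repo$items[[rec$name]] <- rec
  invisible(rec)
}

payload_abspath <- function(repo, rec) {
  file.path(repo$root, rec$payload_path)
}

# Index writes are atomic (temp file + rename) so a failed store never leaves
# a torn index behind.
persist_index <- function(repo) {
  write_file_atomic(serialize_index(repo$items),
                    file.path(repo$root, INDEX_FILENAME))
  invisible(repo)
}

# Fresh payload filename under data/: sanitized item name (+ extension) with
# a numeric suffix if the natural name is taken.
alloc_payload_path <- function(repo, name, ext = ".bin") {
  base <- sanitize_name(name)
  # attachments keep their original extension inside `name` itself
  candidate <- paste0(base, ext)
  in_use <- vapply(repo$items, `[[`, "", "payload_path")
  k <- 0L
  repeat {
    rel <- file.path("data", candidate)
    if (!rel %in% in_use && !file.exists(file.path(repo$root, rel))) {
      return(rel)
    }
    k <- k + 1L
    candidate <- paste0(base, "-", k, ext)
  }
}
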
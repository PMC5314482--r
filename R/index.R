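INDEX_FILENAME <- "repo_index.json"
INDEX_FORMAT_VERSION <- 1L

# --- JSON mapping -----------------------------------------------------------
# Scalars are unboxed explicitly and vectors kept as arrays, so the on-disk
# schema is stable regardless of length-1 coincidences. Optional scalar
# fields are omitted when NULL.

record_to_jsonable <- function(rec) {
  ub <- jsonlite::unbox
  out <- list(
    name = ub(rec$name),
    description = ub(rec$description),
    tags = as.character(rec$tags),
    payload_path = ub(rec$payload_path),
    checksum = ub(rec$checksum),
    size_bytes = ub(rec$size_bytes),
    dims = as.integer(rec$dims),
    created_at = ub(rec$created_at),
    modified_at = ub(rec$modified_at),
    depends = as.character(rec$depends),
    kind_flags = as.character(rec$kind_flags),
    serializer = ub(rec$serializer)
  )
  for (f in c("source", "attached_to", "project", "url")) {
    if (!is.null(rec[[f]])) out[[f]] <- ub(rec[[f]])
  }
  if (!is.null(rec$version_of)) {
    out$version_of <- list(base = ub(rec$version_of$base),
                           n = ub(as.integer(rec$version_of$n)))
  }
  out
}

jsonable_to_record <- function(x) {
  need <- c("name", "description", "payload_path", "checksum", "size_bytes",
            "created_at", "modified_at", "serializer")
  for (f in need) {
    if (is.null(x[[f]])) {
      stop_repo("format", sprintf("index record is missing field '%s'", f))
    }
  }
  vchr <- function(v) if (is.null(v)) character() else unlist(v, use.names = FALSE)
  version_of <- NULL
  if (!is.null(x$version_of)) {
    version_of <- list(base = x$version_of$base, n = as.integer(x$version_of$n))
  }
  new_record(
    name = x$name,
    description = x$description,
    tags = as.character(vchr(x$tags)),
    payload_path = x$payload_path,
    checksum = x$checksum,
    size_bytes = as.double(x$size_bytes),
    dims = as.integer(vchr(x$dims)),
    created_at = x$created_at,
    modified_at = x$modified_at,
    source = x$source,
    depends = as.character(vchr(x$depends)),
    attached_to = x$attached_to,
    project = x$project,
    url = x$url,
    kind_flags = as.character(vchr(x$kind_flags)),
    version_of = version_of,
    serializer = x$serializer
  )
}

#' Serialize a repository index to JSON bytes
#'
#' The index is the single shareable metadata file of a repository: format
#' version plus the ordered list of item records. Paths inside it are always
#' relative to the repository root, so a repository (or the index alone) can
#' be relocated or published as-is.
#'
#' @param items Named list of item records (insertion order preserved).
#' @param format_version Integer schema version, currently 1.
#' @return Raw vector of UTF-8 JSON bytes.
#' @keywords internal
serialize_index <- function(items, format_version = INDEX_FORMAT_VERSION) {
  doc <- list(
    format_version = jsonlite::unbox(as.integer(format_version)),
    items = lapply(unname(items), record_to_jsonable)
  )
  json <- jsonlite::toJSON(doc, auto_unbox = FALSE, pretty = TRUE, null = "null")
  charToRaw(as.character(json))
}

#' @rdname serialize_index
#' @param bytes Raw vector (or single string) of JSON produced by
#'   [serialize_index()].
#' @keywords internal
deserialize_index <- function(bytes) {
  txt <- if (is.raw(bytes)) rawToChar(bytes) else bytes
  doc <- tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = FALSE),
    error = function(e) {
      stop_repo("format", sprintf("corrupt repository index: %s", conditionMessage(e)))
    }
  )
  if (is.null(doc$format_version)) {
    stop_repo("format", "corrupt repository index: missing format_version")
  }
  fv <- as.integer(doc$format_version)
  if (fv != INDEX_FORMAT_VERSION) {
    stop_repo("format",
              sprintf("unsupported index format_version %d (this build reads version %d)",
                      fv, INDEX_FORMAT_VERSION))
  }
  recs <- lapply(doc$items, jsonable_to_record)
  names(recs) <- vapply(recs, `[[`, "", "name")
  if (anyDuplicated(names(recs))) {
    stop_repo("format", "corrupt repository index: duplicate item names")
  }
  recs
}

# Field-wise index equality; timestamps compared at second resolution (they
# are stored that way).
index_equal <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(names(a) %||% character(), names(b) %||% character())) return(FALSE)
  for (nm in names(a)) {
    ra <- a[[nm]]
    rb <- b[[nm]]
    for (f in names(ra)) {
      va <- ra[[f]]
      vb <- rb[[f]]
      if (is.character(va)) va <- as.character(va)
      if (is.character(vb)) vb <- as.character(vb)
      if (!identical(va, vb)) return(FALSE)
    }
  }
  TRUE
}
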
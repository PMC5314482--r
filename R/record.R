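#' Item records
#'
#' An item record is the unit of metadata in a repository index: identity
#' (`name`), annotations (`description`, `tags`, `url`), typed relations
#' (`depends`, `source`, `attached_to`, `project`), payload bookkeeping
#' (`payload_path` relative to the repository root, MD5 `checksum`,
#' `size_bytes`, `dims`, `serializer`), timestamps, `kind_flags` (subset of
#' attachment, project, stash, hidden, versioned) and, for superseded
#' versions, `version_of`.
#'
#' @name item-record
#' @keywords internal
NULL

KIND_FLAGS <- c("attachment", "project", "stash", "hidden", "versioned")
RELATION_TYPES <- c("depends_on", "generated_by", "attached_to")
SERIALIZERS <- c("rds", "file")

new_record <- function(name,
                       description,
                       tags = character(),
                       payload_path,
                       checksum,
                       size_bytes,
                       dims = integer(),
                       created_at = utc_now(),
                       modified_at = created_at,
                       source = NULL,
                       depends = character(),
                       attached_to = NULL,
                       project = NULL,
                       url = NULL,
                       kind_flags = character(),
                       version_of = NULL,
                       serializer = "rds") {
  stopifnot(all(kind_flags %in% KIND_FLAGS))
  structure(
    list(
      name = name,
      description = description,
      tags = unique(as.character(tags)),
      payload_path = payload_path,
      checksum = checksum,
      size_bytes = as.double(size_bytes),
      dims = as.integer(dims),
      created_at = created_at,
      modified_at = modified_at,
      source = source,
      depends = unique(as.character(depends)),
      attached_to = attached_to,
      project = project,
      url = url,
      kind_flags = unique(as.character(kind_flags)),
      version_of = version_of,
      serializer = serializer
    ),
    class = "datarepo_record"
  )
}

rec_has_flag <- function(rec, flag) flag %in% rec$kind_flags

rec_add_flag <- function(rec, flag) {
  rec$kind_flags <- unique(c(rec$kind_flags, flag))
  rec
}

# dims as reported by the serializer: array/table shape, else vector length,
# else empty (opaque payloads).
value_dims <- function(value) {
  d <- dim(value)
  if (!is.null(d)) return(as.integer(d))
  if (is.atomic(value) || is.list(value)) return(length(value))
  integer()
}
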
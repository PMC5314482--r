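#' List repository items
#'
#' Items are retrieved by annotation, not by location: tags act as a
#' generalization of directories, identifying possibly overlapping sets of
#' items. Hidden items (attachments, stash, superseded versions) are
#' excluded unless `include_hidden = TRUE`.
#'
#' @param repo A repository handle.
#' @param include_hidden Include hidden-flagged items?
#' @param tags Optional character vector of tags to filter by.
#' @param tag_op How to combine `tags`: `"any"` (default; at least one tag
#'   matches), `"all"` (every tag present), `"none"` (no tag present).
#' @return A tibble in insertion order with columns `name`, `description`,
#'   `tags` (list-column), `dims` (list-column), `size_bytes`, `flags`
#'   (list-column), `depends` (list-column), `source`, `attached_to`,
#'   `project`, `url`.
#' @examples
#' rp <- repo_init(tempfile("repo"))
#' repo_put(rp, 1:5, "x", "small vector", tags = c("demo", "numbers"))
#' repo_list(rp, tags = "demo")
#' @export
repo_list <- function(repo, include_hidden = FALSE, tags = NULL,
                      tag_op = c("any", "all", "none")) {
  check_repo(repo)
  tag_op <- match.arg(tag_op)
  recs <- repo$items
  if (!include_hidden) {
    recs <- recs[!vapply(recs, rec_has_flag, TRUE, "hidden")]
  }
  if (!is.null(tags)) {
    keep <- vapply(recs, function(r) tag_match(r$tags, tags, tag_op), TRUE)
    recs <- recs[keep]
  }
  records_tibble(recs)
}

tag_match <- function(item_tags, query_tags, op) {
  hits <- query_tags %in% item_tags
  switch(op,
    any = any(hits),
    all = all(hits),
    none = !any(hits)
  )
}

records_tibble <- function(recs) {
  recs <- unname(recs)
  opt_chr <- function(f) {
    vapply(recs, function(r) r[[f]] %||% NA_character_, "")
  }
  tibble::tibble(
    name = vapply(recs, `[[`, "", "name"),
    description = vapply(recs, `[[`, "", "description"),
    tags = lapply(recs, `[[`, "tags"),
    dims = lapply(recs, `[[`, "dims"),
    size_bytes = vapply(recs, `[[`, 0, "size_bytes"),
    flags = lapply(recs, `[[`, "kind_flags"),
    depends = lapply(recs, `[[`, "depends"),
    source = opt_chr("source"),
    attached_to = opt_chr("attached_to"),
    project = opt_chr("project"),
    url = opt_chr("url")
  )
}

#' Search all item metadata for a substring
#'
#' Case-insensitive fixed-substring match over every textual detail of every
#' item — name, description, tags, URL, and relation fields. Hidden items
#' are searched too: search must see everything.
#'
#' @param repo A repository handle.
#' @param pattern Non-empty string to look for.
#' @return Character vector of matching item names, in index order.
#' @export
repo_find <- function(repo, pattern) {
  check_repo(repo)
  assert_string(pattern, "pattern")
  needle <- tolower(pattern)
  hit <- vapply(repo$items, function(r) {
    fields <- c(r$name, r$description, r$tags, r$url, r$source,
                r$depends, r$attached_to, r$project, r$payload_path)
    any(grepl(needle, tolower(fields), fixed = TRUE))
  }, TRUE)
  names(repo$items)[hit] %||% character()
}

#' Build the provenance graph
#'
#' The analysis data flow is reconstructed a posteriori from the three typed
#' relations recorded in the index: *depends on* (`depends`), *generated by*
#' (`source`) and *attached to* (`attached_to`). Each recorded relation
#' becomes one directed edge from the annotated item to the item it
#' references. References to names no longer in the index are collected as
#' `dangling`, never silently dropped.
#'
#' @param repo A repository handle.
#' @return An object of class `repo_graph`: a list with `nodes` (character),
#'   `edges` (tibble `from`, `to`, `type`) and `dangling` (tibble `from`,
#'   `missing`, `type`).
#' @export
repo_graph <- function(repo) {
  check_repo(repo)
  nodes <- names(repo$items) %||% character()
  from <- character(); to <- character(); type <- character()
  d_from <- character(); d_missing <- character(); d_type <- character()
  add <- function(f, t, ty) {
    if (t %in% nodes) {
      from <<- c(from, f); to <<- c(to, t); type <<- c(type, ty)
    } else {
      d_from <<- c(d_from, f); d_missing <<- c(d_missing, t); d_type <<- c(d_type, ty)
    }
  }
  for (rec in repo$items) {
    for (dep in rec$depends) add(rec$name, dep, "depends_on")
    if (!is.null(rec$source)) add(rec$name, rec$source, "generated_by")
    if (!is.null(rec$attached_to)) add(rec$name, rec$attached_to, "attached_to")
  }
  structure(
    list(
      nodes = nodes,
      edges = tibble::tibble(from = from, to = to, type = type),
      dangling = tibble::tibble(from = d_from, missing = d_missing, type = d_type)
    ),
    class = "repo_graph"
  )
}

#' @export
print.repo_graph <- function(x, ...) {
  cat(sprintf("<provenance graph> %d nodes, %d edges",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$dangling) > 0) {
    cat(sprintf(", %d dangling reference%s", nrow(x$dangling),
                if (nrow(x$dangling) == 1) "" else "s"))
  }
  cat("\n")
  invisible(x)
}

#' Items related to a given item
#'
#' Transitive closure over all three relation types. `"both"` (default)
#' treats edges as undirected; `"upstream"` follows outgoing edges (what the
#' item was built from), `"downstream"` incoming ones (what was built from
#' it). The seed item is always included, so the result is a self-contained
#' set suitable for export or copy.
#'
#' @param repo A repository handle.
#' @param name Seed item name.
#' @param direction One of `"both"`, `"upstream"`, `"downstream"`.
#' @return Character vector of item names (includes `name`).
#' @export
repo_related <- function(repo, name, direction = c("both", "upstream", "downstream")) {
  check_repo(repo)
  check_exists(repo, name)
  direction <- match.arg(direction)
  g <- repo_graph(repo)
  adj <- switch(direction,
    upstream = split(g$edges$to, factor(g$edges$from, levels = g$nodes)),
    downstream = split(g$edges$from, factor(g$edges$to, levels = g$nodes)),
    both = {
      a <- split(c(g$edges$to, g$edges$from),
                 factor(c(g$edges$from, g$edges$to), levels = g$nodes))
      a
    }
  )
  seen <- name
  queue <- name
  while (length(queue)) {
    nxt <- unique(unlist(adj[queue], use.names = FALSE))
    queue <- setdiff(nxt, seen)
    seen <- c(seen, queue)
  }
  sort(seen)
}

#' Export the dependency graph as DOT
#'
#' Produces Graphviz DOT text for the provenance graph, one edge style per
#' relation type (solid: depends on; dashed: generated by; dotted: attached
#' to). Items matching `exclude_tags` are omitted together with their
#' incident edges — e.g. dropping everything tagged `"visualization"` leaves
#' the pure data flow.
#'
#' @param repo A repository handle.
#' @param exclude_tags Optional tags; matching items (under `exclude_op`) are
#'   left out of the plot.
#' @param exclude_op Operator for `exclude_tags` matching (default `"any"`).
#' @param include_types Relation types to draw; default all three.
#' @param file Optional path; when given the DOT text is also written there.
#' @return The DOT source as a single string, invisibly when `file` is given.
#' @export
repo_deps_dot <- function(repo, exclude_tags = NULL,
                          exclude_op = c("any", "all", "none"),
                          include_types = RELATION_TYPES, file = NULL) {
  check_repo(repo)
  exclude_op <- match.arg(exclude_op)
  stopifnot(all(include_types %in% RELATION_TYPES))
  g <- repo_graph(repo)
  nodes <- g$nodes
  if (!is.null(exclude_tags)) {
    excluded <- vapply(repo$items, function(r) {
      tag_match(r$tags, exclude_tags, exclude_op)
    }, TRUE)
    nodes <- setdiff(nodes, names(repo$items)[excluded])
  }
  edges <- dplyr::filter(g$edges,
                         .data$from %in% nodes,
                         .data$to %in% nodes,
                         .data$type %in% include_types)
  styles <- c(depends_on = "solid", generated_by = "dashed", attached_to = "dotted")
  q <- function(s) paste0('"', gsub('"', '\\\\"', s), '"')
  lines <- c(
    "digraph repository {",
    "  rankdir=LR;",
    "  node [shape=box, style=rounded];",
    if (length(nodes)) paste0("  ", q(nodes), ";"),
    if (nrow(edges)) {
      paste0("  ", q(edges$from), " -> ", q(edges$to),
             " [style=", styles[edges$type], ", label=\"",
             gsub("_", " ", edges$type), "\"];")
    },
    "}"
  )
  dot <- paste(lines, collapse = "\n")
  if (!is.null(file)) {
    writeLines(dot, file)
    return(invisible(dot))
  }
  dot
}

#' Tag an item
#'
#' Tags have set semantics: adding an existing tag is a no-op, removing an
#' absent one too. `modified_at` is refreshed only when the tag set actually
#' changes.
#'
#' @param repo A repository handle.
#' @param name Item name.
#' @param tags Tags to add or remove.
#' @return The item's tag set, invisibly for add/remove.
#' @export
repo_tag <- function(repo, name, tags) {
  check_repo(repo)
  rec <- get_record(repo, name)
  assert_tags(tags)
  new_tags <- unique(c(rec$tags, tags))
  if (!identical(new_tags, rec$tags)) {
    rec$tags <- new_tags
    rec$modified_at <- utc_now()
    set_record(repo, rec)
    persist_index(repo)
  }
  invisible(rec$tags)
}

#' @rdname repo_tag
#' @export
repo_untag <- function(repo, name, tags) {
  check_repo(repo)
  rec <- get_record(repo, name)
  new_tags <- setdiff(rec$tags, tags)
  if (!identical(new_tags, rec$tags)) {
    rec$tags <- new_tags
    rec$modified_at <- utc_now()
    set_record(repo, rec)
    persist_index(repo)
  }
  invisible(rec$tags)
}

#' @rdname repo_tag
#' @export
repo_tags <- function(repo, name) {
  check_repo(repo)
  get_record(repo, name)$tags
}
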
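#' Parse chunk markers in source-code text
#'
#' A chunk associates a contiguous region of a stored source file with the
#' item it generates. A chunk opens at a line of the form
#' `## chunk "<item name>"` and closes at `## chunk end`, at the next opener,
#' or at end of file. Names may contain spaces; names unknown to the
#' repository are allowed at parse time. The recorded code is the verbatim
#' slice of lines strictly between the markers.
#'
#' @param text Source code as a single string or character vector of lines.
#' @return A `chunk_map`: named list, one entry per item, each with `start`,
#'   `end` (line numbers of the code region) and `code` (text).
#' @examples
#' parse_chunks(c('## chunk "x"', "x <- 1", "## chunk end"))
#' @export
parse_chunks <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  re_marker <- "^\\s*##\\s*chunk\\b"
  re_end <- "^\\s*##\\s*chunk\\s+end\\s*$"
  re_open <- "^\\s*##\\s*chunk\\s+\"(.+)\"\\s*$"
  chunks <- list()
  open_name <- NULL
  open_line <- NA_integer_
  close_chunk <- function(last_line) {
    rng <- if (last_line >= open_line + 1L) seq(open_line + 1L, last_line) else integer()
    chunks[[open_name]] <<- list(
      start = open_line + 1L,
      end = last_line,
      code = paste(lines[rng], collapse = "\n")
    )
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!grepl(re_marker, ln)) next
    if (grepl(re_end, ln)) {
      if (!is.null(open_name)) {
        close_chunk(i - 1L)
        open_name <- NULL
      }
      next
    }
    m <- regmatches(ln, regexec(re_open, ln))[[1]]
    if (length(m) < 2L) {
      stop_repo("parse",
                sprintf("line %d: malformed chunk marker (expected ## chunk \"<item name>\")", i))
    }
    # a new opener implicitly closes the previous chunk
    if (!is.null(open_name)) close_chunk(i - 1L)
    if (m[2] %in% names(chunks)) {
      stop_repo("parse", sprintf("line %d: duplicate chunk for item '%s'", i, m[2]))
    }
    open_name <- m[2]
    open_line <- i
  }
  if (!is.null(open_name)) close_chunk(length(lines))
  structure(chunks, class = "chunk_map")
}

#' Show the code chunk that generates an item
#'
#' Follows the item's `source` relation to the stored source file and
#' returns the verbatim chunk annotated with the item's name.
#'
#' @param repo A repository handle.
#' @param name Item name.
#' @return The chunk's code text.
#' @export
repo_chunk <- function(repo, name) {
  check_repo(repo)
  rec <- get_record(repo, name)
  if (is.null(rec$source)) {
    stop_repo("no_source", sprintf("item '%s' has no source annotated", name))
  }
  src <- get_record(repo, rec$source)
  chunks <- parse_chunks(payload_text(repo, src))
  if (!name %in% names(chunks)) {
    stop_repo("no_chunk",
              sprintf("source '%s' contains no chunk for item '%s'", rec$source, name))
  }
  chunks[[name]]$code
}

payload_text <- function(repo, rec) {
  path <- payload_abspath(repo, rec)
  if (!file.exists(path)) {
    stop_repo("integrity", sprintf("payload for '%s' is missing", rec$name))
  }
  if (identical(rec$serializer, "file")) {
    rawToChar(read_file_bytes(path))
  } else {
    v <- read_payload(path, rec$serializer)
    paste(as.character(v), collapse = "\n")
  }
}

# Chunk maps of every stored source file, in index order. Each entry gains a
# `source_item` field; the first definition of an item's chunk wins.
combined_chunk_map <- function(repo) {
  out <- list()
  for (rec in repo$items) {
    if (!identical(rec$serializer, "file")) next
    path <- payload_abspath(repo, rec)
    if (!file.exists(path)) next
    txt <- tryCatch(rawToChar(read_file_bytes(path)), error = function(e) NULL)
    # payloads may be arbitrary bytes (figures etc.); compare bytewise
    if (is.null(txt) || !any(grepl("## chunk", txt, fixed = TRUE, useBytes = TRUE))) next
    cm <- tryCatch(parse_chunks(txt), error = function(e) NULL)
    if (is.null(cm)) next
    for (nm in names(cm)) {
      if (!nm %in% names(out)) {
        entry <- cm[[nm]]
        entry$source_item <- rec$name
        out[[nm]] <- entry
      }
    }
  }
  out
}

# Dependencies used by the planner. A record's `depends` annotation is
# authoritative; for items that have never been built (no record) the
# dependencies are inferred statically from the chunk code: every quoted
# string naming another chunk-annotated or stored item counts. This mirrors
# chunks referencing their inputs as get("<name>").
planner_deps <- function(repo, name, cmap) {
  if (repo_has(repo, name)) {
    return(repo$items[[name]]$depends)
  }
  if (!name %in% names(cmap)) return(character())
  code <- cmap[[name]]$code
  quoted <- unlist(regmatches(code, gregexpr('"[^"]*"|\'[^\']*\'', code)))
  quoted <- gsub('^["\']|["\']$', "", quoted)
  universe <- union(names(cmap), names(repo$items))
  setdiff(intersect(unique(quoted), universe), name)
}

item_present <- function(repo, name) {
  repo_has(repo, name) &&
    file.exists(payload_abspath(repo, repo$items[[name]]))
}

#' Plan a recursive build
#'
#' Decides which chunks must run to (re)create `target`, walking the
#' dependency relation recursively. Under `"skip_existing"` (the default) an
#' item is run only if it is absent (no record, or payload file missing);
#' present items are recorded as skipped, with their dependencies still
#' listed so the plan shows the full pipeline stage by stage.
#' Under `"force_versioned"` every reachable chunk-annotated item is re-run
#' and existing items are preserved as numbered versions; under
#' `"force_overwrite"` they are overwritten in place.
#'
#' @param repo A repository handle.
#' @param target Item to build. Must have a chunk in some stored source file,
#'   or already exist (then the plan may be all-skip).
#' @param policy `"skip_existing"`, `"force_versioned"` or
#'   `"force_overwrite"`.
#' @return A `repo_build_plan`: a tibble with columns `name` and `action`
#'   (`"run"`/`"skip"`), dependencies ordered before dependents, with the
#'   chunk map and policy attached as attributes.
#' @export
repo_plan_build <- function(repo, target,
                            policy = c("skip_existing", "force_versioned",
                                       "force_overwrite")) {
  check_repo(repo)
  policy <- match.arg(policy)
  cmap <- combined_chunk_map(repo)
  if (!repo_has(repo, target) && !target %in% names(cmap)) {
    stop_repo("unknown_item",
              sprintf("'%s' is neither stored nor chunk-annotated", target))
  }
  force_all <- policy != "skip_existing"

  steps_name <- character()
  steps_action <- character()
  visiting <- character()
  done <- character()
  run_flag <- list()

  visit <- function(name) {
    if (name %in% done) return(invisible(NULL))
    if (name %in% visiting) {
      cycle <- c(visiting[seq(match(name, visiting), length(visiting))], name)
      # metadata cycles among already-present (skipped) items are
      # representable; only cycles that must actually run are fatal
      if (any(vapply(cycle, function(x) isTRUE(run_flag[[x]]), TRUE))) {
        stop_repo("cycle",
                  sprintf("dependency cycle: %s", paste(cycle, collapse = " -> ")))
      }
      return(invisible(NULL))
    }
    present <- item_present(repo, name)
    has_chunk <- name %in% names(cmap)
    run <- if (force_all) has_chunk || !present else !present
    if (run && !has_chunk) {
      stop_repo("unsatisfiable",
                sprintf("'%s' must be built but has no code chunk", name))
    }
    run_flag[[name]] <<- run
    visiting <<- c(visiting, name)
    for (dep in planner_deps(repo, name, cmap)) visit(dep)
    visiting <<- visiting[-length(visiting)]
    done <<- c(done, name)
    steps_name <<- c(steps_name, name)
    steps_action <<- c(steps_action, if (run) "run" else "skip")
    invisible(NULL)
  }
  visit(target)

  plan <- tibble::tibble(name = steps_name, action = steps_action)
  structure(plan,
            class = c("repo_build_plan", class(plan)),
            policy = policy, chunks = cmap)
}

#' @export
print.repo_build_plan <- function(x, ...) {
  cat(sprintf("<build plan> policy: %s\n", attr(x, "policy")))
  if (nrow(x) == 0) {
    cat("  (nothing to do)\n")
  } else {
    cat(sprintf("  %-5s %s\n", toupper(x$action), x$name), sep = "")
  }
  invisible(x)
}

#' Default chunk executor
#'
#' Evaluates chunk code in a fresh environment whose parent is the global
#' environment, with the repository handle bound to `rp`. Chunks are plain R
#' that store their result via `repo_put(rp, ...)` / `repo_attach(rp, ...)`.
#' Any function of `(code, repo)` can stand in for it, which keeps builds
#' testable with mock executors.
#'
#' @return A function `function(code, repo)`.
#' @export
repo_executor <- function() {
  function(code, repo) {
    env <- new.env(parent = globalenv())
    assign("rp", repo, envir = env)
    eval(parse(text = code), envir = env)
  }
}

#' Execute a build plan
#'
#' Runs the plan's `run` steps in order through the executor. During the
#' build the repository's default replacement policy follows the plan's
#' policy (`addversion` for `"force_versioned"`, `overwrite` otherwise), so
#' unmodified chunk code picks up the session-wise semantics. After each run
#' step the step's item must exist with its payload on disk; a chunk that
#' fails to produce its item aborts the build. Items completed before a
#' failure remain stored, so an interrupted build can simply be re-planned
#' and resumed (reentrancy).
#'
#' @param repo A repository handle.
#' @param plan A plan from [repo_plan_build()].
#' @param executor A `function(code, repo)`; default [repo_executor()].
#' @return A build report: tibble with `name`, `action`, `status`
#'   (`"done"`/`"skipped"`), `seconds`.
#' @export
repo_execute_build <- function(repo, plan, executor = repo_executor()) {
  check_repo(repo)
  if (!inherits(plan, "repo_build_plan")) {
    stop_repo("bad_argument", "`plan` must come from repo_plan_build()")
  }
  cmap <- attr(plan, "chunks")
  policy <- attr(plan, "policy")
  old_replace <- repo$options$replace
  repo$options$replace <- if (identical(policy, "force_versioned")) "addversion" else "overwrite"
  on.exit(repo$options$replace <- old_replace)

  status <- character(nrow(plan))
  seconds <- numeric(nrow(plan))
  for (i in seq_len(nrow(plan))) {
    nm <- plan$name[i]
    if (plan$action[i] == "skip") {
      status[i] <- "skipped"
      next
    }
    t0 <- proc.time()[["elapsed"]]
    ok <- tryCatch({
      executor(cmap[[nm]]$code, repo)
      TRUE
    }, error = function(e) e)
    seconds[i] <- proc.time()[["elapsed"]] - t0
    if (!isTRUE(ok)) {
      stop_repo("build",
                sprintf("chunk for '%s' failed: %s", nm, conditionMessage(ok)))
    }
    if (!item_present(repo, nm)) {
      stop_repo("build",
                sprintf("chunk for '%s' did not produce its item", nm))
    }
    status[i] <- "done"
  }
  tibble::tibble(name = plan$name, action = plan$action,
                 status = status, seconds = seconds)
}

#' Plan and run a build in one call
#'
#' @inheritParams repo_plan_build
#' @inheritParams repo_execute_build
#' @return The build report from [repo_execute_build()].
#' @export
repo_build <- function(repo, target,
                       policy = c("skip_existing", "force_versioned",
                                  "force_overwrite"),
                       executor = repo_executor()) {
  plan <- repo_plan_build(repo, target, policy)
  repo_execute_build(repo, plan, executor)
}

#' Evaluate code, caching the result in the repository
#'
#' Disk memoization keyed by the MD5 of the exact code text: the first call
#' evaluates the code and stashes the result as a hidden item named
#' `lazydo_<digest>`; later calls with byte-identical code load the cached
#' value without evaluating. Any textual change (even whitespace) is a new
#' key. A failing evaluation caches nothing.
#'
#' @param repo A repository handle.
#' @param code R code as a single string.
#' @param envir Environment in which to evaluate on a cache miss; defaults to
#'   the caller's.
#' @return The (computed or cached) value.
#' @export
repo_lazydo <- function(repo, code, envir = parent.frame()) {
  check_repo(repo)
  assert_string(code, "code")
  key <- paste0("lazydo_", md5_text(code))
  if (repo_has(repo, key)) {
    return(repo_get(repo, key))
  }
  value <- eval(parse(text = code), envir = envir)
  repo_stash(repo, value, key)
  value
}
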
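# Shared fixtures and independent oracles for the suite.

new_repo <- function(env = parent.frame()) {
  repo_init(withr::local_tempdir(.local_envir = env))
}

# A small corpus of round-trippable values covering the serializer's range.
value_corpus <- function(n, seed = 1) {
  set.seed(seed)
  gen_one <- function(depth = 0) {
    kind <- sample(c("num", "int", "chr", "lgl", "raw", "mat", "df", "list", "named"),
                   1, prob = c(2, 2, 2, 1, 1, 1, 1, if (depth < 2) 1.5 else 0.01, 1))
    switch(kind,
      num = stats::rnorm(sample(0:10, 1)),
      int = sample.int(1000, sample(0:10, 1), replace = TRUE),
      chr = c(sample(c(letters, "été", "中文", ""), sample(0:5, 1),
                     replace = TRUE)),
      lgl = sample(c(TRUE, FALSE, NA), sample(0:5, 1), replace = TRUE),
      raw = as.raw(sample(0:255, sample(0:20, 1), replace = TRUE)),
      mat = matrix(stats::rnorm(6), 2, 3),
      df = data.frame(x = 1:3, y = letters[1:3], stringsAsFactors = FALSE),
      list = lapply(seq_len(sample(1:3, 1)), function(i) gen_one(depth + 1)),
      named = stats::setNames(as.list(stats::rnorm(2)), c("a", "b"))
    )
  }
  lapply(seq_len(n), function(i) gen_one())
}

# Random repository of plainly annotated items whose depends/source point at
# earlier items; used for graph, tag and search properties.
random_repo <- function(n_items = 8, seed = 1, env = parent.frame()) {
  set.seed(seed)
  rp <- new_repo(env)
  tag_pool <- c("alpha", "beta", "gamma", "delta")
  for (i in seq_len(n_items)) {
    nm <- sprintf("it%02d", i)
    earlier <- sprintf("it%02d", seq_len(i - 1))
    deps <- if (length(earlier)) {
      sample(earlier, sample(0:min(2, length(earlier)), 1))
    } else {
      character()
    }
    src <- if (length(earlier) && stats::runif(1) < 0.3) sample(earlier, 1) else NULL
    repo_put(rp, stats::rnorm(i), nm,
             description = paste("random item", i),
             tags = sample(tag_pool, sample(1:3, 1)),
             depends = deps, source = src,
             url = if (stats::runif(1) < 0.3) paste0("https://example.org/", nm) else NULL)
  }
  rp
}

# Undirected-reachability oracle: repeated squaring free, plain loop over an
# adjacency matrix built straight from the records.
oracle_related_both <- function(rp, seed_item) {
  nms <- names(rp$items)
  n <- length(nms)
  adj <- matrix(FALSE, n, n, dimnames = list(nms, nms))
  for (rec in rp$items) {
    for (ref in c(rec$depends, rec$source, rec$attached_to)) {
      if (ref %in% nms) {
        adj[rec$name, ref] <- TRUE
        adj[ref, rec$name] <- TRUE
      }
    }
  }
  reach <- seed_item
  repeat {
    nxt <- unique(c(reach, nms[colSums(adj[reach, , drop = FALSE]) > 0]))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  sort(reach)
}

# Brute-force tag algebra over the non-hidden universe.
oracle_tag_filter <- function(rp, tags, op) {
  visible <- Filter(function(r) !"hidden" %in% r$kind_flags, rp$items)
  match_any <- function(r) any(tags %in% r$tags)
  keep <- switch(op,
    any = vapply(visible, match_any, TRUE),
    all = vapply(visible, function(r) all(tags %in% r$tags), TRUE),
    none = !vapply(visible, match_any, TRUE)
  )
  names(visible)[keep] %||% character()
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Naive full scan over every serialized metadata field.
oracle_find <- function(rp, pattern) {
  nms <- names(rp$items)
  hit <- vapply(rp$items, function(r) {
    txt <- unlist(r[c("name", "description", "tags", "url", "source",
                      "depends", "attached_to", "project", "payload_path")],
                  use.names = FALSE)
    any(grepl(tolower(pattern), tolower(txt), fixed = TRUE))
  }, TRUE)
  nms[hit] %||% character()
}

# --- chunk-annotated DAG worlds for build tests ----------------------------

chunk_code_lines <- function(name, deps) {
  dep_vec <- if (length(deps)) {
    sprintf("c(%s)", paste(sprintf('"%s"', deps), collapse = ", "))
  } else {
    "character()"
  }
  c(sprintf('## chunk "%s"', name),
    sprintf("deps <- %s", dep_vec),
    "for (d in deps) invisible(repo_get(rp, d))",
    sprintf('repo_put(rp, deps, "%s", "generated in test", tags = "generated", depends = deps)',
            name),
    "## chunk end")
}

# Random DAG with edges from later items to earlier ones; returns the edge
# list plus a repository holding only the chunk-annotated source file.
random_chunk_dag <- function(n_items = 6, seed = 1, env = parent.frame()) {
  set.seed(seed)
  nms <- sprintf("n%02d", seq_len(n_items))
  deps <- list()
  for (i in seq_along(nms)) {
    pool <- nms[seq_len(i - 1)]
    deps[[nms[i]]] <- if (length(pool)) {
      sample(pool, sample(0:min(3, length(pool)), 1))
    } else {
      character()
    }
  }
  src <- unlist(lapply(nms, function(nm) chunk_code_lines(nm, deps[[nm]])))
  rp <- new_repo(env)
  path <- withr::local_tempfile(lines = src, fileext = ".R", .local_envir = env)
  repo_attach(rp, path, "test pipeline source", tags = "code", name = "src.R")
  list(repo = rp, names = nms, deps = deps, source = src)
}

# executor decorator counting invocations (and optionally failing at step k)
counting_executor <- function(counter, fail_at = NA) {
  inner <- repo_executor()
  function(code, repo) {
    counter$calls <- counter$calls + 1L
    if (!is.na(fail_at) && counter$calls == fail_at) {
      stop("injected failure")
    }
    inner(code, repo)
  }
}

new_counter <- function() {
  e <- new.env()
  e$calls <- 0L
  e
}

# dependency-consistent order check: every dependency of a run item must be
# present in the report at an earlier position (or have been skipped)
order_consistent <- function(report, deps) {
  pos <- stats::setNames(seq_len(nrow(report)), report$name)
  for (nm in report$name[report$action == "run"]) {
    for (d in deps[[nm]]) {
      if (d %in% names(pos) && pos[[d]] >= pos[[nm]]) return(FALSE)
    }
  }
  TRUE
}

# Parse node and edge sets back out of DOT text (the export is line-based).
parse_dot <- function(dot) {
  lines <- strsplit(dot, "\n", fixed = TRUE)[[1]]
  edge_lines <- grep(" -> ", lines, fixed = TRUE, value = TRUE)
  node_lines <- setdiff(grep('^\\s*".*";\\s*$', lines, value = TRUE), edge_lines)
  unquote <- function(x) gsub('^"|"$', "", x)
  nodes <- unquote(sub('^\\s*(".*");\\s*$', "\\1", node_lines))
  edges <- do.call(rbind, lapply(edge_lines, function(ln) {
    m <- regmatches(ln, regexec('^\\s*"(.*)" -> "(.*)" \\[style=(\\w+)', ln))[[1]]
    data.frame(from = m[2], to = m[3], style = m[4], stringsAsFactors = FALSE)
  }))
  list(nodes = nodes, edges = edges)
}

# Random but structurally valid index records for serialization round trips.
random_record <- function(i, universe) {
  nm <- sprintf("item-%03d é%d", i, i)
  datarepo:::new_record(
    name = nm,
    description = paste("description with unicode 中文 #", i),
    tags = sample(c("a", "b", "c/d", "sp ace"), sample(1:3, 1)),
    payload_path = file.path("data", sprintf("item_%03d.bin", i)),
    checksum = paste(sample(c(0:9, letters[1:6]), 32, replace = TRUE), collapse = ""),
    size_bytes = sample(0:10000, 1),
    dims = if (stats::runif(1) < 0.5) sample(1:50, sample(1:3, 1)) else integer(),
    source = if (length(universe) && stats::runif(1) < 0.3) sample(universe, 1) else NULL,
    depends = if (length(universe)) {
      sample(universe, sample(0:min(2, length(universe)), 1))
    } else {
      character()
    },
    attached_to = if (length(universe) && stats::runif(1) < 0.2) sample(universe, 1) else NULL,
    url = if (stats::runif(1) < 0.4) sprintf("https://example.org/%d?q=%d", i, i) else NULL,
    kind_flags = sample(datarepo:::KIND_FLAGS, sample(0:2, 1)),
    version_of = if (stats::runif(1) < 0.2) list(base = "base name", n = i) else NULL
  )
}

random_index <- function(n) {
  recs <- list()
  for (i in seq_len(n)) {
    r <- random_record(i, names(recs))
    recs[[r$name]] <- r
  }
  recs
}
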
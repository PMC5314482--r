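#' Synthetic raw data table
#'
#' Deterministic generator of a small tabular dataset in the shape of a
#' protein-expression screen: 120 samples by 8 numeric measurement columns
#' (`p1`..`p8`, standard normal), two categorical covariates and a sample
#' identifier, with 10% of numeric cells missing at random. The values are
#' synthetic — the generator emulates the *shape* of such data (missing
#' values, mixed column types), not any real measurements.
#'
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @param n_rows,n_cols Table dimensions (samples x numeric columns).
#' @param na_rate Fraction of numeric cells set to missing.
#' @return `fixture_raw_table()`: a data.frame; `fixture_raw_table_text()`:
#'   the same table as CSV text (character vector of lines, missing cells
#'   empty), byte-deterministic for a given seed.
#' @export
fixture_raw_table <- function(seed, n_rows = 120L, n_cols = 8L, na_rate = 0.1) {
  with_preserved_rng(seed, {
    mat <- matrix(round(stats::rnorm(n_rows * n_cols), 4), n_rows, n_cols)
    n_na <- round(na_rate * length(mat))
    mat[sample(length(mat), n_na)] <- NA
    colnames(mat) <- paste0("p", seq_len(n_cols))
    data.frame(
      sample = sprintf("s%03d", seq_len(n_rows)),
      genotype = sample(c("control", "trisomic"), n_rows, replace = TRUE),
      treatment = sample(c("saline", "memantine"), n_rows, replace = TRUE),
      mat,
      stringsAsFactors = FALSE
    )
  })
}

#' @rdname fixture_raw_table
#' @export
fixture_raw_table_text <- function(seed, n_rows = 120L, n_cols = 8L, na_rate = 0.1) {
  tab <- fixture_raw_table(seed, n_rows, n_cols, na_rate)
  num <- tab[, grep("^p", names(tab)), drop = FALSE]
  cells <- vapply(seq_len(nrow(tab)), function(i) {
    vals <- ifelse(is.na(num[i, ]), "", sprintf("%.4f", unlist(num[i, ])))
    paste(c(tab$sample[i], tab$genotype[i], tab$treatment[i], vals), collapse = ",")
  }, "")
  c(paste(names(tab), collapse = ","), cells)
}

with_preserved_rng <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

fixture_source_code <- function(seed) {
  c(
    "# pipeline source for the example repository",
    "",
    '## chunk "mice_cortex.csv"',
    'path <- file.path(tempdir(), "mice_cortex.csv")',
    sprintf("writeLines(datarepo::fixture_raw_table_text(seed = %d), path)", seed),
    'repo_attach(rp, path, "raw synthetic protein expression table",',
    '            tags = c("dataset", "raw"),',
    '            url = "https://example.org/mice/mice_cortex.csv")',
    "## chunk end",
    "",
    '## chunk "Mice Cortex"',
    'raw <- repo_get(rp, "mice_cortex.csv")',
    "tab <- read.csv(text = rawToChar(raw), stringsAsFactors = FALSE)",
    'num <- as.matrix(tab[, grep("^p", names(tab))])',
    "rownames(num) <- tab$sample",
    'repo_put(rp, num, "Mice Cortex", "imported protein expression matrix",',
    '         tags = c("dataset", "mice"), depends = "mice_cortex.csv")',
    "## chunk end",
    "",
    '## chunk "Mice Cortex notNA"',
    'm <- repo_get(rp, "Mice Cortex")',
    "m <- m[stats::complete.cases(m), , drop = FALSE]",
    "m <- scale(m)",
    'repo_put(rp, m, "Mice Cortex notNA",',
    '         "protein matrix, incomplete samples removed, scaled",',
    '         tags = c("dataset", "mice"), depends = "Mice Cortex")',
    "## chunk end"
  )
}

#' Generate a complete example repository
#'
#' Builds, deterministically from `seed`, a repository emulating a small
#' analysis pipeline end to end: a raw CSV stored as an attachment with a
#' (fake) provenance URL; an imported numeric matrix depending on it; a
#' row-filtered version depending on that; a scaled replacement stored with
#' add-version semantics (so `"Mice Cortex notNA#1"` preserves the
#' unscaled matrix); two chained figure attachments; a project item; a
#' stashed intermediate; and a chunk-annotated source file covering the data
#' items, so the whole pipeline can be rebuilt with [repo_build()].
#'
#' @param root Empty or non-existing directory for the repository.
#' @param seed Integer seed controlling all generated content.
#' @return The repository handle, with a `manifest` attribute: a list of
#'   expected names, flags, checksums, sizes, graph edges and chunk line
#'   ranges, usable as an oracle.
#' @examples
#' rp <- repo_example(tempfile("repo"), seed = 1)
#' repo_list(rp)
#' @export
repo_example <- function(root, seed = 42L) {
  if (dir.exists(root) && length(list.files(root, all.files = TRUE, no.. = TRUE))) {
    stop_repo("bad_argument", sprintf("'%s' is not empty", root))
  }
  seed <- as.integer(seed)
  rp <- repo_init(root)

  # source file with chunk annotations, stored like any other attachment
  src_lines <- fixture_source_code(seed)
  src_path <- file.path(tempdir(), paste0("pipeline_", seed, ".R"))
  writeLines(src_lines, src_path)
  repo_attach(rp, src_path, "analysis source code", tags = c("source", "code"),
              name = "pipeline.R")

  repo_project(rp, "mice-analysis", "synthetic protein expression analysis")
  repo_options(rp, default_source = "pipeline.R", default_project = "mice-analysis")

  # raw data file, imported matrix, filtered matrix, scaled replacement:
  # the first three chunks of pipeline.R executed in order, then the
  # add-version overwrite recreating the paper-style version history
  cmap <- parse_chunks(src_lines)
  exec <- repo_executor()
  exec(cmap[["mice_cortex.csv"]]$code, rp)
  exec(cmap[["Mice Cortex"]]$code, rp)

  m <- repo_get(rp, "Mice Cortex")
  filtered <- m[stats::complete.cases(m), , drop = FALSE]
  repo_put(rp, filtered, "Mice Cortex notNA",
           "protein matrix, incomplete samples removed",
           tags = c("dataset", "mice"), depends = "Mice Cortex")
  repo_put(rp, scale(filtered), "Mice Cortex notNA",
           "protein matrix, incomplete samples removed, scaled",
           tags = c("dataset", "mice"), depends = "Mice Cortex",
           replace = "addversion")

  # chained figure attachments (opaque deterministic bytes; no renderer)
  with_preserved_rng(seed + 1L, {
    for (spec in list(
      list(file = "pca2d.pdf", to = "Mice Cortex notNA",
           desc = "2D principal component plot of the filtered data"),
      list(file = "pca_variance.pdf", to = "pca2d.pdf",
           desc = "variance explained by each principal component")
    )) {
      p <- file.path(tempdir(), paste0(seed, "_", spec$file))
      writeBin(as.raw(sample(0:255, 512, replace = TRUE)), p)
      repo_attach(rp, p, spec$desc, tags = c("visualization", "mice"),
                  to = spec$to, name = spec$file)
    }
  })

  repo_stash(rp, colMeans(filtered), "column means scratch")

  manifest <- list(
    seed = seed,
    names = names(rp$items),
    flags = lapply(rp$items, `[[`, "kind_flags"),
    checksums = vapply(rp$items, `[[`, "", "checksum"),
    sizes = vapply(rp$items, `[[`, 0, "size_bytes"),
    urls = vapply(rp$items, function(r) r$url %||% NA_character_, ""),
    edges = repo_graph(rp)$edges,
    chunk_ranges = lapply(cmap, function(ch) ch[c("start", "end")]),
    raw_rows = 120L,
    filtered_rows = nrow(filtered)
  )
  attr(rp, "manifest") <- manifest
  rp
}
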
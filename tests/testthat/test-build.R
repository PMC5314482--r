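test_that("chunk markers parse to exact line ranges", {
  txt <- c("x <- 0", '## chunk "Mice Cortex"', "a <- 1", "b <- 2",
           "## chunk end", "y <- 3")
  cm <- parse_chunks(txt)
  expect_length(cm, 1)
  expect_equal(cm[["Mice Cortex"]]$start, 3)
  expect_equal(cm[["Mice Cortex"]]$end, 4)
  expect_identical(cm[["Mice Cortex"]]$code, "a <- 1\nb <- 2")

  expect_length(parse_chunks("no markers here"), 0)

  # adjacent chunks: an opener implicitly closes the previous chunk
  adj <- parse_chunks(c('## chunk "a"', "1", '## chunk "b"', "2", "3"))
  expect_equal(adj[["a"]][c("start", "end")], list(start = 2L, end = 2L))
  expect_equal(adj[["b"]][c("start", "end")], list(start = 4L, end = 5L))
  expect_identical(adj[["b"]]$code, "2\n3")

  expect_error(parse_chunks('## chunk noquotes'), class = "datarepo_parse")
  expect_error(parse_chunks(c("x", '## chunk "dup"', '## chunk "dup"')),
               regexp = "line 3", class = "datarepo_parse")
})

test_that("chunks written programmatically are recovered exactly", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(1:5, 1)
    names_ <- sprintf("item %d", seq_len(n))
    written <- list()
    lines <- character()
    for (nm in names_) {
      body <- replicate(sample(1:4, 1),
                        paste(sample(letters, 5), collapse = " "))
      written[[nm]] <- paste(body, collapse = "\n")
      lines <- c(lines, sprintf('## chunk "%s"', nm), body,
                 if (runif(1) < 0.7) "## chunk end")
    }
    cm <- parse_chunks(lines)
    expect_identical(names(cm), names_)
    for (nm in names_) expect_identical(cm[[nm]]$code, written[[nm]])
  }
})

test_that("repo_chunk returns the verbatim generating code or classed errors", {
  fx <- repo_example(withr::local_tempdir(), seed = 4)
  code <- repo_chunk(fx, "Mice Cortex")
  src <- strsplit(rawToChar(repo_get(fx, "pipeline.R")), "\n")[[1]]
  rng <- attr(fx, "manifest")$chunk_ranges[["Mice Cortex"]]
  expect_identical(code, paste(src[rng$start:rng$end], collapse = "\n"))

  rp <- new_repo()
  repo_put(rp, 1, "nosrc", "no source", tags = "t")
  expect_error(repo_chunk(rp, "nosrc"), class = "datarepo_no_source")

  f <- withr::local_tempfile(lines = '## chunk "other"', fileext = ".R")
  repo_attach(rp, f, "source", tags = "code", name = "s.R")
  repo_put(rp, 2, "unmarked", "no chunk", tags = "t", source = "s.R")
  expect_error(repo_chunk(rp, "unmarked"), class = "datarepo_no_chunk")
})

test_that("plans run dependencies before dependents and skip present items", {
  rp <- new_repo()
  lines <- c(chunk_code_lines("a", character()),
             chunk_code_lines("b", "a"),
             chunk_code_lines("c", "b"))
  f <- withr::local_tempfile(lines = lines, fileext = ".R")
  repo_attach(rp, f, "chain source", tags = "code", name = "chain.R")

  plan <- repo_plan_build(rp, "c")
  expect_equal(plan$name, c("a", "b", "c"))
  expect_equal(plan$action, rep("run", 3))

  # pre-populate a: it is listed as skipped, b and c still run
  repo_put(rp, 0, "a", "preexisting", tags = "t")
  plan2 <- repo_plan_build(rp, "c")
  expect_equal(plan2$action[plan2$name == "a"], "skip")
  expect_equal(plan2$action[plan2$name %in% c("b", "c")], c("run", "run"))

  repo_execute_build(rp, plan2)
  expect_true(repo_has(rp, "c"))
  # everything present: all-skip, zero run steps on re-plan
  plan3 <- repo_plan_build(rp, "c")
  expect_true(all(plan3$action == "skip"))

  expect_error(repo_plan_build(rp, "ghost"), class = "datarepo_unknown_item")
})

test_that("dependency cycles are reported with the offending items", {
  rp <- new_repo()
  lines <- c(chunk_code_lines("x", "y"), chunk_code_lines("y", "x"))
  f <- withr::local_tempfile(lines = lines, fileext = ".R")
  repo_attach(rp, f, "cyclic source", tags = "code", name = "cyc.R")
  err <- expect_error(repo_plan_build(rp, "x"), class = "datarepo_cycle")
  expect_match(conditionMessage(err), "x")
  expect_match(conditionMessage(err), "y")
})

test_that("random DAG builds run each chunk exactly once, in order", {
  for (seed in 1:15) {
    w <- random_chunk_dag(n_items = 6, seed = seed)
    counter <- new_counter()
    target <- w$names[length(w$names)]
    report <- repo_execute_build(w$repo, repo_plan_build(w$repo, target),
                                 executor = counting_executor(counter))
    ran <- report$name[report$action == "run"]
    expect_equal(counter$calls, length(ran))
    expect_equal(anyDuplicated(ran), 0)
    expect_true(order_consistent(report, w$deps))
    for (nm in ran) expect_true(repo_has(w$repo, nm))

    # monotonicity: pre-populating a random subset never enlarges the run set
    w2 <- random_chunk_dag(n_items = 6, seed = seed)
    pre <- sample(w2$names, sample(1:4, 1))
    for (nm in pre) repo_put(w2$repo, 0, nm, "prebuilt", tags = "t")
    plan2 <- repo_plan_build(w2$repo, target)
    ran2 <- plan2$name[plan2$action == "run"]
    expect_true(all(ran2 %in% ran))
    expect_false(any(pre %in% ran2))
  }
})

test_that("interrupted builds resume with only the remaining steps", {
  rp <- new_repo()
  nms <- c("s1", "s2", "s3", "s4")
  lines <- unlist(lapply(seq_along(nms), function(i) {
    chunk_code_lines(nms[i], if (i > 1) nms[i - 1] else character())
  }))
  f <- withr::local_tempfile(lines = lines, fileext = ".R")
  repo_attach(rp, f, "chain source", tags = "code", name = "chain.R")

  plan <- repo_plan_build(rp, "s4")
  counter <- new_counter()
  expect_error(
    repo_execute_build(rp, plan, executor = counting_executor(counter, fail_at = 3)),
    class = "datarepo_build"
  )
  # steps completed before the failure remain stored
  expect_true(repo_has(rp, "s1") && repo_has(rp, "s2"))
  expect_false(repo_has(rp, "s3") || repo_has(rp, "s4"))

  plan2 <- repo_plan_build(rp, "s4")
  expect_equal(plan2$action[match(c("s1", "s2", "s3", "s4"), plan2$name)],
               c("skip", "skip", "run", "run"))
  counter2 <- new_counter()
  repo_execute_build(rp, plan2, executor = counting_executor(counter2))
  expect_equal(counter2$calls, 2L)
  expect_true(repo_has(rp, "s4"))
})

test_that("a chunk that fails to produce its item aborts the build", {
  rp <- new_repo()
  f <- withr::local_tempfile(lines = c('## chunk "lazy"', "x <- 1", "## chunk end"),
                             fileext = ".R")
  repo_attach(rp, f, "source", tags = "code", name = "s.R")
  err <- expect_error(repo_build(rp, "lazy"), class = "datarepo_build")
  expect_match(conditionMessage(err), "did not produce")
})

test_that("force_versioned rebuilds preserve previous versions", {
  rp <- new_repo()
  lines <- c(chunk_code_lines("base", character()),
             chunk_code_lines("derived", "base"))
  f <- withr::local_tempfile(lines = lines, fileext = ".R")
  repo_attach(rp, f, "source", tags = "code", name = "s.R")
  repo_build(rp, "derived")
  sums1 <- vapply(rp$items[c("base", "derived")], `[[`, "", "checksum")

  report <- repo_build(rp, "derived", policy = "force_versioned")
  expect_equal(sort(report$name[report$action == "run"]), c("base", "derived"))
  expect_true(repo_has(rp, "base#1"))
  expect_true(repo_has(rp, "derived#1"))
  expect_identical(rp$items[["base#1"]]$checksum, sums1[["base"]])
})

test_that("lazydo caches by exact code text and survives failures", {
  rp <- new_repo()
  counter <- new.env(); counter$n <- 0L
  code <- "{ counter$n <- counter$n + 1L; sum(1:10) }"
  v1 <- repo_lazydo(rp, code)
  expect_equal(v1, 55)
  expect_equal(counter$n, 1L)
  v2 <- repo_lazydo(rp, code)
  expect_equal(v2, 55)
  expect_equal(counter$n, 1L)         # cache hit: not re-evaluated
  # cached as a hidden stash item
  key <- grep("^lazydo_", names(rp$items), value = TRUE)
  expect_length(key, 1)
  expect_true(all(c("stash", "hidden") %in% rp$items[[key]]$kind_flags))

  v3 <- repo_lazydo(rp, paste0(code, " "))  # whitespace change = new key
  expect_equal(counter$n, 2L)
  expect_equal(v3, 55)

  bad <- "{ counter$n <- counter$n + 1L; stop('boom') }"
  expect_error(repo_lazydo(rp, bad), "boom")
  expect_error(repo_lazydo(rp, bad), "boom")  # failure cached nothing
  expect_equal(counter$n, 4L)
})
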
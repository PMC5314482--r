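test_that("put/get round-trips values and records full metadata", {
  rp <- new_repo()
  m <- matrix(rnorm(12), 3, 4)
  rec <- repo_put(rp, m, "mat", "a small matrix", tags = c("demo", "matrix"),
                  url = "https://example.org/mat")
  expect_identical(repo_get(rp, "mat"), m)
  expect_equal(rec$dims, c(3L, 4L))
  expect_match(rec$checksum, "^[0-9a-f]{32}$")
  expect_equal(rec$size_bytes,
               file.info(file.path(repo_root(rp), rec$payload_path))$size)
  expect_error(repo_get(rp, "absent"), class = "datarepo_unknown_item")
})

test_that("mandatory annotations are enforced", {
  rp <- new_repo()
  expect_error(repo_put(rp, 1, "a", description = "", tags = "t"),
               class = "datarepo_bad_argument")
  expect_error(repo_put(rp, 1, "a", description = "ok", tags = character()),
               class = "datarepo_bad_argument")
  expect_error(repo_put(rp, 1, "", description = "ok", tags = "t"),
               class = "datarepo_bad_argument")
})

test_that("relation hygiene: dangling, self and duplicate references rejected", {
  rp <- new_repo()
  repo_put(rp, 1, "a", "first", tags = "t")
  expect_error(repo_put(rp, 2, "b", "second", tags = "t", depends = "nope"),
               "nope", class = "datarepo_unknown_item")
  expect_error(repo_put(rp, 2, "b", "second", tags = "t", depends = c("a", "a")),
               class = "datarepo_bad_argument")
  expect_error(repo_set(rp, "a", depends = "a"),
               class = "datarepo_bad_argument")
})

test_that("replace policies: forbid errors, overwrite keeps identity", {
  rp <- new_repo()
  r1 <- repo_put(rp, 1, "a", "v1", tags = "t")
  expect_error(repo_put(rp, 2, "a", "v2", tags = "t"),
               class = "datarepo_collision")
  r2 <- repo_put(rp, 2, "a", "v2", tags = "t", replace = "overwrite")
  expect_identical(repo_get(rp, "a"), 2)
  expect_identical(r2$created_at, r1$created_at)
  expect_identical(r2$payload_path, r1$payload_path)
  expect_equal(length(rp$items), 1)
})

test_that("addversion preserves history as hidden numbered items", {
  rp <- new_repo()
  repo_put(rp, "v1", "a", "first", tags = "t")
  for (k in 1:10) {
    repo_put(rp, paste0("v", k + 1), "a", "next", tags = "t", replace = "addversion")
  }
  expect_true(all(vapply(paste0("a#", 1:10), repo_has, TRUE, repo = rp)))
  expect_identical(repo_get(rp, "a"), "v11")
  for (k in 1:10) expect_identical(repo_get(rp, paste0("a#", k)), paste0("v", k))
  v1 <- rp$items[["a#1"]]
  expect_true(all(c("versioned", "hidden") %in% v1$kind_flags))
  expect_equal(v1$version_of, list(base = "a", n = 1L))
  # versions are hidden from default listings
  expect_identical(repo_list(rp)$name, "a")
})

test_that("attachments copy bytes verbatim and can chain", {
  rp <- new_repo()
  repo_put(rp, 1:5, "data", "host item", tags = "t")
  f <- withr::local_tempfile(fileext = ".pdf")
  bytes <- as.raw(sample(0:255, 300, replace = TRUE))
  writeBin(bytes, f)
  rec <- repo_attach(rp, f, "a figure", tags = "visualization", to = "data")
  expect_identical(repo_get(rp, basename(f)), bytes)
  expect_true(all(c("attachment", "hidden") %in% rec$kind_flags))
  expect_identical(rec$attached_to, "data")

  f2 <- withr::local_tempfile(fileext = ".pdf")
  writeBin(as.raw(1:10), f2)
  rec2 <- repo_attach(rp, f2, "plot of a plot", tags = "visualization",
                      to = basename(f))
  expect_identical(rec2$attached_to, basename(f))
  expect_error(repo_attach(rp, f2, "bad", tags = "t", to = "ghost", name = "x"),
               class = "datarepo_unknown_item")
})

test_that("set updates annotations, payload only on request", {
  rp <- new_repo()
  repo_put(rp, 1:3, "a", "first", tags = "t")
  before <- rp$items[["a"]]$checksum
  repo_set(rp, "a", url = "https://host/data/a", tags = c("t", "u"))
  rp2 <- repo_open(repo_root(rp))      # persisted
  expect_identical(rp2$items[["a"]]$url, "https://host/data/a")
  expect_identical(rp2$items[["a"]]$checksum, before)

  repo_set(rp, "a", value = 4:6)
  expect_identical(repo_get(rp, "a"), 4:6)
  expect_false(identical(rp$items[["a"]]$checksum, before))
  expect_error(repo_set(rp, "absent", url = "x"), class = "datarepo_unknown_item")
})

test_that("rm removes record and payload; references become dangling", {
  rp <- new_repo()
  repo_put(rp, 1, "a", "first", tags = "t")
  repo_put(rp, 2, "b", "second", tags = "t", depends = "a")
  path_a <- file.path(repo_root(rp), rp$items[["a"]]$payload_path)
  repo_rm(rp, "a")
  expect_false(repo_has(rp, "a"))
  expect_false(file.exists(path_a))
  g <- repo_graph(rp)
  expect_equal(g$dangling$from, "b")
  expect_equal(g$dangling$missing, "a")
  # removed payload no longer subject to integrity checking
  expect_true(all(repo_check(rp)$status == "ok"))
})

test_that("stash stores without metadata and clears in bulk", {
  rp <- new_repo()
  repo_put(rp, 1, "real1", "kept", tags = "t")
  repo_put(rp, 2, "real2", "kept", tags = "t")
  repo_put(rp, 3, "real3", "kept", tags = "t")
  repo_stash(rp, 10, "tmp1")
  repo_stash(rp, 20, "tmp2")

  expect_false("tmp1" %in% repo_list(rp)$name)
  expect_true("tmp1" %in% repo_list(rp, include_hidden = TRUE)$name)
  expect_error(repo_stash(rp, 5, "real1"), class = "datarepo_collision")
  # restashing under the same name is quick storage, not a collision
  repo_stash(rp, 99, "tmp1")
  expect_identical(repo_get(rp, "tmp1"), 99)

  expect_equal(repo_stash_clear(rp), 2)
  expect_equal(sort(names(rp$items)), c("real1", "real2", "real3"))
  expect_equal(repo_stash_clear(rp), 0)
})

test_that("a failed put leaves index and disk state unchanged", {
  rp <- new_repo()
  repo_put(rp, 1, "a", "first", tags = "t")
  snapshot <- rawToChar(datarepo:::serialize_index(rp$items))
  expect_error(repo_put(rp, 2, "b", "bad", tags = "t", depends = "ghost"),
               class = "datarepo_unknown_item")
  expect_identical(rawToChar(datarepo:::serialize_index(rp$items)), snapshot)
  on_disk <- repo_open(repo_root(rp))
  expect_true(datarepo:::index_equal(on_disk$items, rp$items))
})

test_that("info reports payload details and recomputable MD5", {
  rp <- new_repo()
  repo_put(rp, matrix(1:6, 2), "m", "matrix", tags = "t")
  inf <- repo_info(rp, "m")
  path <- file.path(repo_root(rp), inf$payload_path)
  expect_identical(inf$checksum, unname(tools::md5sum(path)))
  expect_equal(inf$dims, c(2L, 3L))
  expect_equal(inf$size_bytes, file.info(path)$size)

  empty <- repo_info(new_repo())
  expect_equal(empty$n_items, 0)
  expect_equal(empty$total_bytes, 0)
})

test_that("projects collect members, runtime version and libraries", {
  rp <- new_repo()
  repo_project(rp, "proj1", "first project")
  repo_project(rp, "proj2", "second project")
  expect_error(repo_project(rp, "proj1", "dup"), class = "datarepo_collision")

  expect_length(repo_info(rp, "proj1")$members, 0)

  repo_options(rp, default_project = "proj1")
  repo_put(rp, 1, "a", "item", tags = "t")
  repo_put(rp, 2, "b", "item", tags = "t")
  repo_put(rp, 3, "c", "item", tags = "t", project = "proj2")

  i1 <- repo_info(rp, "proj1")
  i2 <- repo_info(rp, "proj2")
  expect_setequal(i1$members, c("a", "b"))
  expect_setequal(i2$members, "c")
  expect_length(intersect(i1$members, i2$members), 0)
  expect_match(i1$rversion, "^R version")
  expect_true("datarepo" %in% i1$libraries)
})

test_that("item stats: fractions sum to one, sizes match the filesystem", {
  rp <- new_repo()
  expect_equal(nrow(repo_stats(rp)), 0)

  repo_put(rp, as.raw(1:100), "x", "blob", tags = "t")
  repo_put(rp, as.raw(1:100), "y", "blob", tags = "t")
  st <- repo_stats(rp)
  expect_equal(st$fraction, c(0.5, 0.5))

  rp2 <- repo_example(withr::local_tempdir("fx"), seed = 3)
  st2 <- repo_stats(rp2)
  expect_equal(sum(st2$fraction), 1, tolerance = 1e-9)
  fs_sizes <- vapply(rp2$items, function(r) {
    file.info(file.path(repo_root(rp2), r$payload_path))$size
  }, 0)
  expect_equal(sum(st2$size_bytes), sum(fs_sizes))
  expect_true(all(diff(st2$size_bytes) <= 0))
})
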
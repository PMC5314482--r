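# datarepo

Data-centered management of analysis pipelines for R.

Bioinformatic analyses rarely grow as tidy chains of well-defined processes:
methods are prototyped, partial results feed back into the code, and the
"pipeline" only stabilizes after the fact. `datarepo` supports that reality by
putting the *data* first. Instead of scattering `saveRDS()` files across
directories, every artifact of an analysis — imported tables, filtered
matrices, figures, the source code itself — is stored in a self-contained
repository with mandatory annotations: a name, a free-text description, and a
set of tags (tags generalize directories: they identify possibly overlapping
sets of items). The data flow is then *reconstructed a posteriori* from three
typed relations recorded per item:

* **depends on** — the items an item was computed from,
* **generated by** — the stored source file whose code produced it,
* **attached to** — the item a generic file (e.g. a figure) belongs with.

These relations form a directed multigraph over item names; when items are
annotated consistently, that graph *is* the analysis data flow, exportable as
Graphviz DOT. On top of the store the package provides:

* **Integrity** — every payload carries an MD5 checksum; `repo_check()`
  reports `ok` / `missing` / `mismatch` per item, and `repo_get()` refuses
  tampered payloads.
* **Versioning** — storing over an existing name with `replace = "addversion"`
  preserves the old item as hidden `name#1`, `name#2`, …
* **Reproducible builds** — regions of a stored source file delimited by
  `## chunk "<item name>"` / `## chunk end` markers are associated with the
  item they generate; `repo_build(rp, target)` runs the required chunks
  recursively, skipping items that already exist, so interrupted pipelines
  resume at the first missing stage (reentrancy). A session policy rebuilds
  everything while preserving previous versions.
* **Exchange** — repositories are relocatable (all paths are relative to the
  root, metadata lives in the single file `repo_index.json`); items can be
  copied between repositories and exported; the index alone can be shared and
  payloads later `repo_pull()`ed from per-item URLs.
* **Memoization** — `repo_lazydo("code")` evaluates code once and caches the
  result in the repository, keyed by the MD5 of the exact code text.

Listing and report functions return tibbles, so results compose with dplyr;
`autoplot(repo_stats(rp))` draws the classic disk-usage pie.

## Worked example

```r
library(datarepo)

rp <- repo_init(file.path(tempdir(), "myrepo"))

tab <- fixture_raw_table(seed = 1)          # synthetic 120 x 8 screen, 10% NA
repo_put(rp, tab, "Mice Cortex", "protein expression levels, cortex samples",
         tags = c("dataset", "mice"), url = "https://example.org/mice/raw.csv")
filtered <- tab[complete.cases(tab), ]
repo_put(rp, filtered, "Mice Cortex notNA", "complete cases only",
         tags = c("dataset", "mice"), depends = "Mice Cortex")

repo_info(rp, "Mice Cortex notNA")
#> Mice Cortex notNA
#>   description: complete cases only
#>   tags:        dataset, mice
#>   dimensions:  53, 11
#>   created:     2026-09-18T00:19:28Z
#>   size:        6.1 kB
#>   path:        data/Mice_Cortex_notNA.bin
#>   MD5:         4f62adf4a0777e2b7c1a02d79ddf6dec
#>   depends:     Mice Cortex
```

53 of the 120 samples are complete (with 10% of cells missing independently,
a row of 8 measurements is complete with probability 0.9^8 ≈ 0.43); the item
records its dimensions, disk footprint, relative payload path, checksum and
its dependency on the full table. Disk usage and integrity:

```r
repo_stats(rp)
#> # A tibble: 2 × 3
#>   name              size_bytes fraction
#> 1 Mice Cortex            13216    0.679
#> 2 Mice Cortex notNA       6245    0.321

repo_check(rp)
#> # A tibble: 2 × 2
#>   name              status
#> 1 Mice Cortex       ok
#> 2 Mice Cortex notNA ok
```

`repo_example()` generates a complete repository emulating a small end-to-end
pipeline (raw CSV attachment with URL → imported matrix → filtered matrix →
scaled replacement with a preserved version → chained figure attachments →
project item → chunk-annotated source), and is what the test suite builds its
oracles from.

A thin command line lives in `inst/cli/datarepo`
(`datarepo init|put|attach|get|ls|info|find|deps|build|check|…`); every
subcommand is a veneer over the functions above.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

rebuilds the example pipeline from its chunk-annotated source alone with the
given seed, verifies integrity, provenance and retrieval on the result, and
writes the results JSON.
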
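---
title: "Data-centered pipeline management with datarepo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-centered pipeline management with datarepo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(datarepo)
```

## The model

`datarepo` implements a *data-centered* approach to pipeline management.
Rather than designing a pipeline up front as a chain of processes, the
package assumes the common exploratory reality of bioinformatic work: data
artifacts accumulate first, and the process structure is worth documenting
only once it stabilizes. The unit of the model is therefore the **item** —
any stored artifact plus mandatory annotations (name, description, tags) —
and the pipeline is an **a posteriori reconstruction** from three typed
relations recorded per item:

| relation     | index field   | meaning                                   |
|--------------|---------------|-------------------------------------------|
| depends on   | `depends`     | items this item was computed from          |
| generated by | `source`      | stored source file whose code produced it  |
| attached to  | `attached_to` | item a generic file belongs with           |

Each recorded relation is one directed edge from the annotated item to the
item it references; `repo_graph()` assembles the multigraph and collects
references to removed items as *dangling* rather than dropping them, since a
missing node is information about the repository's history, not noise.

The key assumption is that annotations are cheap enough to be written as a
side effect of normal work: `repo_put()` replaces `saveRDS()` and takes the
relations as arguments, and `repo_options()` lets a session declare one
default source file and project so repeated calls stay terse. Nothing
enforces that the annotations are *correct* — the model trades enforcement
for zero design overhead, and the build machinery (below) is what makes
annotations checkable after the fact.

## Repository layout and the index

A repository is one directory: payload files under `data/`, and all metadata
in a single JSON document `repo_index.json` with an explicit
`format_version`. Two deliberate choices:

* **Portable text index.** A host-language binary serialization would be
  simpler, but a documented JSON schema makes the index diffable,
  greppable and readable outside R. Unknown future format versions are
  rejected explicitly rather than misparsed.
* **Relative paths only.** Every `payload_path` is relative to the root, so
  repositories relocate and clone with `cp -r`, and the index file alone is
  shareable: all metadata operations (listing, search, graphs) work with
  zero payload files present, `repo_check()` reports every payload
  `missing`, and `repo_pull()` with per-item URLs fills the payloads back
  in. This is the intended distribution mechanism: publish the repository
  directory, hand out the index.

Payload filenames are the sanitized item name (non-alphanumerics to `_`)
plus a numeric de-collision suffix; the index is authoritative and the
naming scheme is internal. `#` is unrepresentable in sanitized names, which
is exactly why superseded versions are named `name#N` — a version name can
never collide with a user name on disk. Index writes are atomic (temp file
plus rename), and any failing store operation materializes its payload bytes
*before* touching the in-memory index, so a failed `repo_put()` leaves the
repository exactly as it was.

Values are serialized with base R `serialize()` (recorded per item as
serializer `"rds"`); attachments are verbatim bytes (`"file"`). The
serializer is recorded per item in the index — an extension beyond the
minimal metadata set, kept because a reader of a shared index otherwise
cannot know how to interpret an exported payload.

Timestamps are ISO-8601 UTC at second resolution; index equality ignores
sub-second differences by construction.

## Tags, search, hiding

Tag queries support three operators — `any`, `all`, `none` — over the
non-hidden items. The operator set is deliberately minimal: it covers the
practical use cases (union browsing, intersection narrowing, and exclusion
such as "the dependency graph without the `visualization` items") without a
boolean expression language. `repo_find()` is case-insensitive fixed
substring match over *all* metadata fields, hidden items included: search
and provenance must see everything, while default listings hide what is
non-current (attachments, stash items, superseded versions — the last is a
package choice: a superseded version is by definition not current, so
listing it by default would bury the live items).

`repo_related()` includes the seed item and defaults to undirected
reachability, because its main use is selecting a self-contained set for
`repo_export()`/`repo_copy()`; `upstream`/`downstream` directed variants are
provided for lineage questions.

## Chunks and builds

A stored source file can associate any contiguous region of its lines with
the item that region generates:

```
## chunk "Mice Cortex"
raw <- repo_get(rp, "mice_cortex.csv")
...
## chunk end
```

The grammar is: a chunk opens at `## chunk "<name>"`, and closes at
`## chunk end`, at the next opener (implicit close), or at end of file. The
explicit closer is a robustness choice — marker-only grammars force the next
opener to end the previous chunk, which silently swallows trailing
non-chunk code. Malformed openers and duplicate chunk names are parse errors
with line numbers.

`repo_plan_build()` walks dependencies recursively and decides `run` versus
`skip`. Under the default `skip_existing` policy an item runs iff it is
absent — no record, or a record whose payload file is missing (the
shared-index case). Present items are listed as skipped, with their
dependencies still shown, so a plan reads as the full pipeline stage by
stage; a plan for an interrupted build therefore skips exactly the completed
stages and reruns the rest (reentrancy).

One design question had no prescribed answer: *where do dependencies come
from for an item that has never been built?* Dependency edges live in item
records, which do not exist yet for never-built items. The package resolves
this statically: for an absent item, every quoted string in its chunk that
names another chunk-annotated or stored item is taken as a dependency. This
matches how chunks naturally reference their inputs (`repo_get(rp, "dep")`),
is deterministic, and requires no grammar extension. Recorded `depends`
remain authoritative whenever the record exists. The inference can
over-approximate (a quoted item name in a comment counts) and cannot see
computed names; both limitations vanish once the item has been built and
carries real metadata.

Execution is injected: the executor is any `function(code, repo)`, the
default evaluating the code in a fresh environment with the handle bound to
`rp`. After each run step the planner's postcondition is enforced — the
step's item must exist with its payload on disk, otherwise the build aborts
with "chunk did not produce its item". This is stricter than strictly
necessary, but it is what makes the claim "this chunk is necessary and
sufficient to build this item" checkable.

Policies map to replacement semantics during the build: `force_versioned`
temporarily sets the session default replace policy to `addversion` (so
unmodified chunk code preserves previous versions), `force_overwrite` and
`skip_existing` use `overwrite` (so a record whose payload went missing can
be re-put without a collision). Dependency cycles are detected at planning
time and reported with the cycle; cycles in metadata alone (among items that
are all present and skipped) are representable and not an error — only a
cycle that must *run* is unsatisfiable.

`repo_lazydo()` keys its cache on the MD5 of the exact code text, with no
normalization: whitespace changes re-evaluate. Normalizing would require a
parser-level equivalence decision with fuzzy edges; exact keying is
predictable and the cost of a spurious miss is one re-computation. Failures
cache nothing.

## Integrity and exchange

All checksums are MD5 over payload bytes (`tools::md5sum`). MD5 is used for
integrity against accidental corruption, not as a cryptographic guarantee.
`repo_get()` verifies before deserializing; `repo_check()` classifies every
item as `ok`/`missing`/`mismatch` and treats problems as data, not errors —
the CLI turns any non-`ok` into a nonzero exit instead.

`repo_pull()` by default *replaces* the payload with whatever the URL serves
(its purpose is updating to the latest upstream content), recomputing the
checksum and reporting the change; `verify = TRUE` inverts the contract and
requires the fetched bytes to match the stored checksum — the right mode
when filling in a shared index. The fetcher is an injected function so tests
never touch the network. URLs assigned by `repo_set_base_url()` join the
base with the URL-encoded *payload filename*, not the item name, so a
published repository tree is directly servable.

## The synthetic example repository

`repo_example()` generates the package's worked pipeline deterministically
from a seed: a 120-sample by 8-column numeric table with two categorical
covariates and a 10% missing-cell rate (standard-normal values), stored as a
CSV attachment with a fake URL; an imported matrix; a complete-cases
filtered matrix; a scaled replacement stored with `addversion`; two chained
figure attachments; a project item; a stash item; and a chunk-annotated
source file from which the data items can be rebuilt end to end. The 120×8
shape and 10% missingness are fixture parameters chosen to keep every test
sub-second while leaving a realistic fraction (~43%) of complete rows; they
are properties of the generator, not claims about any real dataset.

What the generator does *not* emulate: real measurement distributions,
structured missingness (missingness is independent per cell), meaningful
figure content (attachment bytes are opaque), or large payloads. A green
test establishes that the storage, provenance, versioning, build and
exchange semantics hold on this world — not that the package scales to
multi-gigabyte payloads or concurrent writers.

## Degenerate inputs and tie-breaks

* Empty repositories: all listings, graphs, stats and checks return empty
  tibbles/graphs, never errors; `repo_stats()` emits no fractions rather
  than 0/0.
* Version numbers take the smallest positive unused integer, so deleting
  `a#2` and re-versioning reuses the gap.
* Duplicate `depends` entries and self-relations are rejected at
  annotation time; full cycle handling is the planner's job, since cyclic
  metadata is representable.
* Stash items are exempt from the mandatory description/tags rule (that is
  their purpose) and may be silently overwritten by another stash of the
  same name; colliding with a regular item is an error.
* `repo_copy()` under the default `forbid` policy validates all names
  before copying anything, so a collision leaves the destination untouched.

## Known limitations

* Single-writer: index replacement is atomic, but there is no locking for
  concurrent writers.
* Chunk execution is in-process R with no sandboxing; a chunk can do
  anything the session can.
* Dependency inference for never-built items is textual (see above).
* The binary index format of other tools in this space is not read; the
  JSON index is this package's own documented format.
* MD5 integrity detects corruption, not adversarial tampering.
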
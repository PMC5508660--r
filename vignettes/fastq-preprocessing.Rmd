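---
title: "Methods: FASTQ quality control and preprocessing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FASTQ quality control and preprocessing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tidyfastq)
```

## The data model

A FASTQ record is four lines: an `@`-prefixed identifier, the nucleotide
sequence, a `+` separator (optionally repeating the identifier), and a
quality string with one printable ASCII character per base. tidyfastq
represents a read set as a tibble with columns `header`, `sequence`, `plus`
and `quality`; the record invariants — non-empty sequence on ingest, equal
sequence and quality lengths, every quality character decoding to a
non-negative Phred score — are enforced at parse time with errors naming the
1-based record index. Multi-line (wrapped) FASTQ is rejected rather than
supported: the four-line form is the interchange format, and silently
accepting wrapped records invites quality/sequence misalignment.

Two quality encodings are supported, both as explicit choices (never
auto-detected): `sanger` with ASCII offset 33 (Phred range 0–93) and
`illumina` with offset 64 (0–62). The `illumina` option means offset-64
*Phred* scores; the older Solexa odds-ratio scale, which differs below
Q ≈ 10 and needs a different transform, is deliberately not implemented. A
quality character that falls below the active offset aborts with a message
suggesting the other encoding, because that is almost always the actual
mistake.

## Phred scores and error probabilities

The Phred score is logarithmic in the base-calling error probability:
$Q = -10\log_{10} P$, equivalently $P = 10^{-Q/10}$. Both directions are
exposed (`phred_to_error()`, `error_to_phred()`); they are mutual inverses
to well below 1e-9 across the full representable range, which the test
suite checks on a dense grid over $Q \in [0, 93]$.

Per read, two averages are computed and kept distinct on purpose:

* `mean_phred` — the arithmetic mean of the per-base $Q$ values. This is
  the quantity the quality filter thresholds, matching the plain reading of
  "average Phred score".
* `mean_error_prob` — the arithmetic mean of the per-base $P$ values,
  **not** $10^{-\bar Q/10}$. Averaging probabilities weights bad bases far
  more heavily; since $10^{-q/10}$ is convex, Jensen's inequality gives
  `mean_error_prob >= phred_to_error(mean_phred)` for every read, and the
  tests assert exactly that, which pins the averaging order against
  accidental refactoring.

GC percent is $100 \times (\#G + \#C)/\text{length}$, case-insensitive,
with ambiguous characters counting toward the denominator only.

Summary tables report min/max/mean of read length, GC percent, mean Phred
and mean error probability, with the mean unweighted per read (a 25-base
read counts as much as a 100-base one — the summary describes reads, not
bases). Rendering uses two decimal places for lengths, GC and Phred, and
3-significant-digit scientific notation for error probabilities, whose
natural scale is logarithmic; empty read sets render as `NA`.

## Filters

All filters keep survivors in input order and are idempotent.
Thresholds are strict-below-removes: a read exactly at `qf` or `lf` is
kept. Duplicate identity is the sequence string alone, compared
case-insensitively — not sequence+quality and not the header — and the
*first* occurrence is retained. Retaining the best-quality copy instead
would be defensible, but first-occurrence is deterministic, order-preserving
and cheap in a streaming setting; the choice is documented rather than
configurable. The ambiguous-base filter removes any read containing a
character other than A/C/G/T (either case): N, IUPAC ambiguity codes and
gap characters all disqualify.

Duplicate detection keeps an in-memory hash of uppercased sequences, so its
memory grows with the number of distinct sequences. The contract is
deterministic output, not bounded memory; for files whose distinct-sequence
set does not fit in RAM a disk-backed structure would be needed, which is
out of scope.

## Trimming and adapter stripping

Fixed end-trims remove `n` bases and the same count of quality characters
from the chosen end, saturating at the read length. Left- and right-trims
commute whenever the two amounts fit in the read, and the sequence/quality
length equality is preserved by construction after every operation.

Adapter stripping is *anchored*: the adapter is compared, exactly once,
against the terminal window of the read — the first (or last)
`nchar(adapter)` bases. The window matches when its Hamming distance to the
adapter is at most the mismatch budget; `N` in the read counts as a
mismatch to every adapter base; comparison is case-insensitive. Matched
windows are removed with their quality characters. Three deliberate
restrictions follow from the anchored design:

* interior adapter occurrences are not searched for;
* partial overhangs (adapter hanging off the read end) are not matched —
  reads shorter than the adapter never match;
* stripping happens once per read per side; tandem copies lose one copy
  per invocation.

The mismatch budget must be strictly smaller than the adapter length
(otherwise every window matches). `enumerate_mismatch_variants()` makes the
combinatorics inspectable: there are $\binom{L}{k}\,3^k$ sequences at
exactly $k$ mismatches from an $L$-base adapter, and the tests verify on
all 4-mers that the distance test and the enumeration define the same
acceptance set.

## The pipeline

`run_pipeline()` chains the enabled stages into one filtered file, in a
fixed canonical order:

1. left adapter strip, 2. right adapter strip, 3. left trim, 4. right trim,
5. zero-length drop, 6. ambiguous-base filter, 7. quality filter,
8. length filter, 9. duplicate removal.

The order matters and is a design choice: adapters sit outside the insert,
so they come off first; quality and length are then judged on the post-trim
read — the sequence that actually survives to downstream use — and
deduplication sees final sequences, so two reads that become identical
after trimming are treated as duplicates. Reads trimmed to zero length are
dropped silently but counted in their own `zero_length` stage, keeping the
conservation identity `input = output + sum(per-stage removals)` exact,
which the tests re-verify on every run.

Transforms (`fasta`, `rev_comp`, `rna`) are not part of the filter chain:
each writes its *own* new file, derived from the filtered output, and
multiple transform flags run independently. Reverse complement maps every
IUPAC code to its complement (case preserved) and reverses the quality
string in step, so each base keeps its own quality; DNA-to-RNA is the
T→U/t→u substitution only. When a run enables no filter and exists only to
feed transforms, the staging filtered file is recorded as an intermediate
and `-clean` (or `cleanup_temp()`) deletes it; inputs and final outputs are
never deleted, and deletion failure warns rather than aborts.

Processing streams in chunks (default 10,000 records) through a connection:
peak memory is bounded by the chunk size, summaries accumulate running
min/max/sum/count, and dedup state persists across chunks, so a chunked run
is byte-identical to a single-chunk run — a property the tests check
directly. Logging goes to standard error; the summary table to standard
output, so it can be piped.

The command-line front end mirrors the library one-to-one
(`-lib -path -i -smry -qf -lf -trim_l -trim_r -adpt_l -adpt_r -mis_l
-mis_r -dup -no_n -fasta -rev_comp -rna -clean`), accepts single- or
double-dash forms and `-flag=value`, defaults `mis_l`/`mis_r` to 0 when the
adapter is given, and rejects them without it. Exit codes: 0 success,
2 usage error, 1 runtime error.

## The synthetic-read simulator

`simulate_fastq()` generates the fixtures every test runs on, with planted
(not post-hoc counted) ground truth: exact duplicate copies appended after
their originals, reads carrying 1–3 `N` bases, and adapter copies
prepended or appended with profile-drawn qualities, each recorded per read
in a manifest. Defaults emulate a realistic short-read library: lengths
uniform on 25–100 bases, per-position mean quality decaying linearly from
38 at 0.1 Phred per position — the monotone quality decay seen along real
reads — with Gaussian jitter (sd 3), rounded and clamped to [2, 40].
Identical seeds give byte-identical files.

What the simulator does *not* emulate bounds what green tests prove:
sequences are uniform random (no genomic composition, no GC bias), errors
are not modelled as substitutions or indels coupled to the quality values,
duplicates are exact copies rather than PCR-family near-duplicates, and
qualities are position-independent draws around the profile. Passing tests
demonstrate that the filters, trimmers and bookkeeping implement their
definitions exactly on valid FASTQ; they say nothing about, for example,
adapter detection sensitivity under sequencing error beyond the explicit
Hamming budget.

## Numerical and degenerate-input choices

* Quality decoding is exact integer arithmetic; no floating-point enters
  until means are taken.
* Empty read sets summarise to `read_count` 0 with `NA` fields; empty
  writes produce empty files with count 0.
* Zero-length records exist only transiently inside the pipeline (between
  trimming and the zero-length drop); ingest rejects them.
* Gzip input/output is keyed on the `.gz` suffix; CRLF input is accepted,
  output is always UNIX newlines.
* Test and acceptance problem sizes — 400 to 3,000 simulated reads per
  fixture — were chosen as the smallest sets at which every planted rate
  yields double-digit planted counts; all checks there are exact, so
  larger sizes add runtime without adding discrimination.

## Known limitations

Paired-end synchronisation, quality-based (sliding-window) trimming,
floating or overlap-aware adapter alignment, near-duplicate collapsing and
encoding auto-detection are out of scope. The canonical stage order is
fixed; a pipeline needing, say, quality filtering on the untrimmed read
must call the filter functions directly in the order it wants — the
building blocks compose freely even though the CLI order does not.
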
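---
title: "Multi-allelic positional Burrows-Wheeler transforms: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-allelic positional Burrows-Wheeler transforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpbwt)
```

## The problem

A phased haplotype panel is an `M x N` matrix `x` of allele codes: `M`
haplotypes (two per diploid sample), `N` variant sites in chromosomal order.
Long identical segments shared between two haplotypes are candidate
identity-by-descent (IBD) segments, and finding all of them naively costs
`O(M^2)` pairwise scans. The positional Burrows-Wheeler transform (PBWT)
avoids that by maintaining, site by site, the permutation of haplotypes
sorted by their *reversed prefix* — at position `k`, the string
`x[i][k-1], x[i][k-2], ..., x[i][0]`. In this order, haplotypes sharing a
long segment ending at `k` are adjacent, so matching becomes a linear scan,
and the reordered panel becomes highly run-length compressible wherever
nearby sites are correlated (linkage disequilibrium).

The classical formulation assumes bi-allelic sites (codes 0/1). Real panels
increasingly contain sites with three or more alleles — multi-allelic SNPs
and discretized copy-number classes — and this package implements the PBWT
machinery for an arbitrary per-site alphabet of `t_k` allele codes
`0 .. t_k - 1`, together with two corrections that matter in practice:
matches that run to the end of the panel (including fully identical
haplotypes) are reported, and set-maximal matches ending at the last site
are handled by a dedicated final pass.

All coordinates in the package are 0-based with half-open intervals
`[start, end)`. This matches the index arithmetic of the algorithms (a match
"ending at k" mismatches exactly at site `k`) and avoids the off-by-one
ambiguity that 1-based inclusive intervals invite.

## Prefix and divergence arrays

The state at position `k` is the prefix array `a_k` (the permutation of
`0..M-1` in reversed-prefix order) and the divergence array `d_k`, where
`d_k[i]` is the site at which the maximal match between the haplotypes at
sorted positions `i` and `i-1` begins; equivalently, `k - d_k[i]` is the
longest common suffix length of their `k`-prefixes. `d_k[0]` carries the
sentinel value `k` ("no neighbor above"), which makes every block scan
terminate at position 0 without special-casing.

One sweep step from `k` to `k+1` is a stable counting sort of `a_k` keyed on
the panel column at `k`: one bucket per allele, ascending code order,
within-bucket order preserved. Stability is not optional — it is exactly
what makes the concatenated buckets sorted by the *extended* reversed
prefix, and it pins a unique, reproducible order. Divergence values travel
through the sort with a per-allele pending value `p[l]`, initialized to
`k+1` at the start of the step, raised to every divergence value seen while
scanning, and reset to 0 when allele `l` receives a haplotype. The cost is
`O(t_k + M)` per site for the prefix array alone and `O(t_k * M)` with
divergence updates.

Bucket workspaces are sized to the site's own `t_k`, so a panel that is
mostly bi-allelic with occasional 10-allelic sites pays the 10-way cost only
where it occurs. A site's alphabet may exceed its observed codes (a declared
ALT allele nobody carries) but never be smaller; violations fail fast with
the offending site index.

The sweep core is compiled (Rcpp), which is the norm for PBWT
implementations; everything else — I/O, containers, oracles, simulation —
is R.

### Correctness strategy

The published pseudocode for these algorithms is distributed across figures
that do not survive text extraction, so the package treats brute force as
the specification: `oracle_sort()` sorts reversed-prefix strings explicitly
and computes divergences as longest common suffixes; `oracle_matches()`
scans every pair for maximal agreement runs; `oracle_set_maximal()`
enumerates and filters shared segments per query. The test suite asserts
exact equality of the sweep outputs against these oracles on hundreds of
seeded random panels (`M <= 30`, `N <= 60`, `t` up to 10, every `L`), and
separately asserts exact equality with an independently coded classical
bi-allelic implementation (`durbin_build()` and friends, written in the
two-bucket `u`/`v`, `p`/`q` style) on strictly bi-allelic panels. The
divergence-update order relative to bucket placement is therefore validated
behaviorally rather than transcribed.

## Matching

### All pairs of length at least L

`find_long_matches()` reports every maximal shared segment of at least `L`
sites between every pair, in one sweep. At interior position `k`, haplotypes
whose current match is still long enough form blocks of consecutive sorted
positions not separated by `d_k[i] > k - L`; within a block, the start of a
pair's match is the running maximum of the divergence values between the two
sorted positions, and a pair is reported exactly when its two alleles at `k`
differ (the match terminates). A block produces output only when at least
two distinct alleles occur in it, tracked with a seen-allele table and a
counter rather than pairwise flag comparisons. The block that reaches `i =
M-1` without a separator is flushed through the same machinery via a
virtual boundary.

The last site is different: a match can end there by mismatch *or* by
running out of panel. Blocks are therefore formed at the relaxed threshold
`k - L + 1`, and the alleles at the last site arbitrate: agreeing pairs are
emitted with `end = N`, disagreeing pairs only if the segment before the
last site already has length `L`. This is what guarantees that two identical
haplotypes yield their `[0, N)` record — the case a purely
mismatch-terminated definition silently drops.

Two phrasings, "greater than L" and "at least L", circulate for this
operation. The package reports matches of length `>= L`, consistent with
the last-site length check and with the classical released implementation;
the choice is visible in `?find_long_matches`.

### Set-maximal matches

A set-maximal match of query haplotype `q` is a shared segment `[k1, k)`
with some other haplotype that cannot be extended in either direction and is
not dominated — no haplotype matches `q` on a longer interval ending at the
same position, nor on an equal-start interval that continues through `k`.
At each position the candidates are the query's sorted neighbors within the
equal-start divergence range; if any of them carries the query's allele at
`k` the match extends and nothing is reported for `q` there, otherwise all
neighbors attaining the minimal start are reported (ties on both sides
included). A final pass over the state at `N` reports each haplotype's
longest matches running to the panel end. Zero-length "matches" (a
first-site mismatch) are never reported.

Records are *per query* — `hap_i` is the query — so a mutual longest match
legitimately appears twice; `canonicalize_matches()` collapses the output to
the unordered pair set when that is wanted. Interior positions use the
neighbor-scan generalized to `t` alleles; since the original interior
pseudocode is omitted in the source material, its behavior is pinned
entirely by the exhaustive per-query oracle.

## Compression

`pbwt_transform()` produces, per site, `y_k` — the panel column gathered
through `a_k` (`y_k[i] = x[a_k[i]][k]`) — along with per-allele counts
`c_k(l)`, occurrence checkpoints, and stored prefix arrays every
`checkpoint_stride` sites. The extension function

```
w_k(i, l) = Occ_k[l][i] + CC_k(l - 1),    CC_k(l) = c_k(0) + ... + c_k(l)
```

is the positional analog of FM-index LF-mapping and satisfies
`a_{k+1}[w_k(i, y_k[i])] = a_k[i]`, so the whole family of prefix arrays —
and from them the original panel — is recoverable from the `y` columns
alone. `pbwt_reconstruct()` does exactly that, scattering `y_k` through the
running prefix array and advancing it with the (vectorized) extension
function; corruption surfaces as counts that do not sum to `M` or an
extension that is not a permutation.

Storage choices follow standard FM-index practice rather than dense
matrices. `Occ` is checkpointed every `occ_stride = 64` sorted positions
(dense `M x t` occurrence tables would dwarf the panel) with scanning
between checkpoints; `c` omits the last allele's count, recoverable as `M`
minus the rest; divergence arrays are *not* stored, because query search
inside the compressed panel — the one feature that needs them — is out of
scope here. The container (`pbwt_encode()` / `pbwt_decode()`) is
deliberately boring: magic bytes `MPBWT`, a version byte, then a single
little-endian varint stream holding the header, run-length encoded `y`
columns, counts, and checkpoints. Byte-level determinism is part of the
contract and is tested, so identical panels always produce identical
containers.

Why this compresses: under linkage disequilibrium, haplotypes adjacent in
reversed-prefix order tend to agree at the next site, so `y_k` has long
runs. On panels with independent sites the sorted and raw column orders are
statistically indistinguishable under the same codec — the transform cannot
manufacture structure that is not there — and the test suite asserts both
directions (a strict gain on block-correlated panels, a paired
no-difference test on independent ones).

## The simulator

`simulate_panel()` emulates the structure of coalescent-simulated panels at
desk scale without an external simulator: a founder haplotype drawn with
per-site derived-allele frequencies uniform on `base_maf = (0.05, 0.5)`,
then each new haplotype copying geometric-length blocks (mean
`block_length`) from previously generated haplotypes with per-site copy
error `mut_rate`. Copying the same template across adjacent sites is what
induces LD; `block_length = 1` removes it while keeping everything else
fixed. `multiallelify()` reproduces the multi-allelic conversion used in the
source experiments: at a seeded random fraction of sites (30% in those
experiments), the carriers of one allele are reassigned codes drawn
uniformly from the target alphabet and the site's declared alphabet becomes
`target_t`. How the new codes should be distributed is not specified in the
source; uniform assignment is this package's choice.

LD is summarized by `adjacent_site_correlation()`, the mean squared
correlation (r²) between adjacent columns. The *signed* correlation is the
wrong summary here: allele labels are arbitrary and variant clades at
different sites may be nested or disjoint, so signed values average to zero
even under strong structure. r² is the field's standard, and its
independent-sites null is about `1/(M-1)`, which is what the simulator's
`block_length = 1` regime is tested against.

What the simulator does *not* reproduce: recombination maps, demographic
history, realistic allele-frequency spectra, and the mutation-sharing depth
of a true coalescent — its LD (adjacent-site r² around 0.02 at `M = 200`)
is block-mosaic structure, not genealogical structure. Passing tests on
these panels therefore demonstrate algorithmic correctness and the
direction of the compressibility effect, not the compression ratios
achievable on real cohort data (which are typically far larger, because
real panels have long stretches of rare variation).

## Validation problem sizes

The shipped tests compare against oracles on 200 random panels spanning
`M ∈ 2..30`, `N ∈ 1..60`, `t ∈ {2,3,5,10}` with every `L`, round-trip 100
panels up to `M = 200`, `N = 500`, `t = 10`, and measure runtime scaling on
uniform panels up to `M = 4000` haplotypes and `N = 5000` sites — sizes at
which the sweep's near-linear growth in `M` and `N` is clearly measurable
(log-log slopes close to 1) while the whole suite stays comfortably
interactive. `scripts/acceptance.R` recomputes the same quantities from
scratch under a caller-supplied seed.

## Known limitations

- Query search against a compressed panel (and hence compressed divergence
  arrays) is not implemented.
- Genotype error breaks exact matching, as in any exact PBWT; no
  error-tolerant heuristics are provided.
- Unphased genotypes are rejected — the transform is defined on haplotypes.
  Missing VCF genotypes are either rejected (default) or coded as an extra
  allele per site (`missing_policy = "extra_allele"`), in which case match
  semantics across missing sites are the user's responsibility: a shared
  "missing" code counts as agreement.
- Haplotype order for diploid samples is left-then-right of the phase
  separator; there is no universal convention.
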
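# amyloidscreen

Geometric screening of protein structures for amyloid-like parallel
beta-sheet architecture, from C-alpha coordinates alone.

Amyloid fibrils are insoluble aggregates of many distinct polypeptide
chains stacked into near-parallel beta-sheets (cross-beta architecture,
inter-strand spacing ≈ 4.8 Å). Annotation of such entries is uneven —
most were solved by solid-state NMR — so this package classifies
structures purely geometrically. It is aimed at structural
bioinformaticians who want to pull amyloid and amyloid-like entries out
of a set of PDB/mmCIF files, or to probe borderline structures with
adjustable thresholds.

## The rules

For every ordered pair of beta-sheet chains (A, B), with
d(i) = min_j ‖CA_i(A) − CA_j(B)‖ the minimum cross-chain C-alpha
distance profile, a structure is called amyloid-like iff some maximal
contiguous fragment F of some chain A satisfies:

* **(a) parallelism** — every d(i) in F lies in [2, 15] Å and
  σ(d over F) ≤ 1.5 Å;
* **(b) low curvature** — the pseudo-bond angles θ(CA_{i−1}, CA_i,
  CA_{i+1}), averaged over F, lie in [110°, 180°] (extended strands
  average ≈ 127°, helices ≈ 90°);
* **(c) relative length** — len(F) ≥ len(A) / 7, in residues of the full
  deposited chain.

Structures with fewer than two protein chains are negative by
construction: isolated hairpins and single-chain beta-barrels are
self-parallel but are not aggregates of distinct chains.

## Worked example

```r
library(amyloidscreen)

# a 2-chain synthetic cross-beta stack, 14 residues/chain, no noise
fib <- make_cross_beta(fibril_spec(n_chains = 2, n_residues = 14))
screen_structure(fib)
#> <ScreenResult crossbeta: AMYLOID-LIKE>
#>   chains: 2 (2 sheet-qualifying), ordered pairs: 2
#>   fragments passing all rules: 2
#>   windows rejected: rule-a-empty pairs 0, rule b 0, rule c 0
#>   source_chain_id target_chain_id start end length start_auth end_auth
#> 1               A               B     0  13     14          1       14
#> 2               B               A     0  13     14          1       14
#>          sigma d_lo d_hi mean_theta
#> 1 2.313652e-15  4.8  4.8   126.9493
#> 2 2.313652e-15  4.8  4.8   126.9493
```

Both ordered chain pairs yield one fragment spanning all 14 residues:
the distance profile is constant at the 4.8 Å stack spacing (σ ≈ 0,
far below the 1.5 Å cap) and the mean pseudo-bond angle is the ideal
extended-strand 126.9°, inside [110°, 180°]. A two-helix bundle, by
contrast, passes rule (a) but is rejected by rule (b):

```r
hx <- make_helix_bundle(n_chains = 2, n_residues = 20)
screen_structure(hx, sheet_config = sheet_call_config("none"))
#> <ScreenResult helixbundle: negative>
#>   chains: 2 (2 sheet-qualifying), ordered pairs: 2
#>   fragments passing all rules: 0
#>   windows rejected: rule-a-empty pairs 0, rule b 5, rule c 0
```

Batch screening of a directory, from R or the shell:

```r
scan_structures(list.files("structures/", full.names = TRUE), "out/")
# writes out/amyloid_list.txt, out/fragments.tsv, out/manifest.json
```

```sh
Rscript inst/cli/amyloidscreen.R scan --in structures/ --out out/
Rscript inst/cli/amyloidscreen.R classify structures/entry.cif
Rscript inst/cli/amyloidscreen.R simulate cross-beta --chains 5 --residues 14 --out fib.pdb
Rscript inst/cli/amyloidscreen.R fetch --ids 2KIB,2N0A --cache pdb_cache/
```

All thresholds are exposed (`--sigma-max`, `--d-min`, `--d-max`,
`--theta-min`, `--theta-max`, `--ratio-divisor`, `--sheet-mode`,
`--std`), mirroring `rule_params()` and `sheet_call_config()`.

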
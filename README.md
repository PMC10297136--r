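# mbfpath

De novo discovery of cancer driver pathways from somatic mutation data.

## What it does

Tumor cohorts can be summarized as a binary matrix `A` (m patients × n
genes, `A[i,j] = 1` if gene j is somatically mutated in patient i). Genes
belonging to one driver pathway leave a characteristic footprint in that
matrix: together they cover most patients (**high coverage**) while rarely
being co-mutated in the same patient (**high mutual exclusivity**), because
one driver hit per pathway is usually enough. `mbfpath` finds size-k gene
sets maximizing the covariate-weighted maximum weight submatrix score

```
W_v(M) = 2·|Γ(M)| − Σ_{j∈M} v_j·|Γ(j)|
```

where `Γ(M)` is the set of patients with ≥ 1 mutation in `M` and `v_j` is a
positive per-gene **fusion covariate** discounting genes with high expected
background mutability. `v` is the leading principal component of three
z-scored gene covariates — expression level, replication time, and
chromosome status — rescaled to [0.5, 1.5] (`v ≡ 1` when no covariates are
supplied). The NP-hard maximization over k-subsets is performed by a
**Mouth Brooding Fish (MBF)** population metaheuristic (attraction of a
school toward the incumbent "mother" plus dispersal probes of her swap
neighborhood; parameters SP = 0.6, nFish = 50, Dis = 1.8, Pdis = 0.2,
SPdamp = 0.95), validated against an exhaustive-search oracle on small
instances. Significance of an identified pathway is assessed by a
**permutation test**: each gene column is shuffled across patients
(preserving per-gene mutation rates, destroying between-gene structure)
and the matrix re-optimized, with the plus-one p-value estimator and
α = 0.05.

Intended users: computational cancer-genomics researchers who have a
preprocessed 0/1 mutation matrix (and optionally per-gene covariates) and
want candidate driver gene sets without relying on curated pathway
databases.

## Worked example

Plant a 4-gene pathway covering ~80% of 200 patients inside background
noise, then recover and test it:

```r
library(mbfpath)

sim <- planted_matrix(m = 200, n = 100, k_planted = 4,
                      coverage = 0.8, co_mutation_rate = 0.05,
                      background_rate = 0.02, seed = 101)
colnames(sim$matrix)[sim$planted]
#> [1] "G026" "G037" "G091" "G097"

res <- mbf_optimize(sim$matrix, k = 4, params = mbf_params(seed = 1))
res
#> pathway_result (k = 4): G026 G037 G091 G097
#>   weight 155.000 | coverage 0.835 | mutex 0.775 | p (untested)

res <- permutation_test(sim$matrix, res,
                        config = perm_config(n_permutations = 100, seed = 1),
                        params = mbf_params(seed = 1))
res$p_value
#> [1] 0.00990099
```

The optimizer recovers exactly the planted genes. The set covers 167 of
200 patients (coverage 0.835), and 155 of them carry exactly one mutation
in the set (mutex degree 0.775), so the weight is
`2·167 − 179 = 155` — coverage large, co-occurrence penalty small.
The p-value 1/101 is the smallest value 100
permutations can resolve: no permuted cohort produced any 4-gene set as
heavy as the planted one.

With real data, read the matrix and covariates from TSV and scan a range
of pathway sizes:

```r
mat <- read_mutation_matrix("cohort.tsv")          # dense or sparse TSV
fus <- fuse_covariates(read_covariates("covariates.tsv"))
scan <- multi_k_scan(mat, k_range = 3:10, covariates = fus,
                     params = mbf_params(seed = 1))
as.data.frame(scan)
write_results(scan, "pathways.json", format = "json")
```

The same pipeline is available from a shell via the thin CLI wrapper:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/mbfpath", package = "mbfpath"))')
Rscript "$CLI" find --matrix cohort.tsv --covariates covariates.tsv \
        --k-range 3:10 --seed 1 --out pathways.json --format json
Rscript "$CLI" simulate planted --m 200 --n 100 --k 4 --seed 7 --out sim.tsv
```

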
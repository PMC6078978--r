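# netenhance

Diffusion-based denoising of undirected, weighted networks.

Biological networks — tissue-specific gene interaction maps, Hi-C contact
matrices, image-similarity graphs for species identification — are noisy:
measurement error creates superficially strong spurious edges and hides
real ones, which blurs module boundaries and hurts everything downstream
(community detection, label propagation, retrieval). `netenhance`
implements network enhancement, an unsupervised denoiser for any
symmetric, non-negative weight matrix, together with the evaluation
toolkit used to quantify the benefit and a synthetic generator so every
claim is testable without external data.

## Method

From the input weights `W`, a **localized doubly stochastic operator**
`T` is built in two steps: row-normalized transition probabilities over
each node's k nearest neighbours (self always included),

    P_ij = W_ij / Σ_{k ∈ N_i} W_ik   for j ∈ N_i,  else 0,

followed by the symmetric doubly stochastic completion

    T_ij = Σ_k  P_ik P_jk / Σ_v P_vk .

The diffusion `W_{t+1} = α T W_t T + (1 − α) T` (0 < α < 1) is a
contraction whose fixed point has a closed form: with `T = V Λ Vᵀ`,

    W* = V f_α(Λ) Vᵀ,   f_α(x) = (1 − α) x / (1 − α x²).

Eigenvectors are preserved; eigenvalues shrink, smaller ones
disproportionately; 0 and 1 are fixed points, so the top eigengap widens
and disconnected components are never joined. The result is a sparser,
cleaner network on the same nodes.

## Worked example

```r
library(netenhance)

sim <- generate_block_network(n = 200, n_blocks = 4, seed = 1)
det <- enhance(sim$network, alpha = 0.9, details = TRUE)

retrieval_accuracy(sim$network, sim$labels, top_m = 20)
#> [1] 0.70525
retrieval_accuracy(det$network, sim$labels, top_m = 20)
#> [1] 0.977

spectral_report(det$operator, det$diffusion$denoised, alpha = 0.9)
#> Spectral report (alpha = 0.9, n = 200)
#>   top eigenvalues before: 1.0000 0.4892 0.4612 0.4480 0.1596
#>   top eigenvalues after:  1.0000 0.0623 0.0570 0.0547 0.0163
#>   components (eigenvalue-1 multiplicity): 1
#>   max eigenvector drift: 1.1e-14
#>   max |eig(W*) - f(eig(T))|: 2.11e-15
```

The simulated network plants four communities of 50 nodes under heavy
noise (within-block weight 1.0, between 0.3, Gaussian noise sd 0.5, 20%
dropout of true edges). On the raw network a query node's twenty
strongest neighbours are in its own block only ~70% of the time; after
enhancement ~98%. The spectral report certifies the theory on this very
matrix: eigenvectors unchanged (drift ~1e-14), every eigenvalue mapped
exactly through `f_α`, the leading eigenvalue pinned at 1, and the three
community eigenvalues (0.49, 0.46, 0.45) separated much further from the
noise floor (0.16 → 0.016) after the map.

Other entry points: `diffuse_iterative()` / `diffuse_closed_form()` for
the two diffusion routes, `rwr_propagate()` and `rwr_loo_auroc()` for
random-walk-with-restart label propagation, `nmi()`,
`retrieval_accuracy()`, `auroc()`, `subnetwork_edge_density()` for
evaluation, `detect_communities()` (Louvain via igraph),
`read_network()` / `write_network()` for edge-list, dense and
MatrixMarket files.

## Command line

A thin CLI over the same functions lives at
`system.file("cli", "ne.R", package = "netenhance")`:

```sh
Rscript ne.R simulate --n 200 --blocks 4 --seed 7 --output net.tsv --labels labels.tsv
Rscript ne.R enhance  --input net.tsv --alpha 0.9 --k AUTO --output enhanced.tsv
Rscript ne.R spectra  --input net.tsv --top 10 --output report.tsv
Rscript ne.R propagate --input enhanced.tsv --seeds seeds.txt --output scores.tsv
Rscript ne.R eval retrieval --input enhanced.tsv --labels labels.tsv --top-m 20
```

Exit codes: 0 success, 2 validation/parse error, 3 numerical failure,
4 iterative non-convergence (best iterate still written).

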
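# ecomlsa

Multi-locus sequence analysis (MLSA) and ecotype demarcation for microbial
populations sampled without cultivation.

Bacterial diversity in the wild is organised into *ecotypes*: populations
occupying the same ecological niche whose internal diversity is repeatedly
purged by periodic selection. Deciding where one ecotype ends and the next
begins — from a handful of housekeeping loci sequenced out of clone
libraries or amplicon pools — is the problem this package addresses. The
motivating system is hot-spring cyanobacterial (*Synechococcus*-like) mat
communities sampled across temperature and depth gradients, but every
function takes plain tibbles of aligned sequences and metadata, so any
MLSA-style dataset fits.

The package implements the full analysis arc:

* **Typing** — allele assignment by exact sequence identity, multi-locus
  sequence types (STs), dominant/subdominant/singleton variant roles.
* **Clonal complexes** — eBURST-style clustering of STs linked through
  single-locus variants, with founder prediction and a relaxed
  (double-locus-variant) mode.
* **Population genetics** — per-alignment segregating sites, Watterson's
  `theta_W = S / sum(1/i)` (reported per region), mean/variance of pairwise
  differences, the Hudson–Kaplan minimum number of recombination events
  `Rmin`, a moment estimate of the population recombination rate `4*Ne*r`
  from the variance of pairwise differences, and the resulting
  `R/theta` range.
* **Recombination detection** — SNP patterning of each variant against its
  group's dominant variant (`>1` SNP in a single locus indicates
  recombination), clade-scoped shared-pattern scanning for historic
  events, nearest-reference lineage assignment for inter-lineage transfer
  candidates, and reconciliation of event lists across detection methods
  into unique/overlapping totals.
* **Ecotype simulation and demarcation** — a coalescent simulator for the
  Stable Ecotype Model (ecotype formation rate `omega`, periodic selection
  rate `sigma`, `npop` ecotypes), a likelihood-free fit of those parameters
  to an observed cluster-count-versus-identity curve with 95% confidence
  intervals at the best precision match (1.25x–2x), and conservative
  top-down demarcation of putative ecotypes (PEs) on a tree.
* **Habitat association** — PE-by-habitat contingency tables, Fisher's
  exact test (full enumeration for 2x2, seed-controlled Monte Carlo for
  r x c), the G-test, high-frequency amplicon filtering (>= 50 copies),
  exact read-to-ST/PE matching with homopolymer frame correction, and
  depth-resolved relative-abundance profiles with replicate standard
  errors.
* **Mate-pair synteny** — classification of clone end placements against a
  reference genome as syntenous/non-syntenous with orientation classes.
* **Synthetic data** — a generator emitting ecotype-structured multi-locus
  datasets with known truth (ecotype memberships, implanted gene-conversion
  tracts, habitat-biased sampling, depth gradients), used throughout the
  test suite.

Fitted model objects follow broom conventions (`tidy()`, `glance()`,
`autoplot()`); results are tibbles throughout and compose with the pipe.

## Worked example

Generate a 40-record, 3-ecotype dataset with strong periodic selection,
type it, summarise it, fit the ecotype model and test habitat association:

```r
library(ecomlsa)
library(dplyr)

ds <- simulate_mlsa_dataset(n_records = 40, npop = 3, sigma = 5,
                            recomb_within_ratio = 0, seed = 42)

sts <- assign_alleles(ds$alignments) |>
  build_sequence_types(c("rbsK","PK","hisF","lepB","CHP","aroA","dnaG"))
head(sts, 3)
#>   st_id count members     rbsK    PK  hisF  lepB   CHP  aroA  dnaG
#> 1     1    14 <chr [14]>     2     2     2     2     3     2     2
#> 2     2     8 <chr [8]>      1     1     1     1     1     1     1
#> 3     3     3 <chr [3]>      1     3     1     4     5     5     3

attr(demarcate_clonal_complexes(sts, min_slv = 2), "complexes")
#>   cc_id consensus_st n_members n_slv n_dlv
#> 1 CC-1             7         6     6     0
#> 2 CC-2            13         5     4     0

conc <- concat_alignment(ds$alignments)
summarize_popgen(conc, locus = "concat7")
#>     locus  n n_theta    L  S theta_w ave_pwd var_pwd rmin r_wakeley
#> 1 concat7 40      40 3736 61   14.34   24.81   372.7    0      1.63
```

The 14-member ST1 is the dominant variant of its ecotype; the two clonal
complexes collect its single-locus satellites. The concatenation carries 61
segregating sites (`theta_W` = 14.3 per region over 3736 nt); no site pair
violates the four-gamete test (`rmin` = 0), as expected with conversion
implants disabled.

```r
fit <- fit_ecotype_model(conc, nrep = 32, npop_grid = 1:8,
                         omega_grid = 10^seq(-2.5, 1, length.out = 3),
                         sigma_grid = 10^seq(-2.5, 1.5, length.out = 3),
                         hillclimb = FALSE, seed = 1)
fit
#> Stable Ecotype Model fit
#>   npop  7 (95% CI 1-8)
#>   omega 10 (95% CI 0.003162-10)
#>   sigma 0.003162 (95% CI 0.003162-31.62)
#>   precision 1.5x, score 0.50 (32 reps/candidate, n=13, L=3736)

pes <- demarcate_pes(conc, seed = 1)
count(pes, pe)
#>   pe        n
#> 1 PE1      15
#> 2 PE2      13
#> 3 PE3      12
```

The point estimates are weakly identified (note the interval widths — a
characteristic of this likelihood-free fit, whose published counterparts
report similarly wide intervals), but the conservative clade-by-clade
demarcation recovers the three simulated ecotypes exactly (adjusted Rand
index 1 against the generator truth).

```r
tab <- habitat_contingency(pes, ds$metadata, min_group = 5)
tab
#>       60C 65C
#>   PE1  10   5
#>   PE2   9   4
#>   PE3   2  10
fisher_exact_rxc(tab, seed = 1)
#> [1] 0.0124
```

The generator sampled PE3's ecotype preferentially from the warmer habitat;
Fisher's exact test of contingency flags the heterogeneity (p = 0.012 at
the package's alpha = 0.05 convention).

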
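# JointScoreTest

Multi-marker association testing for **paired donor/recipient (D/R)
genetic data in transplantation**. Emerging evidence suggests that D/R
genetic matching outside the HLA region affects transplant outcomes such
as acute rejection. For a gene with *m* SNPs in *n* D/R pairs, this package
tests — jointly — whether the recipient genotypes or a gene-based D/R
matching score are associated with the outcome, for users running
candidate-gene or genome-wide gene-level analyses of transplant cohorts.

## The model and the test

With outcome *Y*, covariates *W*, recipient genotypes
*X = (X₁ᴿ,…,Xₘᴿ)* and a gene-based matching score *Z*,

    g(μᵢ) = α₀ + Wᵢα + Xᵢβ + Zᵢγ,      H₀: β = 0 and γ = 0.

The matching score sums a per-SNP D/R distance over the gene,
*Zᵢ = Σⱼ D(Xᵢⱼᴰ, Xᵢⱼᴿ)*, with four distances available: identity-by-state
|Xᴰ−Xᴿ|, incompatibility 1{Xᴰ≠Xᴿ}, the allogenomics mismatch count
(donor allele copies absent from the recipient genotype) and its binary
version; optional 1/MAF weights upweight rarer SNPs.

The **joint score test (JST)** builds the efficient score vector
*U = (U₁ᴿ,…,Uₘᴿ, U_S)* from the covariate-only null fit (columns of
(X, Z) residualized on the covariates with weights p̂₁(1−p̂₁)), estimates
its covariance empirically as V̂ = Q′Q from the per-pair contributions,
eigen-decomposes the recipient block V̂_R and keeps the smallest number
*s* of leading principal components explaining a preset fraction (65–99%)
of the total variance:

    U_P = ( a₁′Uᴿ/√λ₁, …, a_s′Uᴿ/√λ_s, U_S ),
    T   = U_P′ [ I_s  c ; c′  V̂_S ]⁻¹ U_P   ~   χ²(s+1) under H₀.

Dropping the trailing components lowers the degrees of freedom from m+1 to
s+1, which is where the power gain over the joint GLM comes from, while
keeping separate fixed effects for the recipient genotype and the matching
score (unlike SKAT, which ties them to a common variance component).
Comparators included: the joint GLM likelihood-ratio/score test and
SKAT-style quadratic-form tests with unweighted linear and IBS kernels.

## Worked example

```r
library(JointScoreTest)

model <- genePreset("NAT2")                    # m = 15 SNPs, block LD
coh <- simulateNullCohort(model, nPairs = 500, prevalence = 0.2, seed = 1)
coh
#> PairedCohort: 500 D/R pairs, 15 SNPs, 2 covariate(s), binary outcome
#>   cases: 97 (prevalence 0.194)

ms <- matchingScore(donorGeno(coh), recipientGeno(coh), "IBS")
ms
#> MatchScore (IBS): 500 pairs over 15 SNPs; mean 8.458, range [0, 19]

jstTest(coh, ms, threshold = 0.65)
#> Joint score test (recipient SNPs + D/R matching score)
#>   score type: IBS;  SNPs used: 15
#>   s = 4 PCs (65% variance), statistic = 3.9113, df = 5, p = 0.5623
```

The 15 recipient-SNP score components are compressed to s = 4 principal
components (65% of variance), the IBS matching score adds one more
dimension, and the statistic 3.91 on 5 df (p = 0.56) correctly finds no
association in this null-simulated cohort.

For real data the same test runs gene-by-gene from standard files:

```r
coh <- loadPairedData("recipient.vcf", "donor.vcf", "pheno.tsv", "covar.tsv")
regions <- assignGenes(snpInfo(coh), "genes.bed")
scan <- runGenomeScan(coh, regions, threshold = 0.85)   # BH FDR per score type
```

A thin command-line wrapper with `run` and `simulate` subcommands is
installed at `inst/scripts/jst.R`.

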
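# DecayDynamics

Estimating zygotic mRNA half-lives from total RNA-seq time series — without
transcription inhibition or metabolic labelling — by jointly modelling
pre-mRNA and mature mRNA dynamics, plus the single-molecule imaging and
codon-usage analyses that accompany such a study.

## The problem and the model

In early embryos, zygotic transcripts are produced and degraded
simultaneously, so their decay rates cannot be read off an mRNA time course
directly.  Total RNA-seq separates the two processes: intronic reads proxy
the instantaneous transcription rate via pre-mRNA abundance *p(t)* (introns
are spliced co-transcriptionally and decay within minutes), while
transcript-level TPM measures mature mRNA *m(t)*.  The two are linked by
first-order kinetics,

```
dm/dt = S p(t) − D m(t),        t½ = ln(2) / D
```

with *S* a production/splicing scale (per minute) and *D* the degradation
rate (per minute).  Placing a Gaussian-process prior with an RBF kernel on
*p(t)* makes *m(t)* a GP as well: the linear ODE maps the RBF kernel into
closed-form cross- and auto-covariances (erf integrals of the
exponential-decay convolution), so `(p, m)` observations at the ten
collection times (95–220 min after egg lay, three replicates) have a joint
Gaussian marginal likelihood with six parameters: RBF lengthscale and
variance, *S*, *D*, and two observation-noise variances.  MAP estimates come
from multi-restart L-BFGS-B in log-parameter space; full posteriors from a
preconditioned Metropolis-adjusted Langevin (MALA) sampler, giving 95%
credible intervals on *t½* and short (<15 min) / medium (15–25 min) /
long (>25 min) stability categories (half-lives above 250 min are excluded
as unidentifiable over a 125-minute window).

Around this core the package implements the full published analysis
pipeline: modified-RPKM and intron-length normalisation; minimum-TPM,
GP likelihood-ratio "dynamic", zygotic (TPM < 0.5 at t = 95) and
pre/mature-correlation (r > 0.4) filters; peak-delay estimation by GP
posterior sampling with a delay-vs-half-life confusion matrix; codon
stabilisation coefficients and codon-optimality statistics; and smFISH spot
quantification — globally optimal 5′/3′ end pairing (< 300 nm), mRNA
compaction, the P-body colocalisation index `C_P = m_coloc / (m_total·N_P)`
(< 200 nm, or 150 nm for single ends), lone-end enrichment, detection
efficiency from alternating-probe controls, and exponential decay fits.
A synthetic-data generator produces ODE-consistent expression cohorts, 3D
spot fields and codon cohorts with recorded ground truth.

## Worked example

```r
library(DecayDynamics)

# simulate a small cohort with known degradation rates
sim <- simulateExpressionCohort(3, D = c(0.01, 0.03, 0.08), seed = 11)
times <- rep(defaultTimeGrid(), each = 3)

# fit one transcript: MAP + MALA posterior
fit <- fitHalfLife(times, exprValues(sim$pre)[2, ],
                   times, exprValues(sim$mature)[2, ],
                   transcriptID = "tx2", nSamples = 1000, burnIn = 300,
                   seed = 1)
fit$map
#> ODEModelParams (joint GP-ODE model)
#>   lengthscale = 25.71 min, variance = 4.027
#>   S = 0.03952 /min, D = 0.03075 /min (t1/2 = 22.5 min)
#>   noiseVarP = 0.003769, noiseVarM = 0.009402
round(fit$ci, 1)
#>  lower median  upper
#>   18.9   22.2   26.8
fit$category
#> [1] medium
```

The true half-life of this transcript is ln(2)/0.03 = 23.1 min: the MAP
estimate (22.5 min) recovers it within 3% and the 95% credible interval
[18.9, 26.8] covers it.  `runHalfLifePipeline()` chains the filters and the
fits over a whole cohort and returns the per-transcript results table;
`runImagingPipeline()` does the same for spot fields.

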
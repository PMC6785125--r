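# cdtem

Coalescent demographic inference and molecular-rate calibration by
demographic transition, for single-locus (typically mitochondrial)
population samples.

## The problem

Marine population genetics rarely has fossils or clean vicariance events to
calibrate a molecular clock, and deep phylogenetic rates underestimate the
rate relevant to recent coalescent events (the time dependency of the
molecular clock). When independent evidence says a population expanded
after the last glacial period, the expansion itself can calibrate the
clock: infer the mutation-scaled onset of growth from the sequences, divide
it by calendar dates drawn from the warming phase of a temperature proxy
record, and obtain a *distribution* of substitution rates. `cdtem`
implements this calibration-of-demographic-transition (CDT) pipeline end to
end:

* **Summary statistics** — haplotype collapsing, haplotype and nucleotide
  diversity, Tajima's *D*, Fu's *F*s, *R*2 with coalescent null
  distributions, pairwise Φst with permutation tests, Tamura (1992) + Γ
  distances, minimum spanning haplotype networks.
* **Two-epoch coalescent model (TEM)** — an ancient constant size θ1
  followed by logistic or exponential growth to θ2 with transition time
  *TT* (substitutions/site); Bayesian MCMC over genealogy, demographic,
  HKY+Γ and clock parameters (strict / lognormal / exponential relaxed),
  with stepping-stone and harmonic-mean marginal likelihoods and 2·lnBF
  model comparison.
* **CDT rate calibration** — warming-rate weights from a temperature
  record, calibration-date sampling, rate = TT/date crossing, lognormal vs
  Gaussian density fit selected by AIC, with rates reported in %/My.
* **Bayesian skyline plot (BSP)** — 10-group piecewise-linear skyline under
  a CDT rate prior or a fixed conventional rate (e.g. 0.7 %/My), effective
  population size trajectories, maximum clade credibility trees with
  median node heights, and population split-time posteriors.
* **Synthetic data** — an exact time-rescaling coalescent simulator for
  two-epoch and clean-split histories, HKY+Γ sequence evolution, and
  synthetic glacial–interglacial temperature records, so the whole pipeline
  is testable without any downloads.

The central quantity is the mutation-scaled transition time *TT*. Crossing
its posterior with *k* calendar dates drawn ∝ max(warming rate, 0) yields
rate samples r = TT/date; their density is summarized as
lognormal(LogMean, LogSD) on the subst/site/My scale, and the median rate
in %/My (1 %/My = 10⁻⁸ subst/site/year) then scales skylines and split
times.

## Worked example

```r
library(cdtem)

## simulate a post-glacially expanded COI-like sample (40 x 608 bp)
m   <- two_epoch_model("logistic", theta_modern = 2e-1,
                       theta_ancient = 1e-4, transition_time = 2.58e-4)
sub <- substitution_model(kappa = 10,
                          base_frequencies = c(0.25, 0.15, 0.20, 0.40),
                          gamma_shape = 0.2)
gen <- simulate_coalescent(40, m, seed = 1)
aln <- simulate_sequences(gen, sub, 608, seed = 2)

collapse_haplotypes(aln)
#> 11 haplotypes from 40 sequences; 10 segregating sites
tajimas_d(aln)
#> [1] -2.287971
neutrality_null(aln, "tajima_d", n_reps = 1000, seed = 3)
#> tajima_d = -2.2880, one-tailed p = 0.0020 (1000 coalescent replicates)

## infer the two-epoch model (Metropolis-coupled chains) and calibrate
tr <- run_tem_mcmc(aln, "logistic", "strict",
                   chain = list(steps = 60000, sample_every = 100,
                                heated = 3, heat_delta = 0.6,
                                ess_threshold = 0),
                   seed = 4)
tt <- extract_posterior(tr, "tt")
round(c(tt$median, tt$hpd), 5)
#> [1] 0.00051 0.00010 0.04208

rec   <- synth_temperature(warming_onset = 11650, warming_width = 2000,
                           amplitude = 8, noise_sd = 0.2, seed = 5)
dates <- sample_calibration_dates(warming_rate_weights(rec), 10000, seed = 6)
fit   <- fit_rate_distribution(
           cross_rate_samples(tt$samples, dates, "subsample", 1e6, seed = 7))
fit
#> Rate density fit (selected: lognormal)
#>   lognormal: LogMean -2.029, LogSD 2.283, AIC 430927.9
#>   gaussian : mean 1.8771, sd 11.5610, AIC 7733162.1
#>   median rate: 5.09 %/My
```

The Tajima's *D* of about −2.3 with p ≈ 0.002 is the expansion signature
that licenses the calibration. The transition-time posterior has its
median at 5.1×10⁻⁴ substitutions/site with a 95% HPD reaching down to
1.0×10⁻⁴ — at 608 bp this posterior is wide by nature, which is exactly
why CDT works with a rate distribution. That fitted lognormal (median
here ≈5 %/My; the generating rate was 2.58×10⁻⁴/11,650 y ≈ 2.2 %/My, well
inside the distribution) feeds `run_bsp_mcmc()` as the clock prior,
and `clade_tmrca_posterior()` converts MRCA heights into calendar split
times under it. The wide LogSD is the honest price of a 608-bp locus: CDT
deliberately propagates that uncertainty instead of fixing a point rate.

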
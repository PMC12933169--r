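# stepdays

How many days of wearable step-count monitoring are needed to estimate a
person's habitual physical activity reliably? The answer depends on who
you ask: subjects with steady day-to-day activity need far fewer
monitoring days than erratic ones. `stepdays` answers the question
*per cluster of similar subjects*: it validates device wear time, selects
valid analysis periods, clusters subjects on the four distributional
moments of their daily steps (mean, SD, skewness, kurtosis), and runs a
Monte-Carlo day-subset resampling of intraclass correlation coefficients
to find, for each cluster, the smallest number of days n at which an
n-day mean is a reliable stand-in for the full 7-day (short-term) or
28-day (medium-term) mean.

## The statistic at the core

For m subjects with N valid days each, draw n days per subject without
replacement, and compare the n-day means A_i to the full-period means
B_i with the one-way random-effects ANOVA ICC (k = 2):

    ICC = (MSB − MSW) / (MSB + MSW)

Repeating over 500 random day combinations per subset size gives an ICC
distribution for every n; the minimum monitoring days is the first n
whose mean ICC reaches 0.80 (rule `"mean"`), or whose worst combination
does (rule `"all"`). Under an exchangeable two-component model
(between-subject variance σ²_b of the observed period means, day-to-day
variance σ²_w) the expected curve has the closed form

    ICC(n) = σ²_b / (σ²_b + σ²_w (1/n − 1/N) / 2)

implemented in `expected_icc()` and used as the analytic oracle for the
resampling machinery.

Data-filtering rules along the way: inter-record gaps exceeding 60
minutes are nonwear; days with less than 10 h of waking wear are
invalid; subjects need 7 valid days in a 10-day window (or 28 in 40),
with fewest-skip day sets preferred and ties randomized; clusters come
from complete-linkage agglomerative clustering on the standardized
moment features, dropping clusters below 12 subjects.

## Worked example

```r
library(stepdays)

# a cluster profile: subjects' 7-day means have SD 1538 steps/day, their
# day-to-day SDs are ~N(1619, 685^2)
cl <- cluster_spec("steady", mean_of_means = 5980, sd_of_means = 1538,
                   mean_within_sd = 1619, sd_within_sd = 685)

# expected reliability of an n-day mean against the 7-day mean
round(expected_icc(1:6, 7, 1538^2, 1619^2 + 685^2), 3)
#> [1] 0.641 0.811 0.889 0.935 0.964 0.985

# simulate 500 such subjects and resample 500 day combinations per n
md <- simulate_min_days(cl, n_days = 7, m = 500, seed = 1)
as.data.frame(attr(md, "curve"))
#>   n  mean_icc      sd_icc   min_icc n_undefined
#> 1 1 0.6550305 0.019233892 0.5808127           0
#> 2 2 0.8212752 0.010875368 0.7812481           0
#> 3 3 0.8959394 0.006427623 0.8704195           0
#> 4 4 0.9384305 0.004264264 0.9186519           0
#> 5 5 0.9664564 0.002188100 0.9592961           0
#> 6 6 0.9856466 0.000889420 0.9828811           0
as.integer(md)
#> [1] 2
```

Two monitoring days already push the mean ICC past 0.80 for this
low-variability profile — but the same computation on a high-variability
profile (`sd_of_means = 1028`, `mean_within_sd = 3068`) needs 6 of the
7 days. Near-threshold profiles can flip by one day between runs;
`min_days_majority()` repeats the run over 11 master seeds and takes the
modal value.

The `analysis/` directory holds the full narrative pipeline as numbered
scripts — simulate cohorts (including wear streams and invalid days),
validate wear, select periods, cluster the moment features, resample
ICCs per cluster, and produce the calibrated minimum-days table and
reliability-curve figure. Each writes its tables under `results/`.

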
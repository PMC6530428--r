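# bayesgaze

Tools for studying how people reason about statistical situations built
from two binary events — the setting of classic Bayesian reasoning tasks
such as the mammography problem — and for analyzing the eye-tracking data
collected while they do so.

A situation couples events A (disease, course choice) and B (test result,
career orientation) through the joint distribution
(p₁₁, p₁₀, p₀₁, p₀₀) and a reference population N. Sixteen probabilities
can be asked about it; the hard ones are the *Bayesian* (inverted)
conditionals, where

```
P(A|B) = P(B|A)·P(A) / (P(B|A)·P(A) + P(B|¬A)·P(¬A))
```

must be assembled from the base rate and both likelihoods. For the
mammography scenario (prevalence 1%, sensitivity 80%, false-alarm rate
9.6%) this is 7.8% — or, in natural frequencies on the tree
A → (B, C) → (D, E, F, G), "80 out of 1,030". People who get it wrong do
so in recurring ways: answering with the conjoint cell (*joint
occurrence*), the inverse conditional (*Fisherian*), the base rate alone,
likelihood sums or differences, the pre-Bayes ratio, and so on.

The package provides:

* **Scenario engine** — `scenario_from_rates()`, `probability_set()`,
  `frequency_tree()`, `answer_query()`: all sixteen probabilities, exact
  natural-frequency answers, and the ten-query design per context.
* **Strategy engine** — `predict_answer()` for the correct strategy and
  the full error catalog, generalized to all four Bayesian queries;
  `classify_answer()` / `classify_answers()` match observed answers
  against the candidate space (including quantity confusions and
  complement misreads) with explicit ambiguity flags; `tally_errors()`
  and `separability_audit()` summarize them.
* **Gaze analytics** — parametric AOI layouts for tree-diagram and
  2×2-table stimuli (`build_layout()`), formula-derived relevant AOIs,
  fixation assignment, scan paths, the standard AOI indicators
  (`aoi_indicators()`: order in sequence, dwell time, fixation count, hit
  ratio), and duration-weighted Gaussian heat maps (`gaze_heatmap()`).
* **Synthetic cohort** — `simulate_experiment()` draws latent per-trial
  strategies and generates both numeric answers and strategy-conditioned
  fixation sequences for the full 24-participant × 20-inference design,
  seeded and byte-reproducible.
* **Reporting** — `run_report()` / `write_report()` assemble solution
  rates, error tallies, AOI tables and stratified heat maps into diffable
  CSV/JSON/PGM artifacts; `inst/cli/bayesgaze.R` is a thin command-line
  front end (`simulate`, `classify`, `gaze-metrics`, `heatmap`,
  `report`).

## Worked example

```r
library(bayesgaze)

mam <- builtin_scenario("mammography")
frequency_tree(mam)
#> <frequency tree>
#>   A=10,000 -> (B=   100, C= 9,900) -> (D=    80, E=    20 | F=   950, G= 8,950)

answer_query(mam, inference_query("P(A|B)", "natural_frequency"))
#> 80 out of 1,030

q <- inference_query("P(notA|notB)", "probability")
predict_answer("fisherian", mam, q)
#> 90.4%

classify_answer(probability_answer(0.904), mam, q)
#> <classification> fisherian (ambiguous)
#> ...
```

The tree holds the natural-frequency rendering of the scenario (note 950,
the half-up rounding of 9,900 × 9.6% = 950.4, with G = 8,950 forced by
additivity). The correct Bayesian answer is the pair 80/1,030 ≈ 7.8%. A
participant answering "90.4%" to the negative-direction question
P(¬A|¬B) — whose correct answer is 99.8% — is classified as Fisherian:
they read the on-screen inverse conditional P(¬B|¬A) off the tree. The
classifier also reports that this value cannot be separated from a
confusion with that same displayed quantity, hence `ambiguous`.

A full synthetic cohort with gaze:

```r
ds  <- simulate_experiment(simulation_config(master_seed = 7))
rep <- run_report(ds)
rep$solution_rates   # by visualization x format x inference class
rep$error_tally      # joint occurrence / Fisherian / ... per cell
```

With the default mixtures this prints, e.g., Bayesian solution rates of
25.0% (tree, probabilities) vs 47.9% (tree, frequencies) for seed 7 —
frequency formats are easier by construction of the simulator — and an
error tally such as "34 established out of 36 errors" per cell.

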
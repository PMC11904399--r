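---
title: "Deriving nutrient intakes and dietary patterns from an unquantified FFQ"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving nutrient intakes and dietary patterns from an unquantified FFQ}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffqkit)
```

## The problem

An unquantified food frequency questionnaire (FFQ) records how often foods
are eaten, not how much. `ffqkit` implements the classic epidemiological
derivation that turns such coded responses — here, the 32-week pregnancy
questionnaire of a UK birth cohort of the early 1990s — into estimated daily
nutrient intakes, dietary-pattern scores and screening variables. The
questionnaire has 43 food/food-group items on a five-category weekly scale
plus detailed questions on eight daily "basics" (bread, milk, spreading and
cooking fats, sugar in tea and coffee, soft drinks, tea/coffee/cola).

## The derivation model

**Frequency recoding.** The five response options map to assumed times per
week: never or rarely = 0, once in 2 weeks = 0.5, 1–3 times a week = 2,
4–7 times a week = 5.5, more than once a day = 10. An unanswered item is
treated as rarely or never eaten (weight 0), which makes the whole engine
total: it never fails on a schema-valid response.

**Portion-weighted summation.** Each question carries a fixed list of
representative foods with gram weights standing in for one consumption
occasion. The weekly intake of nutrient $n$ is

$$W_n \;=\; \sum_q f_q \sum_{(c,\,g)\in P_q(n)} \frac{g}{100}\, d_{c,n},$$

where $f_q$ is the recoded frequency of question $q$, $P_q(n)$ the portion
list, and $d_{c,n}$ the nutrient density of food code $c$ per 100 g. Some
questions carry nutrient-specific alternate lists (tagged for vitamin E,
vitamin C, folate, retinol, carotene, zinc, pyridoxine, niacin, the fatty
acids, or total fat and energy); slot $n$ reads the alternate tagged for $n$
when one exists and the default list otherwise. The meat questions switch
between lean-and-fat, half-and-half and lean-only component lists according
to the fat-on-meat behaviour answer. A missing behaviour answer falls back
to the lean-and-fat list (the conservative, higher-fat reading); "never eat
meat" falls back to lean-only, since any non-zero meat frequency then
contradicts the tick and the lean list is the milder assumption.

**Daily basics.** Bread-slice categories (<1, 1–2, 3–4, ≥5 per day) map to
their midpoints 0.5/1.5/3.5/5.5 with missing recoded to 1.5; slices spread
with fat default to 2 when missing and cap at 6; soft drinks carry a fixed
frequency of 2/week (the questionnaire did not ask one) with the diet-drink
answer scaling the sugary fraction (always 0, sometimes 0.5, not at all 1);
milk/bread/fat type ticks weight "usually" 1 and "sometimes" 0.5 and are
renormalised to shares, falling back to the national-default type (white
bread, whole milk, soft margarine, vegetable oil) when nothing is ticked.
Total milk sums six daily uses (tea, coffee, cereal, pudding, drink on its
own, milky drink) at per-use volumes.

Weekly totals divide by exactly 7 to daily intakes; energy is carried in kJ
and additionally reported in MJ.

**Plausibility exclusions.** A participant whose derived intake falls
outside any printed bound is removed from the whole nutrient output, and the
exclusion log names every violated rule. The energy rule is a window on the
*weekly* kJ total (15 000–120 000, i.e. about 2.1–17.1 MJ/day); the
remaining bounds are upper limits whose magnitudes only make sense on the
*daily* scale in the output units (e.g. calcium < 2 500 mg against a typical
mean near 940 mg/day — seven-fold weekly values would exclude nearly
everyone). Each rule's basis is therefore recorded explicitly in the shipped
JSON transcription. The fish fatty-acid output stream accepts its own rule
set through a hook; none are defined by default because no bound is printed
for it.

**Fish fatty acids and caffeine.** Closed forms over the three seafood
frequencies: weekly n-3 grams are 0.32/0.89/0.35 per portion of
white/oily/shellfish respectively. The EPA and DHA per-portion splits are
not printed anywhere; the package defaults give each class DHA:n-3 ≈ 0.47
and EPA:n-3 ≈ 0.33, matching the ratio of the published population means
(DHA 0.07, EPA 0.05, n-3 0.15 g/day), and live in the config clearly
labelled as package choices. Weekly caffeine is 7 × (27 mg per caffeinated
cup of tea + 57 mg per cup of coffee + 20 mg per cola); decaffeinated counts
contribute nothing.

**Dietary patterns.** Recoded frequencies (times/week, not nutrients) are
standardised and the first five principal components varimax-rotated. The
fitted loadings are kept as an orthonormal basis of the retained subspace,
so rotation preserves its total explained variance, scores are plain
standardised projections (training mean scores exactly zero), and the sign
convention — largest-magnitude loading positive — makes the fit
deterministic. Component names ("health conscious", "traditional", …) are
manual metadata attached after inspecting loadings, never assigned
algorithmically.

**Derived utilities.** AOAC fibre = NSP × 1.33 exactly; the NMES slot is
equivalent to free sugars under the version-6 recodes. Energy
standardisation uses conversion factors protein 17, fat 37, carbohydrate
16 kJ/g (percent mode) or divides by MJ (density mode). Misreporter
screening predicts the energy requirement as Schofield BMR for women 18–29
(0.062 × weight + 2.036 MJ/day) × physical activity level 1.4 and
classifies the reported/predicted ratio against Goldberg-style bounds
0.54–2.0; Schofield coefficients and bounds are standard literature values
held in the config, not printed in the source derivation.

## Constants the tables leave unstated

The sources state that milk volumes, spread and sugar weights exist without
printing them. The package fixes: 7 g spreading fat per slice, 5 g sugar per
spoon, milk-use volumes 30 ml (tea or coffee), 100 ml (cereal, pudding),
200 ml (glass, milky drink), and a 110 g soft-drink portion (the weight the
portion table prints per soft-drink component). Because the soft-drink
question lists three alternative drinks at 110 g each, the engine rescales
that component list to a single 110 g average drink rather than summing
330 g per occasion. All of these sit in `default_constants()` and can be
overridden from JSON via `ffq_config()`, so every constant in the engine is
reachable without code changes.

Two transcription choices: the food code printed as "4-885" for unsweetened
orange juice is normalised to 1091 (the code the same question's vitamin-E
variant prints for the identical description), and the roast-potato
question, printed with three alternative single-fat blocks and no selection
rule, keeps only the blended-oil food as its default. The cooking-fat
question is transcribed (as `c8a_cooking`) but contributes no nutrients: no
printed rule links cooking-fat type to any item's calculation.

## The synthetic cohort

Real cohort data are managed-access, so the generator emulates the response
schema with known latent truth. True times/week for item $j$ of participant
$i$ is $\mathrm{softplus}(\mu_j + \sum_k s_{ik} \lambda_{jk} +
\varepsilon_{ij})$ with five latent patterns shaped after the published
verbal descriptions; responses are the five-category bins of the true
frequency (edges 0.25/1.25/3.5/7.5, chosen so category midpoints track the
recode weights). Demographic defaults copy the published cohort margins
(education 35.4 % A-level+, smoking 19.8 %, owned housing 75.7 %, age 28.6
(4.8) years, BMI 22.9 (3.8) kg/m²); body weight comes from BMI and a
simulated height. Item-level missingness is 5 % per cell by default.
Injected misreporters scale their reported weekly frequencies *and* their
count answers (spread slices, drink counts, sugar spoons) by the misreport
factor — categorical ticks cannot be scaled and stay as answered, so
injected under-reporting attenuates slightly at the bread/milk streams.

Under these defaults the derived cohort lands at plausible scale (mean
daily energy around 6 MJ, protein around 56 g) — the same order as the
published daily means, which is the design goal. The generator does **not**
claim to reproduce the published means: those require the real cohort, the
licensed food-composition database (the shipped composition table is
synthetic, built from per-category density archetypes with deterministic
per-code jitter) and the original response distributions. Passing recovery
tests therefore demonstrate that the *engine* is correct and invertible at
realistic signal-to-noise, not that any real-world estimate is reproduced.

## Validation strategy and problem sizes

The test suite checks, at sizes chosen to run comfortably on one CPU:
every printed constant and rule; equivalence of the weekly summation with
an independently written brute-force loop over question × component food ×
nutrient on a 1 000-participant cohort at 10⁻⁹ relative tolerance;
recovery of the five latent loading vectors (matched absolute correlation
> 0.9) and of energy (true-vs-derived correlation > 0.9) on a
2 000-participant cohort; exact nutrient recovery on zero-noise,
zero-missingness cohorts; a toy cohort in which each record violates
exactly one plausibility rule and the log names exactly that rule; and the
closed forms against hand arithmetic. `scripts/acceptance.R` recomputes the
same headline quantities from scratch at a caller-supplied seed.

## Known limitations

* Alcohol units, supplement-derived nutrients and the earlier-pregnancy
  drink time-courses are out of scope (the first two are explicitly
  excluded from the FFQ nutrient calculation; only the 5:2
  weekday/weekend averaging helper is provided for the drink questionnaires).
* The fried-food and take-away questions are behaviour covariates only;
  they carry no portion assignment and contribute no nutrients.
* Nutrient accuracy is defined against whatever composition table is
  supplied; the packaged table is synthetic and suitable for testing and
  method development, not for substantive nutritional inference.
* The misreporter screen uses a single Schofield band (women 18–29) —
  adequate for this cohort's age structure, configurable otherwise.
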
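---
title: "Methods: the plan-check rule engine, its synthetic test bed, and the audit statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the plan-check rule engine, its synthetic test bed, and the audit statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plancheckr)
```

## The model

`plancheckr` treats the physics initial chart check as a rule engine over a
validated, vendor-neutral plan representation. Three layers:

1. **Plan model.** DICOM RT Plan files are parsed into a `plan_context`:
   beams with ordered control points (gantry/collimator/couch angles in IEC
   61217 degrees normalised to `[0, 360)`, jaw and MLC positions in mm,
   cumulative meterset weights), reference points, fractionation and
   prescription, all in DICOM patient coordinates. A YAML *sidecar* supplies
   the planning-system database fields DICOM exports do not carry (approval
   status, course intent, DRR and imager metadata, algorithm names, QA-plan
   linkage). RT Dose contributes only the dose-grid resolution; RT Structure
   Set only structure names.
2. **Framework.** A `run_config` names the enabled checkers, in display
   order, and the parameters defining each checker's passing criteria. Every
   checker is an isolated function `plan_context × run_config →
   check_result`; an exception inside one produces a FLAG for that checker
   and the run continues. Four compliance states exist (PASS, FLAG, REPORT,
   MANUAL); the shipped profile uses no MANUAL placeholders, and the test
   suite asserts this.
3. **Checkers.** 25 registered checkers carrying 34 checks (the QA composite
   counts 10 constituents). `docs/checkers.md` is the per-rule reference.

Ordering of checkers is purely presentational: the subset-independence
property (results of any enabled subset equal the corresponding restriction
of the full run) is tested directly.

## Design choices where the design was genuinely open

- **DICOM I/O.** The package ships its own minimal DICOM reader/writer
  (explicit VR little endian only), scoped to the RT Plan / RT Dose /
  RT Structure Set subsets it emits and consumes. This keeps the package
  dependency-free for its central format and makes the synthetic generator
  byte-deterministic. The loader is cross-checked in the test suite against
  an independent raw-tag dump of the same files produced with pydicom.
- **Reading the TPS vs reading exports.** The original clinical deployment
  of such engines reads the planning system through an API and SQL; this
  package instead reads portable DICOM plus one sidecar file, trading
  fidelity to any one vendor for portability and testability. Which fields
  belong in the sidecar is necessarily a superset guess; the schema is
  documented rather than asserted as faithful.
- **"IMRT leaf delivery"** is not a standard, rigorously defined quantity;
  the package defines it as the two standard deliverability failure modes:
  a minimum dynamic leaf gap (default 0.5 mm; pairs fully closed and parked
  outside the X jaws are exempt) and a maximum required leaf speed, computed
  per segment as `|Δposition| × dose_rate / (ΔMU × 60)` mm/s (default limit
  25 mm/s). Both are configuration-exposed so institutions can retune.
- **Boundary convention.** All tolerance comparisons use `≤`: a value
  exactly at tolerance passes. Isocenter equality uses a 0.01 mm band as a
  float-safe equality.
- **Grid-size convention.** The recorded resolution is the *maximum* voxel
  pitch over the three axes — conservative, since any axis coarser than
  policy is a policy violation.
- **Missing sidecar data** degrades to FLAG "insufficient data", never a
  silent PASS: a checker must not certify what it cannot see. Conversely, a
  checker whose preconditions do not apply (e.g. the EPID comparison on a
  25-fraction plan) returns PASS "not applicable" rather than REPORT, so
  the flag count stays meaningful.
- **Soft vs hard invariants.** Decreasing cumulative meterset weights and
  MLC bank inversions are load errors — no meaningful check can run on such
  a plan. A static beam with three control points, a setup beam with
  meterset, or a treatment beam without a tolerance-table label are *soft*
  issues recorded as warnings: the corresponding checkers must be able to
  observe and flag them.
- **Severity switches.** Naming-convention rules carry a per-rule
  `severity: flag|report` switch; experience with such tools shows naming
  checks are where stringency most often needs local softening.

## The synthetic test bed

`generate_clean_context()` writes five plan templates (two-field static with
bolus, five-field sliding-window IMRT, two-arc VMAT, and single-fraction
VMAT/FFF variants with EPID and MapCheck verification plans). They are
*minimal-but-valid* DICOM: required modules only, a reduced 10-pair MLC, zero
dose pixels — checker inputs, not dosimetric truth. What they emulate is the
structure the checkers read (control-point sequences, meterset bookkeeping,
tolerance tables, setup fields, QA linkage); what they do not emulate is
anatomy, realistic fluence, vendor private tags, or the messiness of real
exports. Passing tests therefore demonstrate the rule engine's logic, not
robustness to every vendor dialect.

Determinism is part of the contract: a template and seed yield byte-identical
files (fixed dates, seed-derived UIDs, seeded and bounded MLC jitter), and
different seeds must not change any check outcome. Template parameters are
chosen so every default check passes with margin: e.g. IMRT leaf travel per
segment stays near 3 mm where the speed limit permits about 13 mm.

The defect catalog (30 mutations, `docs/defects.md`) operationalizes the
recurring error classes an initial chart check guards against and adds one
defect per remaining pass/flag checker. The detection matrix over seeds is
asserted to be the identity on the defect→checker map: sensitivity 1.0,
no off-target flags, and clean-plan specificity 1.0. One representational
note: a trailing-whitespace plan name cannot survive a DICOM round trip
(string padding), so the injected naming defect uses a lower-case name and
the whitespace rule is tested on in-memory contexts.

## Audit statistics

- **Categorization** uses the fixed 17-label taxonomy (9 un-related, 8
  related to the automated checks). Percentages are of the period grand
  total, rounded half-up — 1 decimal for categories, 2 for subtotals — to
  match printed audit tables; empty periods render as "—".
- **Fisher's exact test** (two-sided) uses the minimum-likelihood
  definition: the sum of hypergeometric probabilities of all tables with the
  observed margins at most as probable as the observed one (relative
  tolerance 1e-7), computed in log space via `lchoose`. This is the dominant
  convention in standard statistical software. Degenerate margins return
  p = 1 with a warning. The implementation is verified against exhaustive
  enumeration for all tables with margins ≤ 10 and against
  `stats::fisher.test` on random tables.
- **Mann–Whitney U** uses midranks, the tie-corrected variance, and a
  continuity correction that shrinks `|U − μ|` by ½ (toggleable — the
  correction convention cannot be pinned down from published summary
  statistics alone, so it is exposed rather than hidden). For small samples
  an exact two-sided p, `P(|U − μ| ≥ |u_obs − μ|)` under the permutation
  distribution, is computed by enumerating labelings and reported alongside;
  enumeration is attempted when `n₁·n₂ ≤ 400` *and* the number of labelings
  `C(n, n₁)` stays below 10⁵ (balanced samples reach infeasible counts long
  before the product bound does). If all values are tied, σ = 0 and the
  defined result is U = n₁n₂/2, p = 1, with a warning.
- **Known accuracy limitation.** The continuity-corrected normal
  approximation is *not* uniformly within 0.02 of the exact p for all
  sample sizes up to 8: exhaustive enumeration shows a worst-case
  discrepancy of 0.129 at n₁ = 1, n₂ = 3, U = 0, and the 0.02 bound first
  holds once min(n₁, n₂) ≥ 5 (worst case 0.017). The acceptance suite
  asserts the stricter bound as specified and documents this failure rather
  than hiding it; users comparing tiny samples should read `p_exact`.
- **Timing summaries** report per-person and overall n/mean/median per
  period and with/pre ratios rounded to 2 decimals; persons observed in only
  one period get blank ratios, and per-person p-values are computed only
  when both periods hold at least 3 checks.

## The audit simulator

`simulate_audit_logs()` draws per-category issue counts as
Binomial(n_checks, rate) and per-check times as log-normal per person and
period. Its defaults *are* the study conditions of the two-period audit the
statistics reproduce: 187 and 186 checks, category rates equal to the
recorded per-check proportions, and log-normal parameters matched to the
recorded period summaries (mean/median 49.4/45 min before, 39.3/35 min
after; matching a log-normal to a mean–median pair fixes μ = log median,
σ² = 2·log(mean/median)). The log-normal choice reflects strictly positive,
right-skewed durations. A Monte Carlo of this generator (500 replicates)
measures the power of the Fisher test at α = 0.001 to be 0.54 — the
recorded table's p-value (8.8×10⁻⁴) sits just below α, so resampling both
periods rejects only about half the time; the regression test asserts a
bound of 0.45, about four binomial standard deviations below the measured
power. Generator parameters were chosen from the study conditions once and
are not tuned to test outcomes.

## Problem sizes and numerical notes

The test suite runs the clean contract over all five templates with multiple
seeds, the full 30-defect corpus over 50 seeds in the acceptance sweep (and
2 seeds in the unit sweep), the Fisher oracle over every 2×2 table with
margins ≤ 10, and the Mann–Whitney oracle exhaustively over all attainable U
for every sample-size pair up to 8 — sizes at which the exact enumerations
are themselves trivially verifiable. DS-encoded numbers round-trip through
the DICOM layer at `%.8g`, comfortably inside the 1e-6 mm/MU equality
tolerance used by the round-trip tests.

## Limitations

- Only explicit-VR little-endian DICOM is read or written; real-world
  exports in other transfer syntaxes must be transcoded first.
- The sidecar is a modelling device: nothing validates it against a live
  planning system.
- No dose recomputation, DVH/plan-quality evaluation, or cross-system
  (EMR/scheduling) checks — the engine verifies integrity and policy, not
  plan quality.
- The per-person Mann–Whitney p-values of a published audit cannot be
  reproduced from printed summaries (raw per-check times are not published);
  the package instead verifies its statistics against enumeration oracles
  and recovers known generating parameters from its own simulator.
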
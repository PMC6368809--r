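---
title: "Predicting protein functions from literature with predicate logic: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein functions from literature with predicate logic: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protlogic)
```

## The problem and the model

Most text-based protein function predictors annotate an unannotated protein
$P_u$ with the function categories that co-occur *explicitly* with it in
biomedical sentences. protlogic additionally recovers functions that are only
*implicitly* present: terms that never co-occur with $P_u$ directly but
follow logically from the terms that do. The system has two components.

**Statistical component.** Biological-molecule terms are extracted from the
sentences of the documents associated with $P_u$ by dictionary lookup, and a
term counts as *semantically related* to the protein only if three gates
pass:

1. *Pronoun rule* — in at least one sentence the two mentions are connected
   by a pronoun (`that`, `who`, `which`) with no intervening preposition
   modifier (`whereas`, `but`, `while`), which marks the pair unrelated in
   that sentence;
2. *Collocation significance* — with $k$ the number of sentences containing
   both terms, $n_a, n_b$ the marginal sentence counts and $N$ the corpus
   size, the Z-score
   $$ z = \frac{k - Np}{\sqrt{Np(1-p)}}, \qquad p = \frac{n_a}{N}\cdot\frac{n_b}{N}, $$
   must exceed the configured threshold;
3. *Training validation* — the same pair must be related in the training
   corpus (the related-pair index), when one is supplied.

**Logic component.** Known protein characteristics are encoded as
*specification rules* in a small logic DSL — implications over typed atoms
such as `FD(Px)` (folding), `ST(Px)` (structure), `AAS(Px)` (amino-acid
sequence), `F(Px)` (function), `CBND(Px, Ly)` (covalent bond to a ligand),
`PPI`/`NCBND`/`PCF` (pairwise protein predicates). The bundled file
`rules_table1.plr` transcribes the thirteen sample rules (R1–R13); the DSL
makes the set extensible. Extracted terms become ground *given premises*
(e.g. `FD(PA)`, `ST(PA)`), the rules are grounded over the extracted
constants, and a forward-chaining engine applies the ten standard inference
rules (Modus Ponens/Tollens, Simplification, Conjunction, Disjunctive
Syllogism and Amplification, Contradiction, Conditional Proof, Proof by
Cases, Law of Syllogism) until a fixpoint. Every newly derived function atom
`F(Px)` then transfers all categories annotated to `Px` to $P_u$ as
*implicit* predictions, each backed by a natural-deduction proof that
`check_proof()` can replay.

```{r worked-example}
rules <- spec_rules()
fx <- worked_example_fixtures()
fa <- derive_function_atoms(fx$ex1$given, rules, fx$ex1$constants)
fa$proof[[1]]
```

## Design choices in the logic engine

Several points were genuinely open and were resolved as follows.

**Termination and the formula universe.** Conjunction, Disjunctive
Amplification and Proof by Cases generate unboundedly in free chaining. The
engine therefore only admits conclusions inside the *subformula closure* of
the given premises and grounded rules. This is exactly the set of formulas
that can ever matter for triggering a rule, and it bounds the iteration
count by the universe size. A consequence worth knowing: a textbook
derivation may use a Conjunction step (such as `FD(Px) & ST(Px)` feeding a
Conditional Proof) whose conjunction is *not* a subformula of any rule; the
chainer reaches the same conclusion through two Modus Ponens steps instead,
and the proof checker — which is deliberately universe-free — still accepts
the textbook derivation verbatim.

**Directional patterns, commutative instances.** Formula equality is
structural: connectives stay binary and ordered as written, because the
inference-rule patterns are directional as printed. Recognising a formula as
an *instance of a specification rule* is the one place matching works modulo
commutativity of `&`/`|`: rule variables are universally quantified and
those connectives are commutative, and the bundled 13-line worked example
instantiates one rule with its two protein roles swapped, which commutes a
conjunction relative to the printed pattern.

**Rule symmetrisation.** Simplification licenses both conjuncts (the printed
pattern shows only the left one), and Disjunctive Amplification may embed
its premise as either disjunct of a universe disjunction. Both are sound
(the suite checks every derived formula against a truth-table entailment
oracle) and both are needed for disjunctive rule antecedents to trigger.
Contradiction is implemented as the literal pattern `~p -> False ∴ p`, with
no refutation search. Binary rules accept their premises in either order.

**Grounding.** Substitutions are sort-respecting (protein variables take
protein constants, ligand variables ligand constants) and injective by
default — two-protein rules never self-instantiate, avoiding degenerate
derivations such as a protein inheriting its own function through an
interaction rule; the flag is exposed for experimentation. Enumeration order
is deterministic: rule-file order, then lexicographic constant order.

**First proof wins.** Once derived, a formula keeps its first justification;
re-derivations are ignored. Proof minimality is not claimed, determinism is.

**Erratum handling.** Two of the bundled worked-example derivations correct
apparent typesetting slips in their source: one cites premise "M10" where
only rule R10 exists (read as R10 with roles swapped), and one prints
antecedent step indices that point at a line's own successors (corrected to
the two rule-instance lines and to the given premise plus the syllogism
conclusion, preserving all formulas, rule names and the line count). The
corrections are documented in the fixture source.

## Extraction choices

Tokens are lowercased with punctuation stripped (`:` is kept inside tokens
so ontology ids like `GO:0006915` survive); spans are 0-based half-open.
Matching is case-insensitive, longest-match-first, non-overlapping. Template
payloads bind to the nearest protein/ligand name mention by token distance
with ties broken leftward; binary predicates take the two nearest distinct
names in textual order. The co-occurrence unit is the sentence throughout,
matching the sentence-level linguistic rules. A sentence that separates a
pair with a disconnector is discarded as evidence for that pair but does not
veto other sentences.

The lexicon's `payload_kind` takes four values — `template`, `category`,
plus `protein` and `ligand` name entries — so that dictionary named-entity
lookup and term extraction share one table.

**The Z threshold.** The default threshold is the stated operating point
$z > -1.96$. Taken literally this accepts nearly every co-occurring pair
(a standard-normal statistic exceeds $-1.96$ with probability $0.975$), so
the gate that does most of the work at the default is the pronoun rule plus
training validation. Users who want the conventional one-sided significance
test should set `z_threshold = 1.96`; the parameter is exposed everywhere.
Pairs whose variance is degenerate because both terms appear in *every*
sentence are treated as passing (their co-occurrence is certain); the
scalar `compute_zscore()` raises an error instead, since no finite score
exists.

## Function transfer and ranking

A derived `F(Px)` transfers *all* categories annotated to `Px`. No numeric
confidence is invented: the only ranking key is the support count — distinct
evidence sentences for explicit records, distinct source proteins for
implicit ones — with `min_support` as a filter and deterministic ordering
(evidence type, support descending, category id). The explicit-only
ablation (`pipeline_config(inference = FALSE)`) removes exactly the implicit
records and nothing else, mirroring the comparison between the complete
system and its statistical component alone.

## Evaluation

Per protein $p$: $\mathrm{Recall} = C_p/N_p$, $\mathrm{Precision} =
C_p/M_p$, $\mathrm{F} = 2PR/(P+R)$, with $C_p$ the correctly predicted,
$N_p$ the true and $M_p$ the predicted function counts. Averaging is macro
(per-protein), because the metrics are defined per protein; correctness is
exact category-id match with no ontology-ancestor credit. Proteins with no
predictions (or no gold categories) have undefined metrics and are skipped
with a warning rather than silently scored zero. `kfold_split()` shuffles
under a seed and deals round-robin, so folds differ in size by at most one;
`cross_validate()` rebuilds the related-pair index from each fold's training
documents.

## The synthetic-data generator

`generate_corpus()` emulates the one property of real literature the method
actually consumes: controlled per-sentence co-occurrence rates with known
relatedness structure. Sentences are assembled from fixed lexical templates —
a pronoun template (`"<a> , which involves the <b> of <anchor>"`), a
disconnector template, and a plain conjunction — plus independent background
term insertions. Everything is driven by one seed through a single RNG
scope, so corpora are byte-identical across runs. What it deliberately does
*not* emulate: real PubMed syntax, ambiguous entity names, coreference, or
realistic term frequency distributions. Passing the planted-signal tests
therefore demonstrates that the pipeline recovers structure *of the kind the
rules describe* when it is present; it says nothing about recall on real
text, where the two lexical relatedness rules are only a weak proxy for
semantic relatedness.

Problem sizes used by the shipped checks, chosen as comfortable desk-scale
conditions: the calibration corpus is 20,000 single-sentence documents over
64 independent background terms at a per-sentence rate of 0.03 (expected
joint count $Np \approx 18$, large enough for the normal approximation; the
fraction of $|z| > 1.96$ pairs is expected slightly *below* 5% because the
plug-in margins under-disperse the statistic by
$\sqrt{(1-p_a)(1-p_b)/(1-p_ap_b)} \approx 0.97$); the demonstration study
uses 120–150 documents of 2–4 sentences with planted rates 0.25–0.35; the
soundness suite runs 500 random instances with at most 3 proteins, 1
ligand, 6 rules and 16 ground atoms (the truth-table oracle's cap).

## Known limitations

- The bundled rule set is the thirteen-rule sample; the full original rule
  list was distributed online and is no longer available. The DSL and
  parser make user-supplied rule files first-class.
- Relatedness uses two lexical rules (pronoun, disconnector); there is no
  dependency parsing or coreference, and protein named-entity recognition
  is dictionary lookup only.
- Benchmark-scale corpora (hundreds of thousands of abstracts) and
  comparisons against other predictors are out of scope; the evaluation
  harness supports the protocol at desk scale.
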
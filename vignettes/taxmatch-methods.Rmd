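---
title: "Near matching of taxonomic names: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Near matching of taxonomic names: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxmatch)
```

## The problem

Biodiversity databases receive organism scientific names that are frequently
misspelled: phonetic (soundalike) slips such as *Peneus* for *Penaeus*,
mis-keyings such as *Acropaginula* for *Arcopaginula*, gender-ending variants
such as *columbianus* for *columbiana*, transposed syllables such as
*Panulirus* / *Palinurus*, and errors in the authority string. Reconciling
such strings against a reference checklist needs near ("fuzzy") matching that
is simultaneously high-recall (the true target is almost never missed),
high-precision (few false candidates), and fast enough to run against
checklists of 10^5^--10^6^ names. `taxmatch` implements the Taxamatch
strategy for this problem: a composite of custom edit distance, custom
phonetic encoding, heuristic pre-/post-filters, result shaping and ranking,
with an n-gram similarity for authorities.

## The model

### Edit distance with block transpositions (MDLD)

The core dynamic comparison is a modified Damerau-Levenshtein distance.
Insertions, deletions and substitutions cost 1. Transposition of two
adjacent equal-length blocks of *b* characters costs *b* (for `block_limit
>= b`), so *Panulirus*/*Palinurus* and *serratulus*/*serrulatus* -- each
distance 4 under plain Levenshtein or single-character Damerau-Levenshtein
-- score 2, matching the intuition of a single transposed-syllable slip.
`block_limit = 0` reduces to Levenshtein, `1` to the optimal-string-alignment
Damerau-Levenshtein. Genus comparisons use block limit 2, species epithets
4 (both configurable); the genus limit is the tighter because genus
comparisons dominate run time. Block transpositions are restricted to
equal-length, adjacent, non-overlapping blocks, each region participating
in at most one transposition; this reproduces every printed pair value, and
the test suite verifies the implementation against an independent
front-anchored edit-script search on an exhaustive short-string sweep.

When `max_distance` is supplied, the computation abandons as soon as a full
DP row exceeds it and returns `Inf` -- a deliberate sentinel, never a
clamped number, so filters can distinguish "unknown but large" from a real
value.

### Phonetic keys

Two encoder generations are provided. The 2001 variant keeps the initial
character, then applies soundalike substitutions to the remainder (AE, OE,
E, U, Y → I; IA, O → A; K → C; SC, Z → S; MC → MAC; H dropped) and
collapses repeated adjacent letters. The 2007 variant first rewrites
selected leading patterns *before* quarantining the initial character
(AE-, EA-, OE- → E; CN-, GN-, KN-, MN- → N; CT-, PT- → T; CZ- → C; DJ- →
J; EU- → U; PH- → F; PS-, TS- → S; QU- → Q; X- → Z), then proceeds as the
2001 variant; for species epithets it finally normalizes the grammatical
gender ending (keys ending -IS, -IM, -AS have the last two characters
replaced by A), so *columbianus*, *columbiana* and *columbianum* share one
key. Phonetic matching is Boolean: two words match iff their 2007 keys are
equal.

Three ordering details are design choices of this package, since only the
substitution inventory is published, not its application order:

* substitutions are applied left-to-right, longest pattern first at each
  position, and the pass repeats to a fixpoint. The fixpoint matters: a
  substitution product (e.g. the I produced from E, followed by an
  original A) must itself resolve (IA → A), otherwise vowel-final stems
  fail to collapse across gender endings (TE + us/a/um would key TIS vs
  TIA). All published key examples are unaffected by the re-pass.
* the gender rule applies when at least one stem character survives (key
  length ≥ 3 before replacement). Stems whose entire non-initial part
  vanishes phonetically (e.g. "ie-": key "IS") are degenerate -- applying
  the rule would empty the stem -- and are the one class for which the
  gender triple does not collapse. The property test exempts exactly that
  class and nothing else.
* duplicates are collapsed again after the gender replacement, preserving
  the invariant that keys never contain adjacent repeated letters.
* MC → MAC applies anywhere in the remainder, and at most one leading
  pattern fires; nothing in the published examples disambiguates either
  choice.

### Padded n-gram similarity and authorities

Authority strings vary too freely for edit-distance thresholds (author
teams reordered, initials or years present or absent, diacritics mangled),
so similarity rather than distance is used: the multiset of length-*n*
windows of each uppercased string, padded with *n* − 1 spaces at each end,
shared instances divided by the mean gram count. Padding gives terminal
characters full representation ("Tony"/"Toby" move from 1/3 to 3/5);
padded bigrams are insensitive to token order ("Smith & Jones" vs "Jones &
Smith" score 1, trigrams 0.7333), which motivates the 2/3 bigram + 1/3
trigram blend used for authority comparison. The pad character is the
space character -- identical to internal token separators -- which is what
makes the token-permutation value come out at exactly 1.

Before comparison, authorities are normalized (`et`/`and` → `&` except in
`et al.`, initials compacted, comma inserted before a trailing year,
abbreviations such as `L.` expanded from a replaceable table, uppercased)
and pairwise adjusted: when exactly one string ends with a year, the last
three digits are dropped (`Linnaeus, 1758` → `Linnaeus, 1`); when exactly
one opens with a bracket, that bracket is dropped. Both rules soften,
without erasing, asymmetric formatting. The blend is computed on both the
diacritic-retaining and the ASCII-folded forms and averaged. A missing
authority yields `NA`, never 0: "no authority" is not "dissimilar", and
authority similarity is displayed but never used for ranking.

## The matching pipeline

A query is parsed positionally (genus, optional parenthesized subgenus,
epithet, rank-marked infraspecific pair, trailing authority; hybrid signs
removed and flagged; qualifiers `sp.`, `spp.`, `cf.`, `aff.`, `?` removed
and recorded), normalized (uppercase, hyphens removed, diacritics folded
through an explicit table), then matched:

1. **Genus pre-filter** over all unmasked genera. Passes on any of:
   equal 2007 genus keys (1a); query epithet key present among the target
   genus's species epithet keys and genus lengths within 3 (1b); lengths
   within 2 and a first/last substring band matching by length class (1c).
   Rule 1b is the safety net that makes the single-edit recall guarantee
   hold for binomials: a genus word damaged beyond 1c's substring bands is
   still admitted through its unchanged epithet. The one structural escape
   is a bare uninomial with an interior adjacent transposition at the band
   boundary of a 5--6 character word, which 1c as printed rejects.
2. **Genus distance** (MDLD, block 2) on survivors, early-abandoned above 3.
3. **Genus post-filter**: distance ≥ 4 discarded; phonetic matches
   accepted; otherwise at least 50% good characters (≤ 1 error in a ≤ 3
   character word, ≤ 2 in 4--5, ≤ 3 from 6; word length = the shorter
   name, a reading the rules state explicitly only for the pre-filter) and
   a matching initial character from distance 2.
4. **Species pre-filter**: children of surviving genera with epithet
   lengths within 4.
5. **Species distance** (MDLD, block 4) and **post-filter**: combined
   genus + epithet distance ≤ 4; phonetic epithets accepted; otherwise the
   50%-good-characters ladder (≤ 1/3, ≤ 2/5, ≤ 3/7, ≤ 4 from 8) with
   initial-character agreement at epithet distance 2--3 and a 3-character
   prefix at distance 4.
6. **Result shaping** (switchable off): distance-0 hits are reported as
   exact; combined distance ≤ 2 and phonetic hits are always returned;
   distance 3 only in their absence; distance 4 only when nothing closer
   exists. Genus-level shaping (1/phonetic, then 2, then 3) applies only
   to uninomial queries -- for binomials no near-match genus is rejected
   while it holds an accepted near-match species.
7. **Ranking**: combined distance 1 plus phonetic matches are "nearest
   matches", the rest "other near matches", alphabetical within groups.

"Phonetic match" for a binomial candidate means both genus keys and
(gender-normalized) epithet keys are equal; the published rules use the
bare phrase at both levels without defining the binomial case, and the
conjunction is the reading under which phonetic candidates deserve their
shaping immunity.

Reference checklists are indexed once (`build_index()`): normalized names,
lengths, 2007 keys, and per-genus epithet key sets are precomputed, and
rows flagged as misspellings, nomina nuda or later usages are masked --
present but never returned, so a stored misspelling cannot mask a true
hit during shaping. Genera with no species remain matchable at genus
level. `brute_force_match()` re-derives everything from raw strings per
record in a plain loop; the test suite asserts the optimized and naive
engines return identical reports on every tested query, which is the
sense in which the index is an optimization and not a semantics change.

Two execution variants are exposed: `rapid` mode restricts the genus
pre-filter to the phonetic rules 1a/1b (large speed gain, documented
recall loss for non-phonetic genus-only errors), and a free-text `group`
label restricts matching to a subset of the checklist. Both mirror the
reference system's deployment options; no taxonomic hierarchy is modelled.

## Synthetic data: what it emulates and what it does not

`generate_reference()` builds checklists from a consonant-vowel syllable
sampler: genus names of 4--16 characters, epithets of 4--14 with classical
endings -us/-a/-um/-is, unique per checklist, pure ASCII, deterministic
under a seed. The length ranges bracket the bulk of real genus/epithet
lengths (reference-checklist genus names peak at 9--12 characters); the
classical endings exercise the gender machinery. What the sampler does
*not* emulate: the real abundance of near-identical congeners (so
synthetic precision is optimistic), non-classical and dedicated
commemorative epithets, diacritics in authorities, and the skewed
species-per-genus distribution of real checklists. A green synthetic test
therefore establishes the structural recall properties and engine
equivalence, not field precision figures.

`generate_misspelling()` produces one error of a requested published type
(1a single non-initial edit; 1b non-initial adjacent transposition; 1c
word-start error; 2 two-character change; 3 two-character block
transposition or ≥ 3 edits; 4 errors in both words), resampling until the
independent classifier `classify_error()` reproduces the requested label
-- generator and classifier are consistent by construction, and the
distance contracts (e.g. Damerau-Levenshtein distance exactly 1 for types
1a/1b) are asserted through the edit-distance module. Two boundary
decisions: an adjacent two-character block swap is classified type 3 and
other two-character changes type 2; and a type-2/3/4 word-start edit is
not folded into 1c, which is reserved for single-character errors. The
type-3 "3+ transformations" branch samples three independent single-character
edits.

`evaluate_cases()` scores recall (fraction of cases whose designated
target is returned anywhere), pooled precision (true hits over all
returned hits) and F1, with recall disaggregated by error type. Under the
stated synthetic world -- 200 genera × 5 species, 200 cases per type --
normal-mode recall for types 1a, 1b and 1c is 1.000, which the acceptance
suite asserts exactly; this mirrors the structural single-edit guarantee
rather than a tuned threshold.

## Numerical and scale choices

* Distances are integers (as `numeric`, with `Inf` as the abandon
  sentinel); similarities are exact ratios of integer counts, so the
  worked-example tests compare at machine precision against fractions
  like 11/15.
* Ties in ranking are broken alphabetically by full name; candidate
  data.frames carry both per-word and combined distances.
* Year detection in authorities accepts 1500--2099 with optional closing
  bracket; abbreviation expansion applies only to whole tokens ending in
  a period, so surnames are never mangled.
* The exhaustive oracle sweep for the edit distance covers all string
  pairs to length 4 over a 3-letter alphabet (14,641 pairs, three block
  limits) plus 400 sampled length-5--6 pairs per limit; engine-vs-oracle
  equivalence uses a 20--30 genus index and ~60 queries across all error
  types and all three modes. These scales keep the default suite within
  a single-CPU minute-scale budget; the properties are scale-free, so
  widening the sweep only re-verifies the same invariants.
* The evaluation index for the acceptance recall targets (200 × 5) runs
  in seconds; real-checklist benchmark tables from the source system
  (465k genera / 1.67M species) are out of scope by design.

## Known limitations

* Subgenus and infraspecific recursion are parsed but not matched;
  hybrid formulae are split and each parent matched separately.
* The parser is positional, not a full nomenclatural grammar: cultivar
  names, chresonyms and named hybrids beyond sign removal are out of
  scope.
* Uninomial queries with an interior adjacent transposition at the 1c
  band boundary (5--6 character words) can be missed unless phonetically
  equal -- the documented pre-filter gap above, which binomials do not
  share.
* Authority similarity is a lexical blend; it does not model author-team
  semantics ("Prins in Grün et al."), and published screenshot values
  from the reference system cannot be reproduced without its target
  strings.
* The CLI takes flags only (no YAML configuration file), and filter
  constants are frozen to the published rule set rather than re-tunable
  against new training data.
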
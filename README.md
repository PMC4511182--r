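# bbrelex

Co-reference-aware extraction of **Localization** and **PartOf** relations
between bacteria, habitats and geographical locations from
encyclopedia-style texts in BRAT standoff format (the Bacteria Biotope
dialect: `.txt` + `.a1` entity mentions + `.a2` relations and `Equiv`
co-reference groups).

Texts about a bacterium routinely introduce it once by its full binomial
name and then switch to an abbreviation (*B. subtilis*), a strain variant
(*Borrelia afzelii* PKo) or a definite description ("This organism ...").
Relations, however, are facts about *entities*, so a supervised relation
classifier that only sees mention pairs both misses distant instances at
decoding time and — more damagingly — mislabels them as negative examples
during training. `bbrelex` is for text-mining practitioners who want to
measure and exploit exactly that effect.

## What it implements

1. **Mention detection** — linear-chain BIO labeling with an
   L1-regularized log-linear model over surface, lexicon (OBO ontology,
   taxon list), Brown-cluster and Cocoa-category features, plus a
   nested-mention re-injection rule.
2. **Co-reference resolution** — precision-first rules: *similarity of
   form* (identity, conventional abbreviation, strain-designator matching,
   Damerau-Levenshtein distance ≤ *e* = 1, generic *bacteria* mentions
   blocked) and *anaphora* (centering/recentness tracking of the focus and
   last bacterium, sentence-initial definite descriptions), closed
   transitively into chains.
3. **Relation detection** — candidate pairs P respecting the signatures
   (PartOf: Habitat→Habitat; Localization: Bacteria→Geographical/Habitat),
   restricted to P_s (sentence distance ≤ *s* = 3); positives G = gold
   instances closed under the predicted equivalence classes; balanced
   negatives sampled from P_s \ G; a logistic (MaxEnt) classifier with
   mention/type/distance/POS/Cocoa/context features; anaphora-created
   arguments rewritten onto chain representatives.
4. **Scorers** — chunk-level mention P/R/F; MUC, B-cubed and CEAF (exact
   Hungarian alignment) for co-reference; equivalence-aware relation
   matching that conflates co-referring mentions through gold `Equiv`
   groups.
5. **Synthetic corpus generator** — deterministic, seeded
   encyclopedia-style documents with gold annotations and all four feature
   resources, so the whole pipeline trains and evaluates offline.

## Worked example

```r
library(bbrelex)

dir <- file.path(tempdir(), "demo")
generate_corpus(synth_config(n_docs = 30, seed = 7), dir)
corpus <- read_corpus(dir)
split  <- corpus_split(corpus$docs)   # 70/30 train/eval

with_coref <- run_task2(split$train, split$eval, corpus$resources,
                        strategy = "sim")
without    <- run_task2(split$train, split$eval, corpus$resources,
                        strategy = "none")
print(with_coref$score)
#> R = 0.956  P = 1.000  F = 0.977
print(without$score)
#> R = 0.667  P = 0.909  F = 0.769
```

With gold mentions provided (the "task 2" setting), similarity-based
co-reference lifts relation F from 0.769 to 0.977 on this corpus: the
recall gap is exactly the relations that are only expressed through an
abbreviated or strain-suffixed name variant far from the full name, which
the no-co-reference system cannot label correctly during training nor reach
at decoding time.

The building blocks are exported individually:

```r
doc <- corpus$docs[[1]]
res <- resolve_coreference(doc)       # similarity + anaphora + closure
res$chains[[1]]
#> $members
#> [1] "T1" "T2" "T4" "T8"
#> $representative
#> [1] "T1"

damerau_levenshtein("Campylobacter", "Campilobacter")
#> [1] 1
abbreviation_match("Bacillus subtilis", "B. subtilis")
#> [1] TRUE
```

`run_task3()` runs the end-to-end setting (predicted mentions feed
co-reference and relation detection). A command-line front end with
`synth`, `run-task2`, `run-task3` and `score` subcommands is installed at
`inst/scripts/bbrelex`.

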
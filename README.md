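# melent

Information-theoretic modeling of melodic expectation and predictive
uncertainty.

## The problem

While listening to a melody, a listener holds expectations about the
pitch of the next note *before* it sounds. Two properties of that
prospective state matter: how unexpected the note turns out to be once it
arrives, and how uncertain the listener was beforehand. `melent` models
both with a variable-order Markov model of pitch expectation: the model
assigns a conditional probability distribution p(x₁)…p(xₙ) over the
possible next pitches given the preceding context, and summarizes it with

- **information content** IC(xᵢ) = −log₂ p(xᵢ) — the surprisal of the
  note that actually occurred (unexpectedness), and
- **Shannon entropy** H = −Σ p(xᵢ) log₂ p(xᵢ) — the uncertainty of the
  prediction itself, with H_max = log₂ n and H_norm = H / H_max.

The package is aimed at auditory-cognition researchers who want to (a)
train such a model on symbolic melodic corpora, (b) select probe-tone
stimuli whose predicted entropy is systematically high or low, (c)
simulate listeners whose unexpectedness ratings are a noisy monotone
function of model IC, and (d) run the full behavioral analysis —
inferred/explicit uncertainty, mixed-design ANOVAs, dependent-correlation
tests, reliability, and a model-comparison grid against rule-based
competitors — end to end, reproducibly, without any external corpus.

## The model

The expectation model is an n-gram model with PPM-style smoothing
(escape method C by default, interpolated blending, update exclusion
during training). Notes are represented as linked viewpoint symbols —
pitch interval × chromatic scale degree, optionally × inter-onset
interval contour — so predictions generalize across transposition. Two
sub-models run in parallel: a **long-term** model trained on a corpus
(schematic, enculturated expectation) and a **short-term** model that
starts empty for each melody and learns on line. Their distributions are
combined by an entropy-weighted geometric mean: each sub-model gets
weight H_norm⁻ᵇ, so the more confident sub-model dominates (b = 1 by
default, b = 0 gives equal weights). With the order bound set to
`"variable"` the context length is chosen per prediction PPM*-style (the
shortest deterministic matching context, else the longest match).

Around the model sit: Krumhansl–Schmuckler key finding with
Krumhansl–Kessler or Temperley profiles; the two-stage entropy-driven
stimulus-selection procedure (corpus-wide per-note entropy ranking,
candidate-context segmentation, nine chromatic probe tones centered on
the context median, final re-ranking by 9-tone renormalized entropy); a
three-predictor Implication–Realization regression baseline (proximity,
pitch reversal, tonal hierarchy); the Schmuckler mean-minus-minimum
difference score; and the behavioral statistics used to analyze rating
data.

## Worked example

Train a long-term model on a synthetic tonal corpus and query the
expectation after a short context:

```r
library(melent)

grammar <- tonal_grammar(pitch_range = c(60, 77), uniform_mix = 0.05, seed = 1)
train_corpus <- generate_markov_corpus(grammar, n_melodies = 30,
                                       notes_per_melody = 40)
train_corpus
#> <melody_corpus> 30 melodies, 1200 notes, alphabet of 18 pitches [C4-F5]

cfg <- model_config(order_bound = "variable", configuration = "both")
ltm <- train_ltm(train_corpus, cfg)

context <- melody(c(60, 64, 62, 65, 64, 67, 65, 64), id = "query")
d <- predict_next(context, key(0, "major"), corpus_alphabet(train_corpus),
                  ltm = ltm, stm = ngram_store(), config = cfg)
dplyr::arrange(d, dplyr::desc(p)) |> head(3)
#>   pitch      p
#> 1    63 0.329
#> 2    64 0.0938
#> 3    62 0.0897

entropy_bits(d)          # 3.357 bits of predictive uncertainty
normalized_entropy(d)    # 0.805 of the maximum for 18 pitches
information_content(d, 64)  # 3.415 bits: hearing E4 here is fairly surprising
```

The model considers D#4 the most likely continuation (p ≈ 0.33); the
distribution is fairly flat (H_norm ≈ 0.8), so a listener with this
internal model would report high uncertainty about the continuation.

The full synthetic experiment — corpus generation, training, stimulus
selection, listener simulation, analysis, model comparison — runs under
one seed:

```r
res <- run_experiment_pipeline(out_dir = "results/run1")
res$stimuli               # 24 contexts: 6 per style x entropy-class cell
tidy(res$analysis$anovas$inferred$anova)  # mixed 2x2x2 ANOVA table
res$comparison            # model-comparison grid incl. competitors
```

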
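# physvoe

Intuitive physics is the everyday knowledge that objects persist, keep their
properties, move along continuous paths, do not interpenetrate, and change
direction lawfully when they collide. Developmental psychology measures this
knowledge in infants with the **violation-of-expectation (VoE)** paradigm:
show matched displays that are physically possible or impossible and compare
how surprising each is. `physvoe` is a desk-scale R toolkit for running that
paradigm on learned video-prediction models. It is aimed at computational
cognitive scientists and machine-learning researchers who want a fully
self-contained, procedurally generated VoE benchmark plus a reference
object-centric model, with every component testable against closed forms.

The toolkit contains:

- a deterministic rigid-body **simulator + ray-cast renderer** producing
  T-frame RGB videos with per-object segmentation masks and camera tracks,
  and a composable "freeform" training-scene generator (rolling, collisions,
  occlusion curtains, stacks, covering, containment, ramps);
- a **probe factory** for five physical concepts — continuity, object
  persistence, unchangeableness, solidity, directional inertia. Each probe
  tuple holds 2 possible + 2 impossible videos built by splicing around a
  pixel-identical common frame, so both probe types contain exactly the
  same frames *and* the same adjacent frame pairs (`verifyProbeTuple()`
  checks both, pixel-exactly);
- an **object-centric model**: a slotted component VAE mapping each masked
  object to a D-dimensional Gaussian code, and an **InteractionLSTM**
  dynamics predictor — per-slot LSTMs with shared weights, pairwise
  interaction messages from each slot's cell state to all cell states and
  all projected object-history buffers, aggregated as concat(sum, max),
  with camera conditioning and a residual connection. Flat baselines match
  the slotted model in parameter count (FEP) or representational capacity
  (FEC);
- a **VoE harness**: per-video surprise is the summed squared pixel error
  between decoded observed and decoded predicted object codes,

  surprise(video) = Σ_{t=1}^{T−1} Σ_{k=1}^{K} (Θ(z_k^{t+1}) − Θ(ẑ_k^{t+1}))²,

  a tuple's relative surprise is (impossible − possible)/(impossible +
  possible), accuracy is 1 iff impossible > possible (strictly), and
  seed-level means are tested with one-tailed one-sample t-tests against
  chance (0 and 0.5).

## Worked example

```r
library(physvoe)
prof <- deskProfile()

# one verified continuity probe tuple: a ball rolls behind two pillars
tup <- makeContinuityProbe(7, prof)
tup
#> <ProbeTuple: continuity, 15 frames 24x24, violation onset 6/6, seed 7>
ver <- verifyProbeTuple(tup)
ver$frame_match; ver$pair_match
#> TRUE  TRUE

# reference predictors bound the evaluation: a memorizing oracle is
# perfectly unsurprised by possible videos and flags every violation ...
percep <- perceptionInit(prof, seed = 1)
scoreTuple(tup, percep, voePredictor("oracle"), rng_seed = 1)[
  c("possible_surprise", "impossible_surprise", "accuracy")]
#> possible 0.00   impossible 10508.44   accuracy 1

# ... while a copy-last-code predictor is chance-level by construction,
# because every adjacent frame transition of an impossible video also
# occurs in a possible one
scoreTuple(tup, percep, voePredictor("copy_last"), rng_seed = 1)[
  c("possible_surprise", "impossible_surprise", "accuracy")]
#> possible 11231.86   impossible 12234.55   accuracy 1   (a coin flip per tuple)

# the flat equal-parameters baseline matches the slotted model's dynamics
# parameter count exactly; equal-capacity exceeds it by ~2.9M
pp <- fullProfile()
countParameters(dynamicsConfig("plato", pp))
#> 44783424
countParameters(dynamicsConfig("fep", pp)) == countParameters(dynamicsConfig("plato", pp))
#> TRUE
countParameters(dynamicsConfig("fec", pp)) - countParameters(dynamicsConfig("plato", pp))
#> 2864624

# seed-level statistics in the usual reporting style
st <- aggregateSeeds(c(0.048, 0.041, 0.044, 0.050, 0.037), 0)
sprintf("M=%.4f sd=%.4f t(%d)=%.1f p=%.2g", st$mean, st$sd, st$df, st$t, st$p_one_tailed)
#> "M=0.0440 sd=0.0052 t(4)=18.8 p=2.4e-05"

# bookkeeping: how much visual experience a 300,000-video corpus contains
visualExperience(300000, 2, 8)
#> 600000 s = 6.94 continuous days = 20.8 wakeful (8 h/day) days
```

The oracle's zero possible surprise confirms the violations are detectable
in principle; the copy-last control shows why a model must integrate more
than one frame of context (for example, extrapolate velocity or remember an
occluded object) to beat chance. An end-to-end desk-scale training run —
`generateFreeform()` → `trainPerception()` → `encodeVideos()` →
`trainDynamics()` → `runExperiment()` — takes on the order of fifteen
minutes on one CPU; see the methods vignette
(`vignettes/physvoe-methods.Rmd`) for what desk scale can and cannot show.

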
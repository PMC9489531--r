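---
title: "Probing intuitive physics with violation-of-expectation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probing intuitive physics with violation-of-expectation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

Developmental psychologists probe physical knowledge in infants with the
violation-of-expectation (VoE) paradigm: show visually matched displays that
are either physically possible or impossible, and ask whether the observer is
more surprised by the impossible ones. `physvoe` ports that paradigm to
machine learning models at desk scale. It contains four connected pieces:

1. a deterministic rigid-body **simulator and renderer** producing short RGB
   videos with per-object segmentation masks and a camera track;
2. a **probe factory** that constructs matched tuples of two possible and two
   impossible videos for five physical concepts — continuity, object
   persistence, unchangeableness, solidity and directional inertia — via a
   frame-splicing construction with machine-checkable guarantees;
3. an **object-centric model**: a slotted component VAE (perception) and an
   InteractionLSTM next-step predictor over object codes (dynamics), with
   parameter-matched flat baselines;
4. a **VoE harness** computing pixel-space surprise, relative surprise,
   accuracy, frame-wise curves and seed-level statistics.

This vignette records the modelling choices, the places where the design was
genuinely open, and what the desk-scale experiments do and do not show.

# The world model

## Physics core

The simulator is intentionally simple: probe semantics need occlusion,
contact and trajectory kinematics, not contact-rich rigid-body dynamics.
Coordinates are right-handed with z up and the ground plane at z = 0; world
units are arbitrary; gravity defaults to 9.8 units/s² and every video spans
2 s. The core supports:

- **ballistic flight** integrated with the exact constant-acceleration
  update (`p += v dt − ½ g dt²ẑ`), so free flight matches the closed-form
  parabola to machine precision — this is a tested invariant, not an
  approximation claim;
- **ground/support contact** with inelastic rest (the contact time inside a
  step is solved exactly);
- **constant-velocity rolling** with exact-time impulse reflection off heavy
  static boxes (velocity mirrored about the contact-face normal, preserving
  speed and the angle of incidence);
- **equal-mass velocity exchange** for rolling sphere collisions;
- **scripted keyframed motions** for events the point-mass core cannot
  produce dynamically: curtain descent/retraction, the overturning plank
  (quadratic ease-in of the hinge angle, mimicking an accelerating
  rotational fall, clamped at the propped angle), and ramp rolls
  (uniform acceleration g·sin α along the incline).

A body's speed therefore never increases except under gravity or at a
scripted/impact event, and `(spec, n_steps) → video` is a pure function:
identical seeds give bit-identical outputs, which the probe construction
relies on.

## Renderer

Frames are rendered by per-pixel ray casting: perspective pinhole camera,
nearest-hit depth ordering (an exact painter's algorithm), flat object
colours, a two-colour checkerboard floor as the depth cue, and a fixed sky
colour. The mask label of a pixel is the nearest object along its ray, so
occluded portions of objects are absent from their own channel, mask
channels are mutually disjoint by construction, and channel k always depicts
object id k. Sky and floor share channel 0 (no separate background channel).
Masks live in channel-stacked binary form with documented conversions to and
from integer-labelled planes (`masksToLabels()` / `labelsToMasks()`).

Camera intrinsics and the drift bounding box are not dictated by anything
upstream; they were chosen once for visual plausibility (vertical field of
view 0.9 rad; canonical start pose at (0, −9, 3.2) looking at (0, 0, 1);
clipped Gaussian random walk with per-frame s.d. 0.12 for training scenes)
and are configuration, not ground truth. Probes always use a stationary
camera so that objects are occluded during the physical-to-aphysical
transition.

## Freeform training scenes

Training scenes are composed from two to four building blocks (rolling,
ground collisions, drop/throw collisions, occluding curtains, stacks,
covering, containment, ramps). Blocks advertise and/or consume locations of
interest; with probability `1 − p_compose` (default `p_compose` = 0.6) a
block places itself independently instead. Object masses follow a
stereotyped table: rolled and stacked objects 10, dropped/thrown objects 40
(four times heavier so they displace what they hit), containers 4 or 5,
arches 60 in total. Colours and the floor checkerboard are uniform random
RGB. One mask channel is reserved for the floor, so a scene uses at most
K − 1 object ids.

# Probe construction and its guarantees

Each probe tuple holds two possible videos and two impossible videos with
identical stationary cameras. The generic construction simulates two
possible scenes A and B that are pixel-identical at one *common frame*
(index stored in the tuple); the impossible videos are A-start + common +
B-end and B-start + common + A-end. Both probe types then contain exactly
the same multiset of frames, and every adjacent ordered frame pair of an
impossible video occurs in some possible video — so no single frame or
frame pair can reveal the violation; only longer temporal context can.
`verifyProbeTuple()` checks both properties pixel-exactly (equality
tolerance exactly 0; the matching guarantee is the dataset's core property,
and the deterministic renderer makes exact equality attainable). Every
generated tuple is verified; generation retries bounded-many times on
geometric failure.

Concept-specific constructions:

- **Continuity** — a ball rolls behind two pillars whose width matches the
  ball's diameter (the pillar is nearer the camera than the ball, so its
  angular width strictly covers the ball's when centred). Possible videos:
  the rolling scene, and the identical scene with no visible ball.
  Impossible videos are built by visibility masking rather than a segment
  swap: the ball is withheld exactly while it would be between the pillars
  (or shown only there). Because a fully-occluded frame is pixel-identical
  to the corresponding empty-scene frame, both matching checks still hold.
  The violation onset is the first masked-visibility frame.
- **Object persistence** — a drawbridge-style plank rotates from flat
  (towards the camera) up and over away from it. In scene A it lands on an
  object behind the hinge and remains propped while occluding it (the
  screen reaches the ground in front of the object, so occlusion is total
  once the angle passes the sight line); in scene B the scene is empty and
  the plank falls flat. The common frame is the last frame at which the
  schedules agree and the object is fully occluded.
- **Unchangeableness** — two static objects differing in colour/shape are
  covered by one full-width screen that descends and rises; the two
  possible scenes use mirrored arrangements and splice at a fully-covered
  frame. A single occluder (rather than per-object occluders as in the
  developmental literature) keeps procedural generation simple; the
  resulting impossible events are also consistent with an alternative
  reading — objects trading places through self-propelled motion — which is
  documented here rather than resolved.
- **Solidity** — the camera views inside the top of an open container but
  not its bottom. Two blocks share one cross-section and colour but differ
  in height, and are dropped so their top faces coincide while falling; at
  the common frame both are partially hidden behind the container's front
  wall with identical visible portions. The tall block rests visibly
  protruding, the short one fully hidden. The mismatched endings realize
  the two impossible variants: a block that should have remained visible
  disappears (as if it fell through container and floor), and a block
  remains visible at the top when it should have fallen further.
- **Directional inertia** — a ball rolls at 25–55° towards a heavy block
  and reflects about the angle of incidence; the second possible video is
  the exact time reversal, and the contact frame (at the middle of the
  video, t = 1 s) is the common frame. The swapped endings send the ball
  back towards its origin, violating directional inertia.

Violation onset is stored 1-based as the index of the first aphysical frame
(`common + 1` for splice-based concepts), used to align frame-wise curves.
Segment lengths per concept are fixed by the scripted timings so each video
is exactly T = 15 frames.

# Perception: a slotted component VAE

Each frame is decomposed by the ground-truth masks into K object image-mask
pairs x_k = x ⊙ m_k. A shared encoder maps (x_k, m_k) to a D-dimensional
diagonal Gaussian posterior q(z_k | x_k, m_k); the floor slot has its own
parameter set (the ground plane is treated as its own object). The object
code is a reparameterised *sample* from the posterior (using the mean is a
documented alternative; sampling follows the source methodology and keeps
the chance-level controls well behaved, see below). Empty channels still
produce posteriors and are tasked with reconstructing an all-zero object
image and mask, so the code space comes to represent "no object" near the
unit-Gaussian prior.

The decoder is a spatial broadcast decoder: the code is broadcast over a
pixel grid with two coordinate channels and passed through a per-pixel
network (1×1 convolutions; ReLU hidden units, sigmoid RGB output, one mask
logit). The layer architecture is not dictated by anything upstream; at
desk scale the encoder is a one-hidden-layer ELU network on the flattened
masked image. These are configuration choices, documented, not claimed as a
replication of any particular full-scale architecture.

The training objective per slot is

- Gaussian reconstruction NLL of the masked object image with a fixed
  decoder scale σ = 0.3 (so a perfect reconstruction reports the analytic
  constant floor rather than zero),
- plus γ · BCE(mask logits, m_k) with γ = 10 (mask fidelity),
- plus β · KL(q ‖ N(0, I)) with β = 0.1.

Optimisation is RMSProp. The full-scale schedule (learning rate 1e-4, 1e6
steps, batch 64) is recorded in `fullProfile()` as documented defaults;
the desk profile trains far fewer steps at a higher rate (see "Scale
profiles").

# Dynamics: the InteractionLSTM

Slot k's inputs at step t are its *object buffer* — the zero-padded history
of its codes over frames 1..t, padded at the future end so time indices
align with frame indices — and the previous LSTM state. The flattened
(T−1)×D buffer of each slot is projected by one linear map + ELU into a
P-dimensional space (P = 1680 at full scale). Projecting the whole history
at once (rather than each frame separately) is the reading of the
"projected buffer" that also reproduces the documented parameter
relationship between the flat baselines and the slotted model: with
per-frame projection the equal-capacity baseline would gain only ~0.4M
dynamics parameters instead of the expected several million.

The interaction network computes messages from each slot's previous cell
state to every cell state (MLP ρ) and to every slot's projected buffer
(MLP λ); both MLPs have three layers of U units with the GELU activation,
and the embedded current camera pose is appended to every message input.
Self-pairs are included (the simpler reading of "to all slots"), and the
floor slot participates as a "from" slot by default. Messages aggregate as
concat(sum, max) — fixed in that order. The per-slot LSTM (shared weights
ψ, object-specific activations) receives concat(projected buffer,
interaction, embedded next-frame camera) — fixed in that order — and a
linear head plus a residual connection from z_k^t produces the prediction
ẑ_k^{t+1}. The teacher-forced loss is Σ_t Σ_k (z_k^{t+1} − ẑ_k^{t+1})²,
with a fresh posterior sample per frame (seeds logged).

Because all slot weights are shared, the dynamics parameter count is
independent of K. The flat equal-parameters baseline (one slot, same D)
therefore has *exactly* the slotted model's dynamics parameter count; the
flat equal-capacity baseline (one slot, D × K code) exceeds it through the
wider buffer projection and prediction head (≈2.9M extra at full-scale
dimensions). Flat models receive a single all-ones mask channel.

Open details fixed here and visible in code: the exact LSTM input ordering;
camera featurization as the 7-vector (position, quaternion) linearly
embedded (dimension E per profile); inclusion of the floor slot in the
interaction "from" set.

# VoE evaluation

Surprise for a video is computed in pixel space: for each step, both the
observed next codes and the predicted next codes are decoded through the
perception decoder Θ and the squared pixel differences are summed over all
slots; the per-video surprise is the sum over steps. Pixel space (rather
than code space) matters because empty-slot codes have high posterior
variance yet all decode to the same blank image; and within a tuple the
possible and impossible videos contain identical objects, so the usual
object-size bias of pixel losses cancels.

Per tuple, the two possible and two impossible surprises are summed;
relative surprise is (impossible − possible)/(impossible + possible)
(defined as 0 when both are 0), and accuracy is 1 iff the impossible
surprise is strictly greater — ties count as incorrect. Frame-wise curves
apply the same normalization at each frame (the tuple-level formula applied
framewise; whether to normalize per frame or by video totals was open, and
framewise normalization is used and documented). Seed-level statistics are
one-sample, one-tailed t-tests of per-seed metric means against chance (0
for relative surprise, 0.5 for accuracy), with normal-theory 95% CIs;
normality across seeds is assumed, not tested, and no multiple-testing
correction is applied. `visualExperience()` performs the bookkeeping from
video counts to seconds and (continuous or 8-h-wakeful) days of visual
experience.

Three reference predictors anchor the evaluation:

- **copy-last** predicts ẑ^{t+1} = z^t. The pair-matching guarantee makes
  every adjacent transition of an impossible video occur in a possible one,
  so the *expected* copy-last surprise is identical across probe types and
  its accuracy is driven to chance by the independent posterior-sampling
  noise — this is a designed control, and is why evaluation samples codes
  rather than using posterior means (means would produce exact ties).
- **untrained dynamics** (the '0'-training condition) behaves like a noisy
  copy-last thanks to the residual connection, and must also sit at chance.
- the **memorizing oracle** predicts the codes of the possible video that
  shares each probe's start segment; it scores exactly zero surprise on
  possible videos and accuracy 1, confirming that the violations are
  detectable in principle from the decoded codes.

A predictor can only beat chance by using more than one frame of context
(for instance extrapolating velocity), which is precisely the temporal
structure the splicing construction isolates.

# Scale profiles and desk-scale expectations

`fullProfile()` records the full-scale configuration as documentation:
64×64 frames, K = 8 slots, D = 16 codes, 2056 LSTM units, 1680-d buffer
projection, 512-unit interaction MLPs, 3000 simulation substeps, 300,000
training videos, 1e6/1.3e6 training steps. Those numbers are not run here.

`deskProfile()` is the configuration the package actually runs end-to-end
on one CPU: 24×24 frames, K = 4 slots, D = 8 codes, 256 LSTM units, 128-d
projection, 64-unit MLPs, 400 simulation substeps, 2,000 training videos,
and short RMSProp schedules (hundreds of steps). The acceptance workflow
generates its probe sets at 100–200 tuples per concept.
These sizes are the package's own choices for a reproducible desk run and
are *not* a replication of full scale: desk-scale training yields a weak
next-step predictor, so desk VoE effect sizes are far smaller than
full-scale ones, and per-concept accuracies can hover near chance even when
the pipeline is correct. The property-based checks (splice guarantees,
oracle equivalences, physics closed forms, parameter parity, chance-level
controls, oracle accuracy 1) are the desk-scale evidence of correctness;
the trained-model accuracy is reported as an additional, noisier signal.

## What the generator does not emulate

The synthetic scenes have flat colours, no lighting, no textures beyond the
checkerboard, no friction cones or torque-driven toppling, and scripted
rather than emergent curtain/plank/ramp events. Passing tests on these data
show that the pipeline and its guarantees are correct and that the models
can learn the regularities *of this world*; they do not show robustness to
photorealistic appearance, contact-rich dynamics, or real video.

# Numerical choices and degenerate inputs

- Common-frame equality and all probe verification comparisons are exact
  (tolerance 0) on uint8 pixels.
- Posterior log-variances are clamped to [−8, 8]; ELU inputs are clamped
  below 30 before exponentiation; the scene-composite weight normalizer
  guards against all-zero masks with ε = 1e-8.
- Degenerate camera bounds yield a constant track; a single-frame request
  returns only the canonical pose.
- Probe generation rejects geometries without full occlusion (continuity,
  persistence), without divergent endings (all concepts), or with blocks
  resting visibly when they should hide (solidity), and retries with a
  derived seed, up to 25 attempts.
- Seed-level t statistics define t = 0 (p = 0.5) when all seeds equal the
  null value exactly.
- All randomness flows through integer seeds; derived seeds stay inside
  32-bit range.

# Known limitations

- The simplified core cannot produce emergent toppling, rolling friction or
  stacking collapse; those events are keyframed.
- Desk-scale training is too short for strong VoE effects; the stretch
  desk-training check can legitimately land near chance on some concepts.
- The perception encoder is a small fully-connected network; at higher
  resolutions a convolutional encoder would be the natural replacement.
- Probe diversity is limited to the five concepts; drawbridge-style
  external generalization probes are out of scope.
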
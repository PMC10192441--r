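---
title: "Decoding an eye-gesture communication language"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding an eye-gesture communication language}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eyespeak)
```

## The problem

Patients in the late stages of motor neuron disease (ALS/PLS) lose voluntary
muscle control progressively until eye movement is the only channel left for
communication. `eyespeak` implements a camera-based decoding pipeline for a
four-state eye-gesture language: **Left**, **Right**, **Up** and **Blink**.
Every sentence is a fixed-length sequence of three states, so a language with
$n$ recognised states and $k$-state sentences can express $n^k$ sentences —
with $n = 4$, $k = 3$ that is exactly 64 phrases, enough to cover daily-life
needs with short training time. The four *no-transition* codes (`LLL`, `RRR`,
`UUU`, `BBB`) are deliberately reserved for the most basic needs — Water,
Food, Toilet, "I am Okay" — because repeating one state is the fastest and
least tiring gesture a patient can produce.

The pipeline has four stages, each usable on its own:

1. **Landmark frontend** — 68 facial landmark coordinates per frame
   (iBUG 300-W layout), from which the two 6-point eye sets are sliced.
2. **Blink detector** — the eye aspect ratio (EAR) per frame, open/closed
   thresholding, and natural-vs-intentional blink discrimination.
3. **Gaze classifier** — pupil segmentation by masking, dilation, fixed
   thresholding and largest-contour extraction; direction from the pupil's
   normalised position.
4. **Decoder** — debounced gesture events accumulate in a tracking list of
   three and emit dictionary phrases.

## The blink model

For the six eye landmarks $p_1 \dots p_6$ ($p_1, p_4$ the horizontal corners,
$p_2, p_3$ on the upper lid, $p_5, p_6$ on the lower lid), the eye aspect
ratio is

$$EAR = \frac{\lVert p_2 - p_6\rVert + \lVert p_3 - p_5\rVert}
             {2\,\lVert p_1 - p_4\rVert}.$$

The ratio is near-constant while the eye is open and collapses to about zero
when it closes, and — being built from Euclidean norms of differences — it is
invariant under translation, rotation and uniform scaling of the landmarks.
A frame is **closed** when $EAR \le t$ and **open** when $EAR > t$; the
threshold boundary is inclusive on the closed side, and $t = 0.2$ by default.

A maximal run of closed frames is one blink. Natural blinks last 100–400 ms;
the deliberate language blink is held around 800 ms. At 25 frames per second
the discrimination rule is a run length of **13 frames** (~520 ms): shorter
runs are natural blinks (reported, but never fed to the decoder), runs of 13
or more are intentional. The 13-frame constant is tied to 25 fps capture, so
when a different frame rate is configured and no explicit override is given,
`blink_config()` rescales it as `round(13 * fps / 25)`, preserving the
duration criterion rather than the frame count.

Two eyes give two EARs per frame; the package averages them for blink
decisions (`ear_mean`) while keeping the per-eye values observable. The
combination rule is a package choice — averaging is robust to single-eye
landmark jitter — since only the per-eye ratio itself is prescribed.

## The gaze model

Per frame and per eye, the segmentation procedure is:

1. draw the filled 6-point eye polygon in white on a black mask of the
   frame's dimensions and grow it with one binary dilation (5 px square
   structuring element by default);
2. extract the eye by masking the grayscale frame, then convert the zeroed
   background to 255 so the dark pupil is the only dark region left;
3. binarise at a fixed intensity threshold (default 70/255) and keep the
   largest dark contour with area at least `min_contour_area` (default 9 px);
4. the contour centroid, normalised to the eye landmark bounding box, gives
   $(g_x, g_y) \in [0,1]^2$.

"Convert zeros to 255" is read as: everything outside the dilated eye
polygon becomes white, so thresholding can only ever find structure inside
the eye region. That reading is isolated in `segment_eyeball()`.

Direction mapping (`classify_direction()`): **UP** when
$g_y < 0.35$; otherwise **LEFT**/**RIGHT** when $g_x$ passes the horizontal
margins (0.40/0.60); otherwise **CENTER**. Three choices deserve comment:

* *Vertical precedence.* An up-gaze also perturbs $g_x$, so the vertical
  test runs first.
* *Subject frame.* Directions are named from the patient's point of view: in
  an un-mirrored camera image the subject's LEFT appears as a pupil shift
  toward the image's right half. `mirror_convention = "viewer"` flips this
  for mirrored capture chains.
* *CENTER is not part of the published 1/2/3 direction codes.* It exists so
  the decoder can demand a return to neutral between gestures; without it a
  long leftward look would be indistinguishable from `LLL`. An eye-down
  state is never produced — it conflicts with blinking and is excluded from
  this version of the language.

Both eyes are segmented and must agree; disagreement or a missing pupil
yields UNKNOWN for the frame. UNKNOWN frames are transparent to the decoder
(they neither register gestures nor end an excursion).

## The decoder

A lateral/up classification must persist for `gesture_debounce_frames`
consecutive frames (default 10, ≈400 ms at 25 fps) to register one gesture,
and registers at most once per excursion from CENTER. The debounce default
is a package choice: the published system describes dwell only for
letter-board interfaces (one second), so 400 ms was picked as a balance
between speed and saccade noise, and it is configurable.

Registered gestures fill a tracking list of at most three; each full triple
emits its phrase and clears the list, and a trailing incomplete group emits
nothing. After an unrecognised interval the patient has a five-second
correction window: within it pending gestures are preserved; when it expires
the list is cleared and the reset is logged. (The published interaction
diagram specifies the window but not its expiry behaviour; clearing on
expiry is the package's reading.)

Blink runs at the boundaries of a recording need care: a run truncated at
the *start* has an unknowable duration and is ignored. A run flagged at the
*end* of a finite recording is accepted by default (`boundary = "end"` in
`register_gestures()`): the recording closed while the eye was still shut,
and the observed run length already satisfies the intentional rule. Scripted
clips place their neutral gap *before* each gesture, so a clip ending in a
blink would otherwise lose its final gesture.

## Streaming and the speed model

In deployment, frames stream from a phone camera to the processing backend;
when they arrive faster than face/eye processing drains them, a bounded
**drop-oldest queue** keeps the stream current: at capacity $c$ with $f > c$
frames injected, occupancy never exceeds $c$ and exactly $f - c$ oldest
frames are dropped. Reconstruction of dropped frames from their neighbours
is *not* implemented (a documented gap). `stream_session()` is the
in-process double of the concurrent receive/process transport, used by the
tests to interleave bursty producers with stalling consumers.

Communication speed decomposes as $CS = P + T$: server processing time plus
transmission time. $T$ follows the chain $F = D \cdot FR$, $X = F \cdot R$,
$B = 8X$, $T = B / N$ for clip duration $D$ (s), frame rate $FR$, resolution
$R$ (pixels/frame), and bandwidth $N$ (bits/s). $P$ is an empirical input
(the deployed backend measured three to four seconds per sentence), not a
modelled quantity.

```{r speed}
m <- communication_speed(D = 2, FR = 25, R = 1e4, N = 1e6, P = 3.5)
glance(m)
```

## What the synthetic generator emulates — and what it does not

All tests run on generated fixtures; no camera, model download or network is
involved. The generator authors the six eye landmarks *first* — a hexagon of
width $W$ and lid opening $h$, so that $EAR = h/W$ exactly — and renders the
image from them: light sclera polygon on a skin-tone background, dark pupil
disc at the scripted $(g_x, g_y)$, lids closed to `open_fraction`
($EAR = 0.3 \times$ `open_fraction` by construction, with 0.3 the fully-open
ratio typical of real faces). Scripted clips emulate 25 fps capture: each
gesture is preceded by 10 neutral frames (return-to-center) and held for 20
frames — 800 ms, matching the deliberate-blink duration and comfortably
above both the 13-frame blink rule and the 10-frame debounce.

A green end-to-end test therefore establishes that the *geometry and
decision logic* are correct on clean renders with exact landmarks. It does
not establish robustness to real-world nuisance factors the generator omits:
head pose, illumination gradients, specular glints, eyelash occlusion,
landmark-predictor error (only uniform jitter is simulated via `noise_px`),
or compression artefacts. The pretrained face/landmark backends are
deliberately out of the test path; the frontend contract guarantees only
that whatever produces the 68 points — dlib upstream, a CSV stream, or the
generator — feeds an identical pipeline.

## Numerical choices and degenerate inputs

* Threshold boundaries: $EAR = t$ is CLOSED (inclusive, as printed in the
  open/closed rule), even though the surrounding prose says "decreased by
  less than 0.2"; the equation wins.
* The 13-frame window is implemented as a *maximal run length*, not a
  sliding window — the two readings coincide on noise-free traces and the
  run semantics compose cleanly with event extraction.
* A closed eye has a zero-area polygon: `build_eye_mask()` raises a
  degenerate-eye error, which the frame classifier maps to CLOSED via the
  EAR path before gaze is ever attempted.
* No dark contour of at least `min_contour_area` pixels means "no pupil":
  the frame classifies as UNKNOWN rather than guessing.
* Tied face detections resolve to the largest box, leftmost-topmost on
  ties; one patient per frame is assumed.
* Multiple faces, head pose and gaze calibration are out of scope.

## Scale of the test suite

The end-to-end acceptance property runs 200 seeded random scripts of one
phrase (three gestures, ~90 frames) each, rendered at 160×128 px — about two
minutes on one CPU. Longer multi-phrase scripts exercise the same code path
(the tracking list clears after every triple) and are covered by dedicated
smaller tests, so the 200-script sweep keeps one phrase per script to stay
within its time budget.
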
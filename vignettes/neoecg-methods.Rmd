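---
title: "Methods: wavelet-based neonatal ECG monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet-based neonatal ECG monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoecg)
```

`neoecg` implements a monitoring chain for single-lead preterm-infant
ECG in which one operator — the undecimated (stationary) wavelet
transform — supports every processing step: drift removal, denoising,
feature conditioning for beat detection, and compression. This
vignette explains the model behind each step, the parameters that
matter, the numerical conventions, and what the synthetic-data tests
do and do not establish about clinical recordings.

## The stationary wavelet transform

The SWT ("algorithme à trous") convolves the signal with an iterated
low-pass/high-pass pair derived from the Daubechies-8 scaling filter.
At level $j$ the filters are dilated by inserting $2^{j-1}-1$ zeros
between taps, so every coefficient array keeps the full signal length:
no decimation, hence translation invariance — a property beat-aligned
processing needs, because a transform that changes when the signal
shifts by one sample would make detected features depend on where a
block boundary happens to fall.

Conventions, chosen here because the transform admits several:

- **Analysis** is circular correlation with the orthonormal filters
  ($\sum h = \sqrt 2$); **synthesis** convolves with the same filters
  and halves, which averages the two redundant polyphase branches.
  Because the Daubechies pair is power complementary
  ($|H(\omega)|^2+|G(\omega)|^2 = 2$), reconstruction is exact to
  machine precision — the test suite bounds the round-trip error by
  $10^{-8}\max|x|$ and observes $\sim10^{-15}$.
- **Boundary handling** is periodic by default. Circular convolution
  makes shift invariance exact and testable, at the price of
  wrap-around artifacts when a block's ends disagree; on 1000-sample
  blocks (4 s at 250 Hz) the artifact is confined to the filter
  support and did not disturb detection in any test. A `symmetric`
  mode reflects the signal to twice its length before the periodic
  transform, trading memory for milder block-edge behaviour. In that
  mode the coefficient arrays keep the extension length $2n$
  (`n_ext`): Daubechies filters are asymmetric, so truncating the
  reflected half would destroy exact invertibility, and we prioritized
  the reconstruction guarantee over array-length uniformity.
- **Band labels.** Detail level $i$ is labelled with the ideal dyadic
  band $[f_s/2^{i+1}, f_s/2^i]$ and the approximation with
  $[0, f_s/2^{k+1}]$. Real filters overlap; the labels locate energy,
  they do not guarantee confinement. At $f_s = 500$ Hz and $k = 5$ the
  d5 band is 7.8125–15.625 Hz — the region where neonatal ECG energy
  concentrates, which is why five levels is the working depth
  throughout.

## Baseline drift removal

The drift estimate is the reconstruction from the level-5
approximation with all details zeroed; the corrected signal is the
input minus that estimate, so correction conserves the signal exactly.
At 250 Hz the approximation band is 0–3.9 Hz nominal; the effective
drift attenuation below 0.5 Hz exceeds 90% in the tests while R-peak
amplitudes move by less than 10%. The operator is not a projection
(the redundant analysis followed by the averaging inverse is not
idempotent on the masked subspace), but a second application changes
the corrected signal by well under 1% RMS under typical wander
(0.2 mV at 0.3 Hz), which is the sense in which "remove the baseline
once" is meaningful.

## Adaptive denoising

Each detail level is soft-thresholded,
$\operatorname{sign}(x)\max(|x|-T_i, 0)$, with
$T_i = \sqrt{\sum(cD_i - \overline{cD_i})^2/(n-1)}$ — the sample
standard deviation of that level's own coefficients. The threshold
therefore carries amplitude units and personalizes itself to each
recording; no population constant enters. The mean is taken per level:
detail means are near zero, but subtracting them keeps the estimator a
genuine dispersion if a level picks up residual offset.

Properties that follow and are tested: scale covariance
($\text{denoise}(\alpha x) = \alpha\,\text{denoise}(x)$), energy
contraction, and determinism.

When the threshold is estimated from data in which genuine QRS energy
dominates the noise, shrinkage costs signal: on a noise-free sparse
beat train the dispersion *is* QRS energy, and denoising then reduces
fidelity rather than improving it. Measured on the synthetic records,
shrinkage-only processing of white-noise corruption is beneficial up to
roughly 5–6 dB input SNR and harmful beyond; the full chain (drift
removal plus shrinkage) on realistically corrupted records — wander,
mains pickup and white noise together — improves SNR by about 7.5–8.5
dB across the 0–10 dB range, with drift removal contributing the bulk.
This is the regime the method is designed for; it is not a denoiser
for already-clean signals.

SNR improvement is defined against a known clean reference (output SNR
minus input SNR); that definition only exists for synthetic data. For
clinical recordings `snr_estimate_hf()` offers a labelled *estimate*
(reduction of power above 40 Hz) and the pipeline never reports it as
a true SNR.

## Personalized R-peak detection

The detector implements the personalized amplitude rule: after a 2 s
warm-up (long enough to contain at least one beat at neonatal rates),
the reference peak is the maximum amplitude observed; candidate local
maxima below 70% of the reference are rejected. Design points the rule
itself leaves open, resolved as follows:

- **Reference tracking.** Per 1000-sample block the reference is the
  block maximum, carried across blocks with a 0.99 decay so it follows
  amplitude drift in both directions instead of ratcheting upward.
- **Refractory period** 0.2 s: neonatal rates reach 200 bpm (RR
  0.3 s), so 0.2 s suppresses T-wave double-detection without ever
  vetoing a genuine beat.
- **Local maximum** means strictly greater than the left neighbour and
  at least the right; plateau ties resolve to the leftmost sample.
- **Polarity** is assumed positive; an `invert` flag serves inverted
  leads.
- Flat or silent signal yields an empty peak train, not an error — a
  monitor must idle gracefully.

## Rhythm rules and HRV

RR intervals derive from consecutive peak times. The decision rules:
an interval strictly above 0.6 s (rate below 100 bpm) signals
bradycardia, one alarm per maximal run of long intervals with every
triggering value stored; at least two consecutive intervals strictly
below 0.43 s (rate above 140 bpm) signal tachycardia. The 0.43 s bound
is $60/140$ rounded to two decimals; the two-beat requirement reflects
the clinical convention that a single short interval is not
tachycardia. For bradycardia the single-interval rule is the default
(alarm on any pause), with `brady_min_beats = 2` available for the
stricter at-least-two-beats clinical definition. The relative RR
$2(RR_k - RR_{k-1})/(RR_k + RR_{k-1})$ is algebraically confined to
$(-2, 2)$; magnitudes above 0.20 are flagged irregular.

RMSSD, SDNN and SDANN are the standard formulas reported in ms. SDANN
windows default to 5 s: classical SDANN uses 5-minute windows on Holter
recordings, but block-wise neonatal monitoring wants rhythm-change
indicators within seconds, so short windows (2 s or 5 s) are the
intended use here and the window is a parameter.

## Block streaming

The pipeline re-buffers any input chunking into 1000-sample blocks
(4 s at 250 Hz, 2 s at 500 Hz): one block is processed while the next
is stored. Detector state (global sample offset, reference amplitude,
last accepted peak, the trailing two samples for boundary maxima) and
rhythm state (open alarm runs) carry across blocks, so streamed output
is bit-identical to whole-record processing — asserted over randomized
records and chunk sizes. A final short block is processed with as many
levels as its length allows and the reduction is logged. Per-block
processing takes a few milliseconds on one CPU, far inside the
real-time budget of a block duration.

## Compression

Thresholding zeroes most detail coefficients; compression encodes the
survivors. Per level: a uniform min–max quantizer (mid-rise, cell
centres on dequantization, so retained coefficients are reproduced
within half a step) at 8 bits by default, and a position encoding that
per level picks the cheaper of a 1-bit-per-coefficient bitmap or an
index list. The approximation is bandlimited to $f_s/2^{k+1}$, so it
is stored decimated by $2^k$ and rebuilt by periodic cubic-spline
interpolation through the dequantized knots; the measured PRD cost of
that decimation is under 2% and the dense alternative
(`approx_decimation = 1`) remains available.

The compression ratio is input bits (samples × ADC resolution, default
16) over output bits. Two accountings are reported because published
ECG compression ratios rarely state what they count: `cr` includes
every header, flag and position bit; `cr_payload` counts coefficient
codes only. On synthetic 60 s records the defaults give `cr` slightly
above 1 and `cr_payload` around 1.7–1.8; both rise as the signal gets
smoother or the thresholds larger (CR is provably monotone in the
zeroed fraction under this accounting, and the tests check it).
Distortion is measured as PRD against the thresholded reconstruction —
the codec's own loss is quantization plus the small interpolation
term; the zero-rejection loss belongs to the denoising step, whose
output the codec reproduces to within a few percent PRD. Entropy
coding is deliberately out of scope.

## The synthetic generator

`generate_ecg()` emulates what matters to this chain: QRS complexes as
Gaussian second-derivative pulses (width 40 ms, amplitude 1 mV) on a
beat grid from a piecewise-constant rate profile (default 150 bpm),
injectable bradycardia episodes realized verbatim in the ground-truth
RR sequence, sinusoidal baseline wander below 1 Hz, white Gaussian
noise, and 50/60 Hz mains pickup — all from a single seeded stream, so
records are bit-reproducible. It does **not** model P/T-wave
morphology variation, ectopy, electrode pop artifacts, respiration
coupling, or amplitude modulation of beats. Consequently the test
results establish correctness of the algorithms under controlled
conditions (exact alarm bookkeeping, detection tolerance of ±2 samples
on clean records, graceful degradation to 10 dB SNR); they do not
certify clinical sensitivity figures, which depend on morphology and
artifact statistics the generator does not reproduce. The WFDB reader
and `evaluate` CLI exist precisely so the chain can be run against
annotated clinical records when they are available.

## Problem sizes and numerical tolerances

The shipped tests use records of 8–600 s at 250 Hz (five simulated
10-minute records for the detection summary), 20 seeds for the SNR
sweep, 100 randomized records for streaming equivalence, and
1000-sample blocks for compression — sizes chosen to exercise every
state-carrying path several times over while keeping the suite quick.
Exact identities (reconstruction, conservation, HRV formulas) are
asserted at $10^{-8}$–$10^{-12}$; statistical properties
(Monte-Carlo threshold consistency) at 2%; detection and alarm claims
are exact counts. Degenerate inputs are contracts, not accidents:
zero-energy signals refuse energy shares, sub-2-sample levels refuse
thresholds, fewer than two peaks yield empty RR series, and
insufficient HRV data reports `NA`, never a silent zero.

## Known limitations

- The amplitude-threshold detector assumes a dominant R wave; severe
  QRS morphology change or lead inversion (without the `invert` flag)
  defeats it.
- Thresholds estimated on nearly-clean signals over-shrink; see the
  denoising section.
- Periodic boundaries can, in principle, create block-edge maxima;
  the 70% rule rejected all such artifacts in testing, but pathological
  block-boundary steps remain conceivable.
- WFDB support covers single-segment format-16 records (the format of
  the public neonatal database) and MIT-format annotations; other
  formats raise clear errors rather than guessing.
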
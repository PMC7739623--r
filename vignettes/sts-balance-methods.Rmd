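---
title: "Static and dynamic balance analysis of sit-to-stand transfers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Static and dynamic balance analysis of sit-to-stand transfers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stsbalance)
```

## The problem

Rising from a chair is one of the most mechanically demanding everyday
movements, and the moment of seat-off -- when the body leaves the seat --
is its most precarious instant. Conventional sit-to-stand (STS) measures
(durations, repetition counts) describe *performance* but not *balance*:
whether the mover's mechanical state is compatible with coming safely to
rest upright. `stsbalance` implements a complete balance analysis of STS
recordings: whole-body kinematic aggregation, a functional base-of-support
(BOS) model of the shod foot, four static balance metrics with
still-standing reference bounds, the 3D foot placement estimator (FPE) as
a model-based dynamic balance metric, automatic movement segmentation, and
non-parametric group statistics at seat-off. A synthetic-cohort generator
with complete analytic ground truth drives the test suite.

## Whole-body state

Each body segment $i$ contributes mass $m_i$, COM position $r_i$ and
velocity $v_i$, a world-frame inertia tensor $J_i$ about its own COM, and
an angular velocity $\omega_i$. The whole-body COM is the mass-weighted
mean; the inertia about the COM adds the parallel-axis terms

$$J_C = \sum_i J_i + m_i\!\left((\rho_i^{\top}\rho_i)\,I - \rho_i\rho_i^{\top}\right),
\qquad \rho_i = r_i - r_C,$$

and the angular momentum about the COM is

$$H_C = \sum_i J_i\,\omega_i + \rho_i \times (m_i\,\dot\rho_i).$$

The *average angular velocity* is the single-rigid-body equivalent
rotation rate, the solution of the linear system
$J_C\,\omega_{avg} = H_C$. It averages the segments' angular momentum
contributions in the same way the COM velocity averages their linear
velocities. Samples with a numerically singular $J_C$ (reciprocal
condition number below $10^{-12}$) are flagged and propagate as missing
values rather than crashing the pipeline.

### Marker model

The package reconstructs segment states from a deliberately compact
planar link marker set: the six IOR-style foot markers per foot (FAL, TAM
at the malleoli; FM1, FM2, FM5 at the metatarsals; FCC at the heel) plus
mid-line joint markers KJC (knee), HJC (hip) and C7. Shank, thigh and a
combined head-arms-trunk (HAT) segment run between consecutive joints;
segment orientation is the sagittal-plane angle of the joint-to-joint
axis, and segment angular velocity its unwrapped finite-difference rate.
Segment masses, COM ratios and radii of gyration come from the classical
cadaver-based anthropometric regression tables (Dempster/Winter lineage),
packaged in `default_body_params()`. This planar model cannot represent
axial rotation of individual limbs; it is sufficient for the sagittal
task analyzed here, and the generator that exercises the pipeline is
built on exactly the same conventions.

### Signal conditioning

Markers and forces are low-pass filtered with a 4th-order Butterworth
filter at 10 Hz applied forward and backward (`signal::filtfilt`), which
doubles the effective order and cancels phase lag. The filter order is a
package decision (configurable); the cut-off follows standard practice
for movement data. Velocities and angular rates are central differences
on the filtered 150 Hz signals, with one-sided differences at the ends.
Force channels (900 Hz) are decimated 6:1 to the marker clock after
filtering; the *unfiltered* seat force is additionally kept, decimated by
block averaging, because the seat-off event is a contact break -- a kink
that zero-phase filtering would smear across several samples. Marker gaps
are linearly interpolated up to a configurable span (default 0.1 s);
longer gaps reject the trial.

## The functional base of support

The functional BOS is the convex region in which a person can place at
least half their body weight without rolling the foot. It is measured
once, from dedicated COP-excursion recordings, and stored as a
*normalized template*: per-foot COP samples are kept only where the foot
is flat (edge drop $w\,|\sin\psi_X| \le 1.5$ cm and
$\ell\,|\sin\theta_Y| \le 1.5$ cm in the X-Y'-Z'' Euler decomposition of
the foot rotation relative to its calibrated flat pose -- the 1.5 cm
allowance reflects foot-pad plus shoe-sole compression) and the normal
force exceeds half body weight. Each foot's convex hull is normalized by
its width $w$ (ankle-pair plus metatarsal-pair half-sums along the foot
frame's x axis) and length $\ell$ ($\hat y\cdot(r_{FM2}-r_{FCC})$);
right-foot hulls are reflected into left-foot space. Profiles are
averaged by sampling each hull's boundary radius along a common fan of
rays from the template center $(-0.15, 0.3)$ (360 rays by default --
sub-millimetre radius resolution at foot scale) and taking the mean
radius per ray. The ray-average of convex polygons need not be convex,
so the result is convexified by a final hull.

At analysis time the template is scaled by each foot's measured $w$ and
$\ell$ and placed in the world ground plane through the foot frame
calibrated during quiet stance (origin dropped to the ground, vertical
z). The whole-body BOS is the convex hull of both foot polygons, and
signed distances to it are positive inside, negative outside. The
packaged default template (`inst/extdata/bos_template_synthetic.json`)
is built from the package's own synthetic excursion generator and is
labelled synthetic; laboratory users should build their own with
`build_template()`.

## Static balance

A body is statically balanced when it has not fallen and its linear and
angular speeds are "small", where small is operationalized as the range
observed during quiet standing. Four per-sample metrics quantify the
distance from that state:

* `d_bg` -- signed distance from the COM ground projection to the BOS
  boundary (positive inside);
* `com_cop_dist` -- horizontal distance between COM ground projection and
  COP (imperfect segment models keep this above zero even in still
  stance, hence a measured bound rather than zero);
* `com_speed` -- $\|v_C\|_2$;
* `avg_ang_speed` -- $\|\omega_{avg}\|_2$.

`still_standing_bounds()` takes each subject's min/max over a 10 s quiet
window, averages the extremes across subjects, and symmetrizes signed
metrics (such as the vertical average angular velocity) about zero using
the larger bound. A sample classifies as statically balanced when
`d_bg >= 0` and the other three metrics sit inside their bounds; the
margin-sign condition expresses "the COM ground projection is within the
BOS" directly rather than treating `d_bg` as a bounded signed metric.

## Dynamic balance: the foot placement estimator

The FPE asks: where must the COP be placed so that the body --
abstracted as a single rigid body with the momentum the multibody system
actually carries -- passively rotates up into a balanced standing pose?

The body state is projected onto a vertical *travel plane*: the turning
axis $\hat t$ is the normalized horizontal component of the angular
momentum about the COM ground projection, $H_G$, and the straight-step
axis is $\hat s = \hat t \times \hat z$, so forward travel gives positive
forward velocity. When horizontal $H_G$ is negligible the previous
frame is reused, then the horizontal COM velocity heading; with neither,
the sample is flagged. The projected state is
$(m, h, v_{s,1}, v_{z,1}, \omega_1, J)$ with
$J = \hat t^{\top} J_C\, \hat t$.

Conserving angular momentum at a point contact on a leg of length
$\ell = h/\cos\varphi$ and then requiring the post-contact kinetic
energy to exactly match the potential energy gained as the COM rises
over the contact yields a scalar residual

$$f(\varphi) = \frac{\left(m h (v_{s,1}c + v_{z,1}s)\,c + J\omega_1 c^2\right)^2}
{m h^2 + J c^2} + 2 m g h\, c\,(c-1), \qquad c=\cos\varphi,\; s=\sin\varphi,$$

whose root locates the FPE at $r_F = r_G + (h\tan\varphi)\,\hat s$.

Numerical choices, all of which were genuinely open:

* **Bracketing and polishing.** $f$ is scanned on a 256-point grid over
  $(0, \pi/2)$; each sign change is bisected close to the root and
  polished by Newton steps with the analytic derivative, any step leaving
  the bracket reverting to bisection. Convergence requires
  $|f| < 10^{-10}\, m g h$.
* **Root physicality.** The residual squares the contact momentum, so it
  also vanishes at angles where the model would rotate *away* from
  upright (and trivially at the degenerate $\varphi = \pi/2$ geometry).
  Only roots whose momentum numerator is non-negative -- forward
  post-contact rotation -- are FPE solutions. When no such root exists
  ahead of the COM (strongly spin-dominated states) the mirrored plane
  is solved and $\varphi < 0$ (a step behind) is returned; backward
  travel is handled the same way.
* **Applicability.** The 3D projection is information-preserving only
  when $\omega_{avg}\cdot\hat z$ is negligible;
  `applicability_check()` flags samples whose vertical average angular
  velocity exceeds the still-standing bound. Flagged samples are
  cautioned, not suppressed.

`post_contact_outcome()` classifies a hypothetical contact at any offset
by momentum conservation followed by the energy criterion: stepping on
the FPE balances (arrival speed below $10^{-4}$ rad/s), short of it the
surplus energy carries the model over (falls forward), beyond it the
model cannot reach the top and reverses (falls backward). Contacts
behind the COM are handled symmetrically (balance there requires
backward rotation).

The per-sample dynamic metrics are the vertical average angular velocity
`wz`, the dynamic balance margin `d_bf` (signed distance from the FPE
point to the BOS boundary), and the COP-to-FPE displacements along
$\hat t$ (turning control) and $\hat s$ (propulsion control).

Because the equivalent single-body state is re-evaluated at every
sample, the method's constancy assumptions ($J$, $\ell$, mechanical
energy) hold only instantaneously; this introduces small angle errors
that are accepted as modeling error, consistent with re-evaluation being
the method's standard usage.

## Movement segmentation

Segmentation is two-stage. First, the COM height and the seat-plate
vertical force are each clustered into three phases with k-means++
seeding (10 restarts, best within-cluster sum of squares, deterministic
given the seed). Height clusters order into seated / crouch / standing by
their means; force clusters into seated / transition / standing.
Candidate repetitions are standing-height runs of at least 0.5 s
connected backwards in time to a seated-force run of at least 0.5 s with
exactly one transition-force-to-standing-force switch in between
("connected backwards" is operationalized as: walking back through the
force runs from the standing-height run, the nearest seated-force run is
taken and the switch count is evaluated on the runs in between).
Candidates during which either foot breaks contact -- fewer than 3 of
its 6 markers staying within 15 mm vertical excursion -- are rejected,
as are aborted rises that return to the seated-force cluster without a
standing-height run (sit-backs).

Second, event times are refined by adaptive thresholds: initiation is
the last instant before seat-off at which the COM speed was within
1 cm/s of the minimum observed in the seated-force run (the *last*
crossing makes the detection robust to quiet-sitting noise); seat-off is
the first instant the raw decimated seat force comes within 1 N of the
value it registers during the standing-height cluster (its median);
stance is the first instant after seat-off with the COM within 1 cm of
the median standing height and upward speed below 1 cm/s. The seat-off
test deliberately runs on the raw force: the contact break is a kink
whose position the zero-phase filter would shift by several samples.
Candidates whose thresholds are never crossed are rejected with a
specific reason (`no_initiation`, `no_seatoff`, `no_stance`).

## Group statistics

The eight balance metrics are read at the seat-off sample, joined by the
total STS duration and the seat-off-to-stance duration. Values are
averaged over repetitions per participant for performance contrasts; the
range over repetitions per participant serves as the within-subject
variability measure, fed through the same machinery. Group contrasts use
the Wilcoxon rank-sum test (unpaired) and the signed-rank test (paired
condition contrasts), two-sided, with no multiple-testing correction.
For small samples the permutation distribution of the midrank statistic
is enumerated exactly (all $\binom{m+n}{m}$ assignments, or all $2^n$
sign patterns), which handles ties exactly; tie-free larger samples use
the exact Wilcoxon distribution, and beyond that the normal
approximation with continuity correction. Summaries are medians with
25-75% interquartile ranges (linear-interpolation quantiles, type 7).

## The synthetic cohort generator

The generator is first-class, tested code, and defines the study
conditions for every end-to-end check. One STS repetition drives a
planar three-link chain (shank, thigh, HAT) plus two static feet:

* about 2 s of quiet sitting, a rise of duration $T$, and 2.5 s of
  quiet standing;
* thigh and shank angles follow a quintic smoothstep (zero velocity and
  acceleration at both ends); the trunk lean follows a bump peaking at
  seat-off (maximum trunk flexion at seat-off), maximum ~0.8 rad;
* seat-off is designed at 45% of the rise; the seat force falls from
  70% of body weight along a smooth-onset ramp $u^2(2-u)$ that reaches
  zero *with finite slope* at the designed instant -- a contact break is
  not smooth, and a zero-slope profile would make the 1 N threshold
  cross tens of milliseconds early;
* the foot-plate COP blends from a seated point under the mid-foot to a
  point tracking the COM ground projection (the generator is a kinematic
  emulation; plate wrenches are quasi-static by design);
* marker noise (0.3 mm SD) and force noise (0.5 N SD) -- typical
  optical-capture and force-plate noise floors -- are added last.

Because the trajectories are analytic, events, COM series and the full
segment states at seat-off are known exactly. Trial variants emulate a
sit-back failure (a 45%-progress excursion that returns to the seat,
followed by a clean rise), a rise during which one foot lifts 20 mm, and
a brief-stand cycle. Quiet-standing trials rotate the standing chain
rigidly about the ankles with band-limited sum-of-sinusoid sway
(analytic derivatives; default COM sway SD 4 mm). COP-excursion trials
cover a known rectangular region of each foot's frame with 80% of body
weight, interleaved with tilted-foot and low-force episodes that the
template builder must reject.

Older-group offsets are injected through the motion plan: a `d_bg`/`d_bf`
offset moves the stance geometry (the seated posture relative to the
feet), which shifts both BOS-relative margins together -- for a
feet-fixed task they are physically inseparable -- and a `com_speed`
offset dilates the rise time. Offset recovery is therefore assessed by
sign and significance, not by magnitude. Defaults (COM_GP 3 cm deeper in
the BOS, COM speed 8 cm/s slower, margin 2 cm larger for the older
group; 10 young and 8 older subjects, 5 repetitions) produce seat-off
values in the ranges reported for healthy younger and older adults.

### What the generator does not emulate

Soft-tissue artifact, marker occlusion and gap structure, genuinely 3D
(frontal/transverse) motion, arm swing, closed-loop postural control,
and contact dynamics of failures (the sit-back is kinematic). Passing
tests on this cohort therefore demonstrate the correctness of the
computational chain under controlled conditions, not robustness to every
pathology of real recordings.

### Numerical consistency between generator and pipeline

Positions reconstructed from noiseless markers agree with the analytic
ground truth to better than $10^{-9}$ m. Velocity-derived quantities are
limited by the pipeline's own discretization (zero-phase filtering plus
central differences at 150 Hz), giving agreement at the $10^{-4}$ m/s
scale -- this is a property of any sampled pipeline, not a defect, and
the tests assert it at discretization-limited tolerances.

## Problem sizes used by the test suite

The packaged checks run a full cohort of 10 + 8 subjects with 5
repetitions (90 trials) for segmentation and effect-direction recovery,
20 no-offset control cohorts of 8 + 8 subjects with 2 repetitions for the
false-positive control, 1000 random solver inputs against $10^6$-point
residual scans, and 1000 random point/polygon distance pairs. These
sizes keep the full suite within a few minutes on a single CPU while
leaving the statistical conclusions comfortably powered.

## Known limitations

* The planar marker model ignores out-of-plane segment rotation; `wz`
  on real data will reflect marker noise as well as true yaw.
* The functional BOS template ships as a synthetic stand-in; per-lab
  calibration is strongly recommended.
* The exact enumeration tests are quadratic-to-exponential in sample
  size and hand over to approximations beyond the documented limits.
* C3D input is not supported; recordings enter through the documented
  TSV dialect (`write_trial_tsv()` / `read_trial_tsv()`).
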
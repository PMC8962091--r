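# tcpcflow

Blood-flow energetics of the Fontan total cavopulmonary connection (TCPC)
from 4D phase-contrast (4D flow) CMR velocity fields.

In a Fontan circulation both caval veins are connected directly to the
pulmonary arteries, so the systemic venous return crosses the TCPC without
a pumping ventricle behind it. Energy dissipated by friction in that
junction must be paid for with higher central venous pressure and reduced
preload — mechanisms implicated in Fontan-associated liver disease and
reduced exercise capacity. `tcpcflow` quantifies that inefficiency from
measured velocity fields, for imaging scientists and cardiovascular
researchers who want the whole chain — preprocessing, segmentation,
segmental geometry, energetics, cohort statistics — in tested, scriptable
form.

## What it computes

For a velocity field **v**(x, t) on a voxel grid (24 cardiac phases
typical) restricted to a TCPC lumen mask:

- **Kinetic energy**: KE(t) = Σ_voxels ½ ρ |v|² V_voxel, reported in mJ;
- **Viscous energy loss rate** from the Navier–Stokes dissipation
  function under the laminar assumption, reported in mW:

  EL(t) = Σ_voxels μ Φ_v V_voxel,
  Φ_v = ½ Σ_ij (∂v_i/∂x_j + ∂v_j/∂x_i)² − ⅔ (∇·v)²,

  with velocity gradients from mask-aware finite differences (central in
  the interior, second-order one-sided at the wall);
- cycle averages and **normalization** for inflow (mJ or mW per L/min) and,
  for branch segments, additionally for length (per cm);
- **segmental analysis**: centerline extraction, division into five
  segments (Fontan tunnel, SVC, LPA, RPA, central confluence; segments
  shorter than 1.5 cm excluded), through-plane flows, and cross-sectional
  areas perpendicular to the centerline at 1 mm intervals, normalized to
  BSA (Haycock);
- preprocessing: VENC anti-aliasing by region-growing unwrapping, and
  semi-automatic lumen segmentation on magnitude-weighted, time-averaged
  speed images;
- **synthetic data**: pulsatile laminar phantoms (tubes, tilted tubes, a
  four-branch TCPC junction) with exact closed-form KE/EL ground truth,
  and a synthetic patient cohort drawn from the published means, SDs and
  pairwise correlations;
- the **statistics layer**: Shapiro–Wilk-driven descriptives,
  Pearson/Spearman correlations with strength labels (weak 0.3–0.5,
  moderate 0.5–0.7, strong 0.7–0.9, excellent > 0.9), Kruskal–Wallis
  segment comparisons with Bonferroni-adjusted pairwise Mann–Whitney
  tests.

## Worked example

A pulsatile TCPC junction phantom (24 phases, 1.5 mm grid, mild noise),
run through the full pipeline:

```r
library(tcpcflow)
res <- run_pipeline(list(phantom = list(geometry = "tcpc_junction",
                                        spacing_mm = 1.5, n_phases = 24,
                                        noise_sd = 0.01, seed = 5)))
res$total$normalized
res$per_segment
```

prints (abridged):

```
anti-aliasing: 64 voxel values corrected
mask: 7557 voxels
inflow (tunnel + svc): 3.48 L/min
total TCPC: KE 0.7987 mJ, EL 0.6564 mW;
  KE_norm_flow 0.2294 mJ per L/min, EL_norm_flow 0.1885 mW per L/min

    segment  length_cm flow_l_min mean_csa_cm2  ke_norm el_norm
     tunnel       3.75       2.44         2.35  0.02917  0.0134
        svc       3.15       1.04         1.42  0.02037  0.0190
        lpa       3.30       1.57         1.03  0.04036  0.0472
        rpa       3.15       1.94         1.59  0.03733  0.0309
 confluence         NA       3.48           NA  0.00789  0.0132
```

Reading it: 3.48 L/min of venous return crosses the junction; the whole
connection stores 0.80 mJ of kinetic energy and converts 0.66 mW to heat,
i.e. 0.23 mJ and 0.19 mW per L/min of inflow. Branch rows are normalized
per L/min per cm of segment; the confluence is normalized for flow only
and is not directly comparable to the branches. The narrow LPA carries the
least flow yet dissipates the most per unit flow and length — exactly the
kind of segment the method is designed to flag.

The numbered drivers under `analysis/` run the full study workflow and
write their tables under `results/`:

- `01_phantom_validation.R` — energetics engine vs Hagen–Poiseuille closed
  forms across grid resolutions; exact-field checks; VENC unwrap
  restoration;
- `02_segmental_analysis.R` — the pipeline above plus a conduit-radius
  sweep (16–18 mm conduits vs undersized) showing normalized dissipation
  rising steeply as the tunnel narrows;
- `03_cohort_statistics.R` — descriptives, energetics–outcome correlations
  at the usable-TCPC subset size (n = 28), and segment comparisons on a
  synthetic cohort.

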
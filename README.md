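# eitroi

Local region-of-interest (ROI) imaging for 2-D electrical impedance
tomography (EIT) with an internal electrode.

## The problem

EIT reconstructs the conductivity change inside a body from currents
injected and voltages measured on surface electrodes. The measurements are
very sensitive near the electrodes and to the boundary shape, and
insensitive to changes deep inside — which is exactly where clinical targets
such as a liver tumour under radiofrequency ablation (RFA), or the heart in
cardiac monitoring, sit. An additional *internal* electrode (e.g. on the RFA
probe itself) adds interior current paths and raises the sensitivity near
the target, but a conventional whole-domain reconstruction still lets
conductivity changes elsewhere (lungs, gastric organs, large vessels)
corrupt the local image.

`eitroi` implements a local-ROI imaging method for this setting: it builds a
spatial filter from the sensitivity matrix itself that suppresses the
influence of pixels outside a small disk of interest around the internal
electrode, then reconstructs only that disk.

## The method

For a disk domain with `E` surface electrodes (and optionally one internal
electrode), the package solves the conductivity equation
`div(sigma grad u) = 0` with gap-model Neumann data by P1 finite elements,
and linearizes time-difference data about a reference conductivity:

```
S dgamma = dV,     S[m, n] = -Int_{q_n} grad(u^j) . grad(u^k) dr
```

where `m` indexes a drive/measurement pair and `q_n` a reconstruction pixel.
Splitting the pixels into the ROI disk `D` (first `R` columns, `S_D`) and
the rest (`S_out`), the filter column for ROI pixel `k` minimizes

```
phi_k = argmin_phi  sum_{j outside D} (s_j . phi)^2  +  alpha ||phi - s_k||^2
```

i.e. it stays close to the pixel's own sensitivity column while becoming as
orthogonal as possible to all outside columns; `alpha > 0` balances the two.
The minimizer is computed exactly from the normal equations
`(S_out S_out' + alpha I) phi_k = alpha s_k`, one Cholesky factorization for
all `R` columns. Stacking the columns into `Phi`, the localized system

```
(Phi' S_D) dgamma_D = Phi' dV
```

is solved by truncated SVD (TSVD), giving an image supported on the ROI
only. Diagnostics quantify what the filter achieves: the cross-correlation
`mu` between ROI and outside sensitivity columns, spectral-norm ratios
`||A_in||/||A||` and `||A_out||/||A||`, the leakage of out-of-ROI signal
through the filter, the number of singular values needed to reach a target
image contrast, and localization errors against known anomaly positions.

All of this runs on simulated disk phantoms from a built-in registry
(`list_scenarios()`), including a single-anomaly phantom in three electrode
configurations (Model 0: surface electrodes only; Model 1: plus an internal
electrode; Model 2: plus ROI-clustered surface electrodes), a four-anomaly
simulation, and radish/potato-style contrast cases with an anomaly outside
the ROI. No external data are required; users can also supply their own
voltage vectors and sensitivity matrices through the documented CSV
formats.

## Worked example

```r
library(eitroi)

s        <- scenario("model2_single")        # unit disk, anomaly at (0.8, 0)
layout   <- scenario_layout(s)
mesh     <- build_mesh(layout, 0.05)
roi      <- compute_roi(layout)              # 5/6 rule around the internal electrode
grid     <- build_pixel_grid(disk_domain(1), 32, roi)
protocol <- scenario_protocol(s, layout)

sigma_ref <- conductivity_field(mesh, s$background, reference = TRUE)
dv   <- difference_data(mesh, sigma_ref, scenario_sigma(mesh, s), protocol)
sens <- compute_sensitivity(mesh, sigma_ref, protocol, grid)
filt <- build_filter(sens)

round(norm_ratio(sens), 3)
round(norm_ratio(apply_filter(filt, sens, dv)$A_full, filt$R), 3)
rec <- reconstruct_local(filt, sens, dv, 0.01)
find_local_maxima(rec, n_max = 1)
```

prints

```
<eit_layout> E = 16 (clustered), arc width 0.1309 rad, internal electrode at (0.5, 0), r = 0.0178571
<eit_roi> center (0.5, 0), radius 0.423736
<eit_sens> 512 x 812 (R = 148 ROI columns)
 in_ratio out_ratio
    0.275     0.998      # raw sensitivity: outside pixels dominate
 in_ratio out_ratio
    0.932     0.377      # after filtering: the ROI dominates
<eit_recon> local_roi: 812 pixels, rel threshold 0.01, rank 14
strongest peak at (0.781, -0.031); true anomaly center (0.8, 0)
```

The norm ratios show the effect of the filter: before filtering the
spectral norm of the system is carried almost entirely by pixels outside
the ROI (out-ratio 0.998); after multiplying by `Phi'` the in-ROI block
dominates (in-ratio 0.932). The local reconstruction then peaks within one
pixel of the true anomaly.

The same pipeline is scriptable end to end via `run_pipeline()` or the CLI
in `inst/cli/eitroi` (`eitroi scenario list`, `eitroi run --config
cfg.json`, ...), which writes meshes, data vectors, matrices, images and a
run manifest to an output directory.

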
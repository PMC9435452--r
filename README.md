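# mirrormorph

Mirror-based quantification of facial surface asymmetry from 3D
stereophotogrammetric meshes, for longitudinal monitoring of one-sided
facial tissue loss (progressive hemifacial atrophy / Parry-Romberg
syndrome and linear scleroderma en coup de sabre) in growing patients.

## The problem and the method

A growing child's face changes shape between clinic visits, so captures
taken months apart cannot be compared directly. The mirroring method
makes each capture its own control:

1. crop the capture to the region of interest (exclude neck, hairline);
2. estimate the **midsagittal plane** and reflect the mesh across it;
3. register the mirrored surface back onto the original — rough
   alignment by principal axes (or landmarks), then fine surface-based
   alignment with the **iterative closest point** (ICP) algorithm with
   outlier rejection, so the lesion itself does not drag the fit;
4. compute the per-vertex **signed distance map** between original and
   registered mirror (green = mirrored surface outside the original,
   i.e. the contralateral side carries more volume; red = volume loss);
5. summarise per visit as
   - *T*<sub>mean</sub> — mean absolute inter-surface distance (mm), with
     its standard deviation, and
   - *T*<sub>&le;c&nbsp;mm</sub> (%) — the percentage of surface points whose
     absolute distance is within cut-offs c = 1, 2, 5 mm (100 = the
     whole analysed surface lies within the band).

Falling percentages and a rising *T*<sub>mean</sub> across visits indicate
progressing asymmetry; because the comparison is within one capture,
normal craniofacial growth cancels by construction.

A synthetic-face module generates stereophotogrammetry-like capture
series (smooth open shell, ~10k-50k vertices, exactly symmetric at
baseline) with controlled lesion depth, global growth, 0.3 mm-scale
acquisition noise and pose jitter, so the full pipeline is testable with
known ground truth and no patient data.

## Worked example

```r
library(mirrormorph)

# simulate a progressing lesion over three visits (growth + noise + pose)
series <- simulate_series(
  face_params(n_vertices = 8000),
  series_params(timepoints = c(0, 12, 24),
                growth_scale  = c(1, 1.02, 1.04),
                atrophy_depth = c(0, 2, 4),
                noise_sigma = 0.3, seed = 42),
  atrophy_field(center = c(30, -12, 31), radius = 15))

reports <- lapply(series, function(visit)
  analyze_timepoint(visit$mesh, analysis_config(seed = 1),
                    timepoint_months = visit$timepoint_months)$report)

writeLines(format_longitudinal_table(build_longitudinal_table(reports)))
```

```
Follow-up (months)  T_mean (mm)  T<=1mm (%)  T<=2mm (%)  T<=5mm (%)
                 0          0.3          99         100         100
                12          0.4          93         100         100
                24          0.6          84          94         100
```

At baseline the simulated face is symmetric up to 0.3 mm capture noise:
*T*<sub>mean</sub> sits at the noise floor (0.3 mm) and 99% of the surface
is within 1 mm. As the simulated lesion deepens (2 mm, then 4 mm on one
cheek), *T*<sub>mean</sub> rises and the 1 mm band loses 15 percentage
points — the signature of progressing asymmetry — while growth and pose
changes between visits leave no trace. Per-visit detail, the colour-mapped
mesh (writable as PLY via `write_mesh`) and the registration diagnostics
come from the same `analyze_timepoint()` call.

Disk-based runs use `cmd_simulate()` / `cmd_analyze()` / `cmd_report()`
(YAML configs, JSON-lines run logs), or the thin shell wrapper in
`inst/cli/mirrormorph`.

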
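# File formats

## Recording CSV

One file per recording. `#`-prefixed header line(s) carry metadata, then a
two-column CSV body.

```
# fs_hz=400, subject_id=S0001
pressure_kpa,flow_lps
-0.012345,0.54321
...
```

| field | type | units | notes |
|---|---|---|---|
| `fs_hz` | number | Hz | required; 400 in the standard pipeline |
| `subject_id` | string | — | optional, defaults to `anon` |
| `pressure_kpa` | float | kPa | oral pressure |
| `flow_lps` | float | L/s | airflow, expiration positive |

Samples are written with 8 significant digits (float32-like fidelity).
Non-finite values, ragged rows and missing `fs_hz` are parse errors.

## Manifest CSV

One row per subject; `subject_id` must be unique (one eligible record per
subject).

| column | type | units |
|---|---|---|
| `subject_id` | string | — |
| `age_years` | number > 0 | years |
| `sex` | `M`/`F` or `1`/`0` (male = 1) | — |
| `height_cm` | number > 0 | cm |
| `weight_kg` | number > 0 | kg |
| `fef2575_ratio` | number > 0 | measured/predicted |
| `fef50_ratio` | number > 0 | measured/predicted |
| `fef75_ratio` | number > 0 | measured/predicted |
| `recording_path` | path | — |

## TFRIM cohort store (RDS)

Single-file R serialization of a list:

| field | shape | content |
|---|---|---|
| `tfrim` | `n x 2 x 24 x 48` | channel 1 resistance, channel 2 reactance, kPa/(L/s) |
| `freqs` | `n x 24` | retained frequencies per subject, Hz, ascending |
| `mean_coherence` | `n x 24` | time-mean screened coherence per retained channel |
| `times` | `48` | window centres, s |
| `subject_ids` | `n` | manifest order |
| `params` | list | `window_s`, `hop_s`, `subsegment_s`, `gamma_th`, `n_channels`, `f_min`, `highpass_hz`, `crop_samples` |

## Configuration YAML

Nested blocks `simulate`, `tfrim`, `network`, `labels`, `training`; any
subset may be given and is overlaid on `default_config()`.  Schema checks:
`gamma_th` in (0, 1], positive window/hop/sub-segment lengths, `vth > 0`,
`lam > 0`, `tau` in (0, 1), `lr > 0`, `folds >= 2`.

## Reports

`evaluate` writes `metrics.json` with `per_fold` (rows: task x fold) and
`average` tables; `train` writes `history_fold<k>.csv` with
`epoch,lr,train_loss,val_loss`, plus `run_manifest.yaml` (package version,
seed, config hash, timestamp).
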
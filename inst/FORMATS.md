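# File formats

All sample indices are 0-based; all intervals are half-open
`[start, end)`; all times are seconds.

## Signals (CSV)

`time_s,value` — one row per sample, uniform grid (readers reject
timestamp jitter above 0.1 sample periods and name the offending rows).
A single-column file is accepted when the sampling rate is supplied
explicitly.

## Annotations (CSV)

`kind,start_sample,end_sample,label` with `kind` one of:

- `jpeak` — one row per J-peak, start = end = sample index
- `trough` — one row per breath trough
- `frame` — one row per breath frame, label `normal` or `apnea`
- `apnea` — one row per injected event, label `post_inhalation` or
  `post_exhalation`

## Peaks (CSV)

`sample_index,time_s,amplitude,flag`, flag `accepted` or `recovered`.

## Features (CSV)

`frame_start,frame_end,avnn_s,sdnn_s,cv,ti_s,n_beats,similarity_pct,flagged`.
Undefined features (frames with fewer than two beats) are empty fields.

## Model (JSON)

`feature_names`, `weights` (scaled space, intercept last), `raw_weights`,
`scaler` (`center`, `scale`), `threshold`, `provenance`.

## Pipeline configuration (YAML)

Sections `sampling`, `wavelet`, `detector`, `feature`, `classifier`,
`output`; unknown sections or keys are rejected; missing keys take
package defaults (see `?pipeline_config`).
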
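# File formats

All text formats are UTF-8 with LF line endings. Times are seconds,
intervals half-open `[start, end)`, numeric values printed as the
shortest decimal that reparses to the identical double.

## Waveform text (`.txt`)

Written by `export_waveform()`, read by `read_waveform()`. Stimulator
ingestion format: header then one current sample (uA) per line.

```
# pacstim waveform v1
# waveform_kind: depacer
# sample_rate: 10000
# f_l: 1
# f_h: 100
# dither_spread: 10
# a0: 40
# pulse_width: 1
# duration: 2
# seed: 1
# envelope_mode: signed_sine
0
0
...
```

Every generation parameter and the seed are embedded, so the file is
self-reproducing. Export → import → export is byte-identical.

## Recording container (`.csv`, `.tsv`, `.feather`)

Written by `write_recording()`, read by `read_recording()`; the dialect
is chosen by extension.

Text dialects: `#`-prefixed header lines, then a delimited table with
one column per channel (uV), one row per sample.

```
# pacstim recording v1
# sample_rate: 250
# meta seed: 1
# meta kind: dose_response_session
# annotation: stim<TAB>60<TAB>90<TAB>40
hippocampus,thalamus
12.7,10.16
...
```

* `# meta <key>: <value>` — free-form metadata (seed, config echo).
* `# annotation: label<TAB>start<TAB>end<TAB>payload` — event table;
  `stim` annotations drive stimulation-epoch masks, `evoked` marks the
  evoking stimulus, `sle` seizure-like events. Annotation times
  round-trip at full precision.

`.feather` is the binary columnar dialect via arrow; the same
attributes (sample rate, annotations, metadata) ride along bit-exactly.

## Result tables

CLI subcommands emit plain CSV: `scalogram` writes long-format
`(time, freq, magnitude, phase, in_coi)` or `(time, freq, z)` when a
baseline is given; `comodulogram` writes
`(window_start, f_phase, f_amp, mi)`; `dose-response` writes
`(amplitude, delta_z, suppressed)`.
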
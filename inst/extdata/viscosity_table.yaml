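# Relative viscosities (eta_crowder / eta_buffer) by polymer and % w/v.
# Literature values; editable. The 20% PEG 8K entry is ~13-fold water.
viscosities:
  - polymer: buffer
    percent_wv: 0
    eta_rel: 1.0
  - polymer: PEG 8K
    percent_wv: 5
    eta_rel: 2.0
  - polymer: PEG 8K
    percent_wv: 10
    eta_rel: 4.0
  - polymer: PEG 8K
    percent_wv: 15
    eta_rel: 7.5
  - polymer: PEG 8K
    percent_wv: 20
    eta_rel: 13.0
  - polymer: PEG 600
    percent_wv: 30
    eta_rel: 5.0
  - polymer: EG
    percent_wv: 40
    eta_rel: 3.2
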
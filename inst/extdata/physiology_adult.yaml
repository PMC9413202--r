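# Reference adult physiology (70 kg), standard whole-body PBPK values.
# Volumes in L, flows in L/h. The liver flow is the hepatic-arterial
# flow; total hepatic inflow adds the gut and spleen (portal) flows.
# rest_of_body is derived by closure against cardiac_output and
# total_body_volume and may be omitted here.
body_weight: 70
cardiac_output: 390
total_body_volume: 70
volumes:
  adipose: 13.0
  bone: 7.9
  brain: 1.4
  gut: 1.2
  heart: 0.3
  kidney: 0.3
  liver: 1.7
  lung: 0.5
  muscle: 28.0
  skin: 2.6
  spleen: 0.18
  arterial: 1.8
  venous: 3.6
flows:
  adipose: 19.5
  bone: 19.5
  brain: 46.8
  gut: 58.5
  heart: 15.6
  kidney: 74.1
  liver: 25.35
  muscle: 66.3
  skin: 19.5
  spleen: 11.7
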
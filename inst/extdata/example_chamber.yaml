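# Example three-section stimulation chamber (synthetic interpretation).
#
# The published figure gives only relative branch resistances, so this file
# encodes one concrete reading: three identical stimulation sections
# (10 mm x 7.7128 mm x 0.8 mm, sigma = 1.5 S/m) in a cascade of current
# dividers, with the two bypass resistances chosen so that a 43.5 uA drive
# realizes the 4.7 / 2.7 / 1.0 mV/mm design point in s1 / s2 / s3.
# Geometry here is a configuration input, not a measured ground truth.
electrolyte:
  sigma: 1.5            # S/m
source:
  from: n0
  to: n3
  current: 43.5e-6      # A
edges:
  - {from: n0, to: n1, label: s1,
     geometry: {length: 10.0e-3, width: 7.7127659574468085e-3, height: 0.8e-3}}
  - {from: n1, to: n2, label: s2,
     geometry: {length: 10.0e-3, width: 7.7127659574468085e-3, height: 0.8e-3}}
  - {from: n1, to: n3, label: bypass1, resistance: 1998.8505747126442}
  - {from: n2, to: n3, label: s3,
     geometry: {length: 10.0e-3, width: 7.7127659574468085e-3, height: 0.8e-3}}
  - {from: n2, to: n3, label: bypass2, resistance: 635.5645706558485}
electrode:
  diameter: 15.0e-3     # m, disk
  # capacitance / voltage_window intentionally absent: only their product is
  # constrained by the observed 12.5 min capacitive window at 43.5 uA
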
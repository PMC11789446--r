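# Categorical call -> vote weight mapping for the nine-tool consensus
# deleteriousness vote. Per-tool maps use the dbNSFP single-letter
# conventions; the `default` map understands the spelled-out generic calls
# and applies to every tool. Numeric calls in [0, 1] bypass the table and
# are used as weights directly.
default:
  deleterious: 1.0
  damaging: 1.0
  disease_causing: 1.0
  intermediate: 0.5
  tolerated: 0.0
  benign: 0.0
  neutral: 0.0
  polymorphism: 0.0
  unknown: 0.0
  missing: 0.0
sift:
  d: 1.0
  t: 0.0
polyphen2:
  d: 1.0            # probably damaging
  probably_damaging: 1.0
  p: 0.5            # possibly damaging
  possibly_damaging: 0.5
  b: 0.0
lrt:
  d: 1.0
  n: 0.0
  u: 0.0
mutation_taster:
  a: 1.0            # disease causing automatic
  d: 1.0
  n: 0.0
  p: 0.0
mutation_assessor:
  h: 1.0            # high functional impact
  high: 1.0
  m: 0.5            # medium functional impact
  medium: 0.5
  l: 0.0
  low: 0.0
  n: 0.0
fathmm:
  d: 1.0
  t: 0.0
metasvm:
  d: 1.0
  t: 0.0
metalr:
  d: 1.0
  t: 0.0
provean:
  d: 1.0
  n: 0.0
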
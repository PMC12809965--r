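# FreeBayes post hoc filter presets: minimum thresholds per annotation.
# These presets are reconstructions of common post hoc practice for
# FreeBayes polyploid callsets, not authoritative values; edit freely and
# point filter_policy(config = ...) at your copy.
#
# minimal: quality floor only — recommended default for diploid callsets,
#          where stricter filtering mostly costs recall.
# strict:  adds mapping-quality and depth floors — can recover precision in
#          tetraploid/hexaploid callsets at higher coverage, at a recall
#          cost.
minimal:
  QUAL: 20
strict:
  QUAL: 30
  MQM: 40
  DP: 10
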
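{
  "n_canonical_output": 206,
  "n_intact_longfoxp3": 39,
  "n_degraded_longfoxp3": 87,
  "n_altprom_polya_output": 133,
  "n_longfoxp3_reads": 126,
  "n_special_splice_longfoxp3": 4,
  "n_short_upstream_polya": 3,
  "coverage_canonical": 463,
  "coverage_alt": 279,
  "coverage_alt_prose": 272,
  "ngs_exon11_max": 894,
  "drs_exon11_max": 912
}
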
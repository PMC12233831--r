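promoter_id,peak_number,chrom,region_start,region_end,ngs_coverage
canonical,1,chrX,49264670,49264735,463
alternative,1,chrX,49266233,49266279,272
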
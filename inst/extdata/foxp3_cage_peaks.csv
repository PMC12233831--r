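promoter_id,peak_number,chrom,cluster_start,cluster_end,tss,score
canonical,1,chrX,49264704,49264717,49264710,18671
canonical,2,chrX,49264549,49264582,49264567,315
alternative,1,chrX,49266299,49266300,49266300,396
alternative,2,chrX,49266450,49266454,49266452,195
alternative,3,chrX,49266491,49266500,49266496,453
alternative,4,chrX,49266722,49266750,49266729,261
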
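{"classes":3,"prevalences":[0.3,0.4,0.3],"mafs":[0.3,0.5],"genotype_rows":[{"genotype":[0,0],"penetrance":[0.6,0.3,0.1]},{"genotype":[1,0],"penetrance":[0.2,0.6,0.2]},{"genotype":[2,0],"penetrance":[0.1,0.3,0.6]},{"genotype":[0,1],"penetrance":[0.2,0.6,0.2]},{"genotype":[1,1],"penetrance":[0.1,0.3,0.6]},{"genotype":[2,1],"penetrance":[0.6,0.3,0.1]},{"genotype":[0,2],"penetrance":[0.1,0.3,0.6]},{"genotype":[1,2],"penetrance":[0.6,0.3,0.1]},{"genotype":[2,2],"penetrance":[0.2,0.6,0.2]}],"pattern_id":"demo-checkerboard"}
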
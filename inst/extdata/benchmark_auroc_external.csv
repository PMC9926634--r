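drug,omics_stacking,moli,superfelt,early_integration,omiembed,moma,pca
Gemcitabine_TCGA,0.655,0.640,0.618,0.604,0.565,0.473,0.527
Gemcitabine_PDX,0.714,0.614,0.692,0.525,0.657,0.627,0.600
Cisplatin,0.644,0.674,0.728,0.604,0.513,0.687,0.743
Docetaxel,0.584,0.647,0.588,0.456,0.478,0.581,0.475
Erlotinib,0.744,0.722,0.563,0.789,0.633,0.715,0.800
Cetuximab,0.575,0.476,0.556,0.470,0.468,0.505,0.523
Paclitaxel,0.619,0.547,0.527,0.418,0.516,0.573,0.435
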
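drug,omics_stacking,moli,superfelt,early_integration,omiembed,moma,pca
Gemcitabine_TCGA,0.581,0.535,0.502,0.513,0.462,0.389,0.421
Gemcitabine_PDX,0.510,0.424,0.457,0.362,0.466,0.414,0.481
Cisplatin,0.942,0.950,0.963,0.932,0.908,0.952,0.964
Docetaxel,0.560,0.590,0.565,0.491,0.544,0.578,0.523
Erlotinib,0.440,0.410,0.223,0.428,0.294,0.369,0.427
Cetuximab,0.125,0.141,0.126,0.108,0.101,0.148,0.110
Paclitaxel,0.256,0.191,0.147,0.120,0.135,0.172,0.163
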
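drug,omics_stacking,moli,superfelt,early_integration,omiembed,moma,pca
Gemcitabine_TCGA,0.646,0.628,0.588,0.611,0.628,0.650,0.614
Gemcitabine_PDX,0.651,0.622,0.646,0.586,0.539,0.625,0.607
Cisplatin,0.722,0.764,0.753,0.660,0.640,0.714,0.710
Docetaxel,0.772,0.792,0.813,0.731,0.803,0.783,0.723
Erlotinib,0.754,0.705,0.744,0.671,0.664,0.739,0.660
Cetuximab,0.731,0.731,0.768,0.677,0.754,0.751,0.655
Paclitaxel,0.667,0.596,0.726,0.607,0.740,0.692,0.588
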
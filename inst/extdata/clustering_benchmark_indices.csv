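object,SC,CH,DBI
polarity,positive,positive,negative
GMM,0.5822,2242.194,0.81623
K-means,0.6464,3032.312,0.75618
K-medoids,0.6277,3863.054,0.70741
ISODATA,0.6101,3432.406,0.72068
DBSCAN,0.6318,4226.564,0.61713
SSA-DBSCAN,0.6775,4615.198,0.53475
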
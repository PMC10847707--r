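{
  "schema_version": "1.0",
  "assays": [
    {
      "reaction": "A",
      "channel": "FAM",
      "tm_wt_c": 70.0,
      "variants": [
        {"gene": "GJB2", "hgvs": "c.35delG", "dbsnp": "rs80338939",
         "acmg_class": "Pathogenic", "inheritance": "autosomal",
         "delta_tm_c": 5.19, "window_halfwidth_c": 0.76}
      ]
    },
    {
      "reaction": "A",
      "channel": "HEX",
      "tm_wt_c": 72.0,
      "variants": [
        {"gene": "GJB2", "hgvs": "c.167delT", "dbsnp": "rs80338942",
         "acmg_class": "Pathogenic", "inheritance": "autosomal",
         "delta_tm_c": 5.6, "window_halfwidth_c": 1.15},
        {"gene": "GJB2", "hgvs": "c.176_191del16", "dbsnp": "rs750188782",
         "acmg_class": "Pathogenic", "inheritance": "autosomal",
         "delta_tm_c": 9.22, "window_halfwidth_c": 0.51}
      ]
    },
    {
      "reaction": "A",
      "channel": "ROX",
      "tm_wt_c": 78.0,
      "variants": [
        {"gene": "GJB3", "hgvs": "c.538C>T", "dbsnp": "rs74315319",
         "acmg_class": "Uncertain significance", "inheritance": "autosomal",
         "delta_tm_c": 9.02, "window_halfwidth_c": 0.64},
        {"gene": "GJB3", "hgvs": "c.547G>A", "dbsnp": "rs74315318",
         "acmg_class": "Conflicting interpretations of pathogenicity", "inheritance": "autosomal",
         "delta_tm_c": 6.05, "window_halfwidth_c": 0.5}
      ]
    },
    {
      "reaction": "A",
      "channel": "ROX2",
      "tm_wt_c": 64.0,
      "variants": [
        {"gene": "GJB2", "hgvs": "c.235delC", "dbsnp": "rs80338943",
         "acmg_class": "Pathogenic", "inheritance": "autosomal",
         "delta_tm_c": 4.82, "window_halfwidth_c": 0.93}
      ]
    },
    {
      "reaction": "A",
      "channel": "CY5",
      "tm_wt_c": 68.0,
      "variants": [
        {"gene": "GJB2", "hgvs": "c.299_300delAT", "dbsnp": "rs111033204",
         "acmg_class": "Pathogenic", "inheritance": "autosomal",
         "delta_tm_c": -6.97, "window_halfwidth_c": 0.87}
      ]
    },
    {
      "reaction": "B",
      "channel": "FAM",
      "tm_wt_c": 70.0,
      "variants": [
        {"gene": "SLC26A4", "hgvs": "c.919-2A>G", "dbsnp": "rs111033313",
         "acmg_class": "Pathogenic", "inheritance": "autosomal",
         "delta_tm_c": 5.42, "window_halfwidth_c": 1.34}
      ]
    },
    {
      "reaction": "B",
      "channel": "ROX",
      "tm_wt_c": 72.0,
      "variants": [
        {"gene": "SLC26A4", "hgvs": "c.1174A>T", "dbsnp": "rs201562855",
         "acmg_class": "Pathogenic", "inheritance": "autosomal",
         "delta_tm_c": 6.05, "window_halfwidth_c": 0.73},
        {"gene": "SLC26A4", "hgvs": "c.754T>C", "dbsnp": null,
         "acmg_class": "Pathogenic", "inheritance": "autosomal",
         "delta_tm_c": -4.26, "window_halfwidth_c": 1.33}
      ]
    },
    {
      "reaction": "B",
      "channel": "CY5",
      "tm_wt_c": 68.0,
      "variants": [
        {"gene": "SLC26A4", "hgvs": "c.1226G>A", "dbsnp": "rs111033305",
         "acmg_class": "Pathogenic", "inheritance": "autosomal",
         "delta_tm_c": -4.51, "window_halfwidth_c": 1.97},
        {"gene": "SLC26A4", "hgvs": "c.1229C>T", "dbsnp": "rs111033220",
         "acmg_class": "Pathogenic", "inheritance": "autosomal",
         "delta_tm_c": 7.0, "window_halfwidth_c": 0.57}
      ]
    },
    {
      "reaction": "C",
      "channel": "FAM",
      "tm_wt_c": 70.0,
      "variants": [
        {"gene": "SLC26A4", "hgvs": "c.1707+5G>A", "dbsnp": "rs192366176",
         "acmg_class": "Pathogenic", "inheritance": "autosomal",
         "delta_tm_c": 6.1, "window_halfwidth_c": 1.52}
      ]
    },
    {
      "reaction": "C",
      "channel": "HEX",
      "tm_wt_c": 70.0,
      "variants": [
        {"gene": "SLC26A4", "hgvs": "c.2162C>T", "dbsnp": "rs121908363",
         "acmg_class": "Pathogenic", "inheritance": "autosomal",
         "delta_tm_c": 4.57, "window_halfwidth_c": 1.65},
        {"gene": "SLC26A4", "hgvs": "c.2168A>G", "dbsnp": "rs121908362",
         "acmg_class": "Pathogenic", "inheritance": "autosomal",
         "delta_tm_c": -4.54, "window_halfwidth_c": 1.48},
        {"gene": "SLC26A4", "hgvs": "c.1975G>C", "dbsnp": "rs200455203",
         "acmg_class": "Pathogenic", "inheritance": "autosomal",
         "delta_tm_c": -7.84, "window_halfwidth_c": 0.58}
      ]
    },
    {
      "reaction": "C",
      "channel": "ROX",
      "tm_wt_c": 74.0,
      "variants": [
        {"gene": "SLC26A4", "hgvs": "c.749T>C", "dbsnp": "rs1790985775",
         "acmg_class": "Uncertain significance", "inheritance": "autosomal",
         "delta_tm_c": 5.1, "window_halfwidth_c": 0.97}
      ]
    },
    {
      "reaction": "C",
      "channel": "CY5",
      "tm_wt_c": 66.0,
      "variants": [
        {"gene": "SLC26A4", "hgvs": "c.2027T>A", "dbsnp": "rs111033318",
         "acmg_class": "Pathogenic", "inheritance": "autosomal",
         "delta_tm_c": -6.5, "window_halfwidth_c": 2.01}
      ]
    },
    {
      "reaction": "D",
      "channel": "FAM",
      "tm_wt_c": 70.0,
      "variants": [
        {"gene": "MT_RNR1", "hgvs": "m.1555A>G", "dbsnp": "rs267606617",
         "acmg_class": "Drug response", "inheritance": "mitochondrial",
         "delta_tm_c": 4.44, "window_halfwidth_c": 1.09}
      ]
    },
    {
      "reaction": "D",
      "channel": "HEX",
      "tm_wt_c": 74.0,
      "variants": [
        {"gene": "MT_RNR1", "hgvs": "m.1494C>T", "dbsnp": "rs267606619",
         "acmg_class": "Drug response", "inheritance": "mitochondrial",
         "delta_tm_c": 8.1, "window_halfwidth_c": 0.56}
      ]
    }
  ]
}
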
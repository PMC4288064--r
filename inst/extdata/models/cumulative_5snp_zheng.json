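{
  "name": "5-SNP_Zheng",
  "type": "cumulative",
  "snps": [
    {
      "rsid": "rs1447295",
      "risk_allele": "A",
      "genetic_model": "dominant"
    },
    {
      "rsid": "rs16901979",
      "risk_allele": "A",
      "genetic_model": "dominant"
    },
    {
      "rsid": "rs6983267",
      "risk_allele": "G",
      "genetic_model": "dominant"
    },
    {
      "rsid": "rs1859962",
      "risk_allele": "G",
      "genetic_model": "recessive"
    },
    {
      "rsid": "rs4430796",
      "risk_allele": "A",
      "genetic_model": "recessive"
    }
  ],
  "reference_table": [
    {
      "total_impact": 0,
      "or_without_fhh": 1,
      "ci_low_without_fhh": null,
      "ci_high_without_fhh": null,
      "or_with_fhh": 1,
      "ci_low_with_fhh": null,
      "ci_high_with_fhh": null
    },
    {
      "total_impact": 1,
      "or_without_fhh": 1.5,
      "ci_low_without_fhh": 1.18,
      "ci_high_without_fhh": 1.92,
      "or_with_fhh": 1.62,
      "ci_low_with_fhh": 1.27,
      "ci_high_with_fhh": 2.08
    },
    {
      "total_impact": 2,
      "or_without_fhh": 1.96,
      "ci_low_without_fhh": 1.54,
      "ci_high_without_fhh": 2.49,
      "or_with_fhh": 2.07,
      "ci_low_with_fhh": 1.62,
      "ci_high_with_fhh": 2.64
    },
    {
      "total_impact": 3,
      "or_without_fhh": 2.21,
      "ci_low_without_fhh": 1.7,
      "ci_high_without_fhh": 2.89,
      "or_with_fhh": 2.71,
      "ci_low_with_fhh": 2.08,
      "ci_high_with_fhh": 3.53
    },
    {
      "total_impact": 4,
      "or_without_fhh": 4.47,
      "ci_low_without_fhh": 2.93,
      "ci_high_without_fhh": 6.8,
      "or_with_fhh": 4.76,
      "ci_low_with_fhh": 3.31,
      "ci_high_with_fhh": 6.84
    },
    {
      "total_impact": 5,
      "or_without_fhh": 4.47,
      "ci_low_without_fhh": 2.93,
      "ci_high_without_fhh": 6.8,
      "or_with_fhh": 9.46,
      "ci_low_with_fhh": 3.62,
      "ci_high_with_fhh": 24.72
    },
    {
      "total_impact": 6,
      "or_without_fhh": null,
      "ci_low_without_fhh": null,
      "ci_high_without_fhh": null,
      "or_with_fhh": 9.46,
      "ci_low_with_fhh": 3.62,
      "ci_high_with_fhh": 24.72
    }
  ],
  "supports_fhh": true,
  "reference_table_source": "published"
}
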
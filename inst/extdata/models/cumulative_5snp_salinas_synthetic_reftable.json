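{
  "name": "5-SNP_Salinas",
  "type": "cumulative",
  "snps": [
    {
      "rsid": "rs1447295",
      "risk_allele": "A",
      "genetic_model": "dominant"
    },
    {
      "rsid": "rs6983267",
      "risk_allele": "G",
      "genetic_model": "dominant"
    },
    {
      "rsid": "rs6983561",
      "risk_allele": "C",
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
      "or_with_fhh": 1
    },
    {
      "total_impact": 1,
      "or_without_fhh": 1.35,
      "or_with_fhh": 1.46
    },
    {
      "total_impact": 2,
      "or_without_fhh": 1.82,
      "or_with_fhh": 1.97
    },
    {
      "total_impact": 3,
      "or_without_fhh": 2.46,
      "or_with_fhh": 2.66
    },
    {
      "total_impact": 4,
      "or_without_fhh": 3.32,
      "or_with_fhh": 3.59
    },
    {
      "total_impact": 5,
      "or_without_fhh": 4.48,
      "or_with_fhh": 4.84
    },
    {
      "total_impact": 6,
      "or_without_fhh": null,
      "or_with_fhh": 6.54
    }
  ],
  "supports_fhh": true,
  "reference_table_source": "synthetic"
}
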
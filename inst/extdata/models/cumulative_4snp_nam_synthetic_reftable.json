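{
  "name": "4-SNP_Nam",
  "type": "cumulative",
  "snps": [
    {
      "rsid": "rs1800629",
      "risk_allele": "A",
      "genetic_model": "dominant"
    },
    {
      "rsid": "rs2348763",
      "risk_allele": "A",
      "genetic_model": "recessive"
    },
    {
      "rsid": "rs1447295",
      "risk_allele": "A",
      "genetic_model": "dominant"
    },
    {
      "rsid": "rs1859962",
      "risk_allele": "G",
      "genetic_model": "recessive"
    }
  ],
  "reference_table": [
    {
      "total_impact": 0,
      "or_without_fhh": 1
    },
    {
      "total_impact": 1,
      "or_without_fhh": 1.35
    },
    {
      "total_impact": 2,
      "or_without_fhh": 1.82
    },
    {
      "total_impact": 3,
      "or_without_fhh": 2.46
    },
    {
      "total_impact": 4,
      "or_without_fhh": 3.32
    }
  ],
  "supports_fhh": false,
  "reference_table_source": "synthetic"
}
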
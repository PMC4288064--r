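{
  "name": "3-SNP_Beuten",
  "type": "cumulative",
  "snps": [
    {
      "rsid": "rs1819698",
      "risk_allele": "T",
      "genetic_model": "dominant"
    },
    {
      "rsid": "rs12439137",
      "risk_allele": "G",
      "genetic_model": "dominant"
    },
    {
      "rsid": "rs2470152",
      "risk_allele": "T",
      "genetic_model": "dominant"
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
    }
  ],
  "supports_fhh": false,
  "reference_table_source": "synthetic"
}
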
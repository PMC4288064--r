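{
  "name": "9-SNP_Helfand",
  "type": "cumulative",
  "snps": [
    {
      "rsid": "rs2710646",
      "risk_allele": "A",
      "genetic_model": "recessive"
    },
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
      "rsid": "rs10993994",
      "risk_allele": "T",
      "genetic_model": "recessive"
    },
    {
      "rsid": "rs10896450",
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
      "genetic_model": "dominant"
    },
    {
      "rsid": "rs5945572",
      "risk_allele": "A",
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
    },
    {
      "total_impact": 4,
      "or_without_fhh": 3.32
    },
    {
      "total_impact": 5,
      "or_without_fhh": 4.48
    },
    {
      "total_impact": 6,
      "or_without_fhh": 6.05
    },
    {
      "total_impact": 7,
      "or_without_fhh": 8.17
    },
    {
      "total_impact": 8,
      "or_without_fhh": 11.03
    },
    {
      "total_impact": 9,
      "or_without_fhh": 14.89
    }
  ],
  "supports_fhh": false,
  "reference_table_source": "synthetic"
}
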
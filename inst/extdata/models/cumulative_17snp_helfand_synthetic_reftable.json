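{
  "name": "17-SNP_Helfand",
  "type": "cumulative",
  "snps": [
    {
      "rsid": "rs721048",
      "risk_allele": "A",
      "genetic_model": "recessive"
    },
    {
      "rsid": "rs10934853",
      "risk_allele": "A",
      "genetic_model": "dominant"
    },
    {
      "rsid": "rs2736098",
      "risk_allele": "A",
      "genetic_model": "recessive"
    },
    {
      "rsid": "rs401681",
      "risk_allele": "C",
      "genetic_model": "dominant"
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
      "rsid": "rs16902094",
      "risk_allele": "G",
      "genetic_model": "dominant"
    },
    {
      "rsid": "rs445114",
      "risk_allele": "T",
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
      "rsid": "rs11228565",
      "risk_allele": "A",
      "genetic_model": "dominant"
    },
    {
      "rsid": "rs11649743",
      "risk_allele": "G",
      "genetic_model": "recessive"
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
      "rsid": "rs8102476",
      "risk_allele": "C",
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
      "or_without_fhh": 6.05,
      "or_with_fhh": 6.54
    },
    {
      "total_impact": 7,
      "or_without_fhh": 8.17,
      "or_with_fhh": 8.83
    },
    {
      "total_impact": 8,
      "or_without_fhh": 11.03,
      "or_with_fhh": 11.91
    },
    {
      "total_impact": 9,
      "or_without_fhh": 14.89,
      "or_with_fhh": 16.09
    },
    {
      "total_impact": 10,
      "or_without_fhh": 20.11,
      "or_with_fhh": 21.72
    },
    {
      "total_impact": 11,
      "or_without_fhh": 27.14,
      "or_with_fhh": 29.32
    },
    {
      "total_impact": 12,
      "or_without_fhh": 36.64,
      "or_with_fhh": 39.58
    },
    {
      "total_impact": 13,
      "or_without_fhh": 49.47,
      "or_with_fhh": 53.43
    },
    {
      "total_impact": 14,
      "or_without_fhh": 66.78,
      "or_with_fhh": 72.13
    },
    {
      "total_impact": 15,
      "or_without_fhh": 90.16,
      "or_with_fhh": 97.37
    },
    {
      "total_impact": 16,
      "or_without_fhh": 121.71,
      "or_with_fhh": 131.45
    },
    {
      "total_impact": 17,
      "or_without_fhh": 164.31,
      "or_with_fhh": 177.46
    },
    {
      "total_impact": 18,
      "or_without_fhh": null,
      "or_with_fhh": 239.57
    }
  ],
  "supports_fhh": true,
  "reference_table_source": "synthetic"
}
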
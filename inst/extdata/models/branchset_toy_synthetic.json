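{
  "name": "toy-branchset-synthetic",
  "type": "branch_set",
  "branches": [
    {
      "branch_id": "branch_1",
      "snp_requirements": [
        {
          "rsid": "rs1447295",
          "genotype": "AA"
        },
        {
          "rsid": "rs6983267",
          "allele": "G"
        }
      ]
    },
    {
      "branch_id": "branch_2",
      "snp_requirements": [
        {
          "rsid": "rs4430796",
          "genotype": "AA"
        },
        {
          "rsid": "rs1859962",
          "genotype": "GG"
        },
        {
          "rsid": "rs16901979",
          "allele": "A"
        }
      ]
    },
    {
      "branch_id": "branch_3",
      "snp_requirements": [
        {
          "rsid": "rs1447295",
          "allele": "A"
        }
      ],
      "clinical_requirements": [
        {
          "field": "smoking",
          "value": "positive"
        },
        {
          "field": "bmi_class",
          "value": "obese"
        }
      ]
    },
    {
      "branch_id": "branch_4",
      "snp_requirements": [
        {
          "rsid": "rs6983267",
          "genotype": "GG"
        }
      ],
      "clinical_requirements": [
        {
          "field": "alcohol",
          "value": "negative"
        }
      ]
    }
  ],
  "metrics": {
    "accuracy": 0.716,
    "precision": 0.7269,
    "recall": 0.6896
  },
  "source": "synthetic"
}
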
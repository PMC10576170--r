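{
  "comment": "Synthetic record, hand-constructed to mirror the shape of a parsed NCBI Taxonomy efetch entry; not a saved service response.",
  "canonical": "Panthera leo",
  "record": {
    "TaxId": "9689",
    "ScientificName": "Panthera leo",
    "Rank": "species",
    "OtherNames": {
      "GenbankCommonName": "lion",
      "Synonym": ["Felis leo"],
      "Name": [
        {"ClassCDE": "authority", "DispName": "Panthera leo (Linnaeus, 1758)"},
        {"ClassCDE": "authority", "DispName": "Felis leo Linnaeus, 1758"}
      ]
    }
  }
}
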
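{
  "description": "Structural schema for the planted ground-truth tables written by write_fixture(): required components and column types.",
  "tables": {
    "genes": {
      "gene": "string",
      "species": "string",
      "is_domain_bearing": "logical"
    },
    "subfamilies": {
      "subfamily_id": "string",
      "family_id": "string",
      "clade_specific": "logical"
    }
  },
  "other": ["pathway_genes"]
}
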
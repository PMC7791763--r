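{
  "participant_id": "HCRC1",
  "fh_available": true,
  "relatives": [
    {"id": "r1", "relation": "grandparent", "lineage": "maternal", "sex": "F",
     "diagnoses": [{"condition": "colorectal"}]},
    {"id": "r2", "relation": "aunt_uncle", "lineage": "maternal", "sex": "F",
     "diagnoses": [{"condition": "colorectal"}]}
  ]
}
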
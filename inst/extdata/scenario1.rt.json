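{
  "format": "rt-tuples",
  "version": "1.0",
  "metadata": {
    "scenario": 1,
    "ice": "IUI-8"
  },
  "particulars": [
    {
      "iui": "IUI-1",
      "label": "Mr. Adam Jones",
      "existence_interval": "t1"
    },
    {
      "iui": "IUI-10",
      "label": "information quality entity",
      "existence_interval": "t10"
    },
    {
      "iui": "IUI-2",
      "label": "IUI-1's disease",
      "existence_interval": "t2"
    },
    {
      "iui": "IUI-3",
      "label": "Dr. Anne Smith",
      "existence_interval": "t3"
    },
    {
      "iui": "IUI-4",
      "label": "cognitive system of IUI-3",
      "existence_interval": "t4"
    },
    {
      "iui": "IUI-5",
      "label": "anatomical part of IUI-4",
      "existence_interval": "t5"
    },
    {
      "iui": "IUI-6",
      "label": "cognitive representation",
      "existence_interval": "t6"
    },
    {
      "iui": "IUI-9",
      "label": "sentence as written on paper",
      "existence_interval": "t9"
    }
  ],
  "universals": [
    {
      "uui": "UUI-1",
      "label": "type 2 diabetes mellitus",
      "exists_flag": true
    },
    {
      "uui": "UUI-3",
      "label": "hyperglycemia (phenotype)",
      "exists_flag": true
    }
  ],
  "temporal_regions": [
    "t1",
    "t10",
    "t11",
    "t12",
    "t13",
    "t14",
    "t15",
    "t16",
    "t17",
    "t18",
    "t19",
    "t2",
    "t20",
    "t21",
    "t3",
    "t4",
    "t5",
    "t6",
    "t7",
    "t9"
  ],
  "temporal_constraints": [
    {
      "subject": "t15",
      "relation": "during",
      "object": "t11"
    },
    {
      "subject": "t16",
      "relation": "during",
      "object": "t2"
    },
    {
      "subject": "t16",
      "relation": "ends",
      "object": "t11"
    },
    {
      "subject": "t21",
      "relation": "during",
      "object": "t11"
    }
  ],
  "instantiations": [
    {
      "particular": "IUI-2",
      "universal": "UUI-1",
      "at": "t2"
    }
  ],
  "relations": [
    {
      "subject": "IUI-10",
      "relation": "concretizes",
      "object": "IUI-8",
      "at": "t10"
    },
    {
      "subject": "IUI-10",
      "relation": "is_about",
      "object": "IUI-1",
      "at": "t10"
    },
    {
      "subject": "IUI-10",
      "relation": "is_about",
      "object": "IUI-2",
      "at": "t10"
    },
    {
      "subject": "IUI-10",
      "relation": "is_about",
      "object": "IUI-7",
      "at": "t10"
    },
    {
      "subject": "IUI-10",
      "relation": "is_about",
      "object": "UUI-1",
      "at": "t10"
    },
    {
      "subject": "IUI-10",
      "relation": "is_conformant_to",
      "object": "IUI-6",
      "at": "t10"
    },
    {
      "subject": "IUI-10",
      "relation": "output_of",
      "object": "IUI-13",
      "at": "t19"
    },
    {
      "subject": "IUI-12",
      "relation": "input_into",
      "object": "IUI-11",
      "at": "t15"
    },
    {
      "subject": "IUI-14",
      "relation": "input_into",
      "object": "IUI-11",
      "at": "t21"
    },
    {
      "subject": "IUI-2",
      "relation": "inheres_in",
      "object": "IUI-1",
      "at": "t2"
    },
    {
      "subject": "IUI-3",
      "relation": "agent_in",
      "object": "IUI-11",
      "at": "t11"
    },
    {
      "subject": "IUI-4",
      "relation": "part_of",
      "object": "IUI-3",
      "at": "t4"
    },
    {
      "subject": "IUI-5",
      "relation": "part_of",
      "object": "IUI-4",
      "at": "t14"
    },
    {
      "subject": "IUI-6",
      "relation": "concretizes",
      "object": "IUI-8",
      "at": "t6"
    },
    {
      "subject": "IUI-6",
      "relation": "inheres_in",
      "object": "IUI-5",
      "at": "t6"
    },
    {
      "subject": "IUI-6",
      "relation": "input_into",
      "object": "IUI-13",
      "at": "t18"
    },
    {
      "subject": "IUI-6",
      "relation": "is_about",
      "object": "IUI-1",
      "at": "t6"
    },
    {
      "subject": "IUI-6",
      "relation": "is_about",
      "object": "IUI-2",
      "at": "t6"
    },
    {
      "subject": "IUI-6",
      "relation": "is_about",
      "object": "IUI-7",
      "at": "t6"
    },
    {
      "subject": "IUI-6",
      "relation": "is_about",
      "object": "UUI-1",
      "at": "t6"
    },
    {
      "subject": "IUI-6",
      "relation": "output_of",
      "object": "IUI-11",
      "at": "t16"
    },
    {
      "subject": "IUI-8",
      "relation": "input_into",
      "object": "IUI-13",
      "at": "t17"
    },
    {
      "subject": "IUI-8",
      "relation": "output_of",
      "object": "IUI-11",
      "at": "t16"
    }
  ],
  "negatives": [],
  "configurations": [
    {
      "id": "IUI-7",
      "members_particulars": [
        "IUI-1",
        "IUI-2"
      ],
      "members_universals": [
        "UUI-1"
      ],
      "constituent_relations": [
        {
          "kind": "relation",
          "subject": "IUI-2",
          "relation": "inheres_in",
          "object": "IUI-1",
          "at": "t2"
        },
        {
          "kind": "instantiation",
          "particular": "IUI-2",
          "universal": "UUI-1",
          "at": "t2"
        }
      ],
      "anchor": "t2"
    }
  ],
  "ices": [
    {
      "id": "IUI-8",
      "content": {
        "asserted_organism": "IUI-1",
        "asserted_disease": "IUI-2",
        "asserted_type": "UUI-1",
        "asserted_anchor": "t16",
        "intended_target": "IUI-7"
      },
      "concretizations": [
        "IUI-10",
        "IUI-6"
      ],
      "produced_by": "IUI-11",
      "first_concretized_at": "t16"
    }
  ],
  "representations": [
    {
      "id": "IUI-10",
      "kind": "inscription_quality",
      "bearer": "IUI-9",
      "concretizes": "IUI-8",
      "exists_during": "t10"
    },
    {
      "id": "IUI-6",
      "kind": "cognitive",
      "bearer": "IUI-5",
      "concretizes": "IUI-8",
      "exists_during": "t6"
    }
  ],
  "processes": [
    {
      "id": "IUI-11",
      "agent": "IUI-3",
      "agent_is_human": true,
      "inputs": [
        "IUI-12",
        "IUI-14"
      ],
      "outputs": [
        "IUI-6",
        "IUI-8"
      ],
      "occupies": "t11"
    },
    {
      "id": "IUI-13",
      "agent": "IUI-3",
      "agent_is_human": true,
      "inputs": [
        "IUI-6",
        "IUI-8"
      ],
      "outputs": [
        "IUI-10"
      ],
      "occupies": "t13"
    }
  ],
  "clinical_pictures": [
    {
      "id": "IUI-12",
      "subject": "IUI-1",
      "inferred_from": [],
      "exists_during": "t12"
    }
  ],
  "knowledge_aggregates": [
    {
      "id": "IUI-14",
      "owner": "IUI-3",
      "disease_types": [
        "UUI-1"
      ],
      "phenotype_types": [
        "UUI-3"
      ],
      "associations": [
        {
          "disease": "UUI-1",
          "phenotype": "UUI-3"
        }
      ]
    }
  ]
}
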
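{
  "schema_version": "1.0",
  "worker_organisms": [
    "k_pneumoniae",
    "m_mazei"
  ],
  "reference_reactions": [],
  "vertices": [
    {
      "id": "acetate@k_pneumoniae",
      "compound": "acetate",
      "organism": "k_pneumoniae"
    },
    {
      "id": "acetate@m_mazei",
      "compound": "acetate",
      "organism": "m_mazei"
    },
    {
      "id": "acetyl_coa@m_mazei",
      "compound": "acetyl_coa",
      "organism": "m_mazei"
    },
    {
      "id": "gap@k_pneumoniae",
      "compound": "gap",
      "organism": "k_pneumoniae"
    },
    {
      "id": "glycerol@k_pneumoniae",
      "compound": "glycerol",
      "organism": "k_pneumoniae"
    },
    {
      "id": "glycerone@k_pneumoniae",
      "compound": "glycerone",
      "organism": "k_pneumoniae"
    },
    {
      "id": "glycerone_p@k_pneumoniae",
      "compound": "glycerone_p",
      "organism": "k_pneumoniae"
    },
    {
      "id": "hpa3@k_pneumoniae",
      "compound": "hpa3",
      "organism": "k_pneumoniae"
    },
    {
      "id": "methane@m_mazei",
      "compound": "methane",
      "organism": "m_mazei"
    },
    {
      "id": "methyl_com@m_mazei",
      "compound": "methyl_com",
      "organism": "m_mazei"
    },
    {
      "id": "pdo@k_pneumoniae",
      "compound": "pdo",
      "organism": "k_pneumoniae"
    },
    {
      "id": "pep@k_pneumoniae",
      "compound": "pep",
      "organism": "k_pneumoniae"
    },
    {
      "id": "pyruvate@k_pneumoniae",
      "compound": "pyruvate",
      "organism": "k_pneumoniae"
    },
    {
      "id": "pyruvate@m_mazei",
      "compound": "pyruvate",
      "organism": "m_mazei"
    }
  ],
  "arcs": [
    {
      "id": "r_ack@m_mazei",
      "reaction": "r_ack",
      "sources": [
        "acetate@m_mazei"
      ],
      "target": "acetyl_coa@m_mazei",
      "weight": 1,
      "category": "endogenous",
      "organism": "m_mazei"
    },
    {
      "id": "r_glp1@k_pneumoniae",
      "reaction": "r_glp1",
      "sources": [
        "glycerol@k_pneumoniae"
      ],
      "target": "glycerone@k_pneumoniae",
      "weight": 1,
      "category": "endogenous",
      "organism": "k_pneumoniae"
    },
    {
      "id": "r_glp2@k_pneumoniae",
      "reaction": "r_glp2",
      "sources": [
        "glycerone@k_pneumoniae"
      ],
      "target": "glycerone_p@k_pneumoniae",
      "weight": 1,
      "category": "endogenous",
      "organism": "k_pneumoniae"
    },
    {
      "id": "r_glp3@k_pneumoniae",
      "reaction": "r_glp3",
      "sources": [
        "glycerone_p@k_pneumoniae"
      ],
      "target": "gap@k_pneumoniae",
      "weight": 1,
      "category": "endogenous",
      "organism": "k_pneumoniae"
    },
    {
      "id": "r_glp4@k_pneumoniae",
      "reaction": "r_glp4",
      "sources": [
        "gap@k_pneumoniae"
      ],
      "target": "pep@k_pneumoniae",
      "weight": 1,
      "category": "endogenous",
      "organism": "k_pneumoniae"
    },
    {
      "id": "r_glp5@k_pneumoniae",
      "reaction": "r_glp5",
      "sources": [
        "pep@k_pneumoniae"
      ],
      "target": "pyruvate@k_pneumoniae",
      "weight": 1,
      "category": "endogenous",
      "organism": "k_pneumoniae"
    },
    {
      "id": "r_mtg1@m_mazei",
      "reaction": "r_mtg1",
      "sources": [
        "pyruvate@m_mazei"
      ],
      "target": "acetyl_coa@m_mazei",
      "weight": 1,
      "category": "endogenous",
      "organism": "m_mazei"
    },
    {
      "id": "r_mtg2@m_mazei",
      "reaction": "r_mtg2",
      "sources": [
        "acetyl_coa@m_mazei"
      ],
      "target": "methyl_com@m_mazei",
      "weight": 1,
      "category": "endogenous",
      "organism": "m_mazei"
    },
    {
      "id": "r_mtg3@m_mazei",
      "reaction": "r_mtg3",
      "sources": [
        "methyl_com@m_mazei"
      ],
      "target": "methane@m_mazei",
      "weight": 1,
      "category": "endogenous",
      "organism": "m_mazei"
    },
    {
      "id": "r_pdo1@k_pneumoniae",
      "reaction": "r_pdo1",
      "sources": [
        "glycerol@k_pneumoniae"
      ],
      "target": "hpa3@k_pneumoniae",
      "weight": 1,
      "category": "endogenous",
      "organism": "k_pneumoniae"
    },
    {
      "id": "r_pdo2@k_pneumoniae",
      "reaction": "r_pdo2",
      "sources": [
        "hpa3@k_pneumoniae"
      ],
      "target": "pdo@k_pneumoniae",
      "weight": 1,
      "category": "endogenous",
      "organism": "k_pneumoniae"
    },
    {
      "id": "r_poxB@k_pneumoniae",
      "reaction": "r_poxB",
      "sources": [
        "pyruvate@k_pneumoniae"
      ],
      "target": "acetate@k_pneumoniae",
      "weight": 1,
      "category": "endogenous",
      "organism": "k_pneumoniae"
    },
    {
      "id": "tr:acetate:k_pneumoniae->m_mazei",
      "reaction": "tr:acetate:k_pneumoniae->m_mazei",
      "sources": [
        "acetate@k_pneumoniae"
      ],
      "target": "acetate@m_mazei",
      "weight": 50,
      "category": "transition",
      "organism": "k_pneumoniae->m_mazei"
    },
    {
      "id": "tr:acetate:m_mazei->k_pneumoniae",
      "reaction": "tr:acetate:m_mazei->k_pneumoniae",
      "sources": [
        "acetate@m_mazei"
      ],
      "target": "acetate@k_pneumoniae",
      "weight": 50,
      "category": "transition",
      "organism": "m_mazei->k_pneumoniae"
    },
    {
      "id": "tr:pyruvate:k_pneumoniae->m_mazei",
      "reaction": "tr:pyruvate:k_pneumoniae->m_mazei",
      "sources": [
        "pyruvate@k_pneumoniae"
      ],
      "target": "pyruvate@m_mazei",
      "weight": 100,
      "category": "transition",
      "organism": "k_pneumoniae->m_mazei"
    },
    {
      "id": "tr:pyruvate:m_mazei->k_pneumoniae",
      "reaction": "tr:pyruvate:m_mazei->k_pneumoniae",
      "sources": [
        "pyruvate@m_mazei"
      ],
      "target": "pyruvate@k_pneumoniae",
      "weight": 100,
      "category": "transition",
      "organism": "m_mazei->k_pneumoniae"
    }
  ],
  "sources": [
    "glycerol@k_pneumoniae"
  ],
  "targets": [
    "methane@m_mazei",
    "pdo@k_pneumoniae"
  ],
  "weights": {
    "w_worker": 1,
    "w_other": 100,
    "w_transition": 100,
    "overrides": [
      {
        "category": "transition",
        "key": "acetate",
        "weight": 50
      }
    ]
  }
}
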
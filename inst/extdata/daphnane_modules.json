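{
  "name": "daphnane_toy",
  "description": "Desk-scale daphnane-type diterpenoid module system: a sketch of the 5/7/6 tricyclic skeleton divided into five module slots (A-C ring core variants, B-ring variants diagnosed by the C3H4O2-class neutral loss, acyl substituents diagnosed by low-mass acylium ions, C-ring orthoester vs 9,13,14-triol diagnosed by the MS1 adduct pattern, and macrocycle variants diagnosed by C10-class neutral losses). Structures are simplified two-dimensional sketches, not literature daphnane structures.",
  "optional_labels": [22, 23, 24],
  "modules": [
    {
      "id": "module_I",
      "label": "A-C ring core (C17 skeleton product ion)",
      "submodules": [
        {
          "id": "I1",
          "label": "typical core (1,2-en-3-one)",
          "smiles": "O=C1C=C([CH2:24])C2(C1)C[CH2:21]CC3(C2)C[CH2:25]CC3(C[O:22])[CH2:23]",
          "deltas": {"core17": [0, 0, 0, 0], "core20": [0, 0, 0, 0]}
        },
        {
          "id": "I2",
          "label": "12-oxygenated core",
          "smiles": "O=C1C=C([CH2:24])C2(C1)C(O)[CH2:21]CC3(C2)C[CH2:25]CC3(C[O:22])[CH2:23]",
          "deltas": {"core17": [0, 0, 1, 0], "core20": [0, 0, 1, 0]}
        },
        {
          "id": "I3",
          "label": "1,2-dihydro core",
          "smiles": "O=C1CC([CH2:24])C2(C1)C[CH2:21]CC3(C2)C[CH2:25]CC3(C[O:22])[CH2:23]",
          "deltas": {"core17": [0, 2, 0, 0], "core20": [0, 2, 0, 0]}
        }
      ]
    },
    {
      "id": "module_II",
      "label": "B-ring variant (characteristic C3-class neutral loss)",
      "submodules": [
        {
          "id": "II1",
          "label": "6,7-epoxide-derived lactone (C3H4O2 loss)",
          "smiles": "[C:21]1OC(=O)C1",
          "deltas": {"bloss": [0, 0, 0, 0]}
        },
        {
          "id": "II2",
          "label": "reduced B ring (C3H6O2 loss)",
          "smiles": "[C:21]1CC(O)C1",
          "deltas": {"bloss": [0, 2, 0, 0]}
        }
      ]
    },
    {
      "id": "module_III",
      "label": "acyl substituent on the orthoester (low-mass acylium)",
      "submodules": [
        {
          "id": "III1",
          "label": "benzoyl",
          "smiles": "[O:22]C(=O)c1ccccc1",
          "deltas": {"acylium": [0, 0, 0, 0]}
        },
        {
          "id": "III2",
          "label": "hexanoyl",
          "smiles": "[O:22]C(=O)CCCCC",
          "deltas": {"acylium": [-1, 6, 0, 0]}
        },
        {
          "id": "III3",
          "label": "cinnamoyl",
          "smiles": "[O:22]C(=O)/C=C/c1ccccc1",
          "deltas": {"acylium": [2, 2, 0, 0]}
        },
        {
          "id": "III4",
          "label": "dec-9-enoyl",
          "smiles": "[O:22]C(=O)CCCCCCCC=C",
          "deltas": {"acylium": [3, 12, 0, 0]}
        }
      ]
    },
    {
      "id": "module_IV",
      "label": "C-ring oxidation (orthoester vs 9,13,14-triol; MS1 pattern)",
      "submodules": [
        {
          "id": "IV1",
          "label": "9,13,14-orthoester",
          "smiles": "[C:25]1OC(C)(C)CO1",
          "deltas": {},
          "ms1_pattern": "protonated_dominant"
        },
        {
          "id": "IV2",
          "label": "9,13,14-triol",
          "smiles": "[C:25]1CC(O)C(O)C1O",
          "deltas": {},
          "ms1_pattern": "dehydration_dominant"
        }
      ]
    },
    {
      "id": "module_V",
      "label": "macrocyclic bridge (C10-class neutral losses)",
      "submodules": [
        {
          "id": "V0",
          "label": "none (normal daphnane)",
          "smiles": "",
          "deltas": {"macroloss": "absent"}
        },
        {
          "id": "V1",
          "label": "macrocycle, one substituent (C10H16O2 loss)",
          "smiles": "[CH2:23]CCCCC(O)CCC[CH2:24]",
          "deltas": {"macroloss": [0, 0, 0, 0]}
        },
        {
          "id": "V2",
          "label": "macrocycle, two substituents (C10H14O2 loss)",
          "smiles": "[CH2:23]CC(O)CCCC(O)CC[CH2:24]",
          "deltas": {"macroloss": [0, -2, 0, 0]}
        },
        {
          "id": "V3",
          "label": "macrocycle, three substituents (C10H12O2 loss)",
          "smiles": "[CH2:23]CC(O)CC(O)CC(O)CC[CH2:24]",
          "deltas": {"macroloss": [0, -4, 0, 0]}
        }
      ]
    }
  ],
  "templates": [
    {
      "id": "core17",
      "kind": "product_ion",
      "m0": "C17H17O2",
      "charge": 1,
      "slots": ["module_I"],
      "label_range": [200, 400]
    },
    {
      "id": "core20",
      "kind": "product_ion",
      "m0": "C20H25O6",
      "charge": 1,
      "slots": ["module_I"],
      "label_range": [200, 400]
    },
    {
      "id": "acylium",
      "kind": "product_ion",
      "m0": "C7H5O",
      "charge": 1,
      "slots": ["module_III"],
      "label_range": [50, 200]
    },
    {
      "id": "bloss",
      "kind": "neutral_loss",
      "m0": "C3H4O2",
      "charge": 0,
      "slots": ["module_II"],
      "carbons": [20, 17],
      "pair_base": "core17",
      "label_range": [200, 400]
    },
    {
      "id": "macroloss",
      "kind": "neutral_loss",
      "m0": "C10H16O2",
      "charge": 0,
      "slots": ["module_V"],
      "carbons": [30, 20],
      "pair_base": "core20",
      "label_range": [200, 560]
    }
  ]
}
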
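[
  {
    "name": "loop",
    "constant_sequence": "MKSPEELKRIFEKYAAKEGDPDQLSKDELKLLIQAEFPSLLKGMGGGXXXXXXXGGGSTLDDLFQELDKDGDGEVSFEEFQVLVKKISQ",
    "placeholder": "X"
  },
  {
    "name": "side",
    "constant_sequence": "MKSPEELKRIFEKYAAKEGDPDQLSXXELXXLIXXEFPSLLKGMSTLDDLFQELDKDGDGEVSFEEFQVLVKKISQ",
    "placeholder": "X"
  }
]
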
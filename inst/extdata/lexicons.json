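{
  "methods_titles": [
    "methods",
    "materials and methods",
    "experimental procedures",
    "star methods",
    "methods and materials",
    "subjects and methods",
    "online methods",
    "materials & methods",
    "methods details",
    "method details",
    "experimental section"
  ],
  "criteria": {
    "IRB": {
      "include": [
        "institutional review board",
        "\\bIRB\\b",
        "ethi(?:cs|cal) committee",
        "human subjects? protocols?"
      ],
      "weak": [
        "(?:approved|reviewed) by [^.;]{0,60}?committee"
      ],
      "exclude": [
        "animal care and use",
        "\\bIACUC\\b",
        "animal (?:care|ethics|welfare)"
      ]
    },
    "CONSENT": {
      "include": [
        "informed (?:\\w+ )?(?:consent|permission|assent)",
        "consent (?:was|were) obtained",
        "\\bassent\\b",
        "(?:written|verbal|oral) consent",
        "parental permission"
      ],
      "weak": [],
      "exclude": []
    },
    "IACUC": {
      "include": [
        "institutional animal care and use committee",
        "\\bIACUC\\b",
        "animal (?:care|ethics|welfare)[^.;]{0,40}committee",
        "\\banimals?\\b[\\s\\S]{0,200}(?:in accordance with|ethical approval|project licen[cs]e)",
        "(?:in accordance with|ethical approval|project licen[cs]e)[\\s\\S]{0,200}\\banimals?\\b"
      ],
      "weak": [],
      "exclude": []
    },
    "RANDOMIZATION": {
      "include": [
        "\\brandomi[sz](?:ed|ation|e|ing)",
        "randomly (?:assigned|allocated|divided|selected|chosen|distributed)"
      ],
      "weak": [],
      "exclude": []
    },
    "BLINDING": {
      "include": [
        "(?:single|double|triple)[- ]?blind"
      ],
      "weak": [
        "\\bblind(?:ed|ing)?\\b",
        "\\bunaware\\b",
        "\\bmasked\\b"
      ],
      "context": [
        "experimenter", "investigator", "observer", "\\bperson\\b", "rater",
        "assessor", "analys[ei]s", "assessment", "scored", "scoring",
        "evaluated", "outcome", "group assignment", "condition", "treatment",
        "genotype", "curator"
      ],
      "exclude": [
        "blind[- ]end"
      ]
    },
    "POWER": {
      "include": [
        "power analys[ei]s",
        "power calculation",
        "powered to detect",
        "statistical power",
        "sample size[^.;]{0,80}(?:calculat|comput|estimat|determin|based on|chosen)"
      ],
      "weak": [],
      "exclude": []
    },
    "SEX": {
      "include": [
        "\\b(?:males?|females?|men|women|boys?|girls?|mothers?|dams)\\b",
        "\\bsexe?s\\b",
        "\\bsex\\b",
        "\\bgender\\b"
      ],
      "weak": [],
      "exclude": [
        "doublesex",
        "sex[- ]lethal",
        "maleless",
        "male[- ]specific lethal",
        "sex[- ]determining region",
        "sex[- ]comb"
      ]
    },
    "CELL_AUTH": {
      "include": [
        "authenticat",
        "STR profil",
        "short tandem repeat",
        "identity (?:was|were) (?:verified|confirmed)",
        "STR analysis"
      ],
      "weak": [],
      "exclude": []
    },
    "CELL_CONTAM": {
      "include": [
        "mycoplasma"
      ],
      "weak": [],
      "exclude": []
    }
  },
  "vendors": [
    "Santa Cruz Biotechnology", "Abcam", "Cell Signaling Technology",
    "Sigma-Aldrich", "Thermo Fisher Scientific", "Invitrogen",
    "BD Biosciences", "EMD Millipore", "Millipore", "R&D Systems", "Bio-Rad",
    "Proteintech", "Novus Biologicals", "Jackson ImmunoResearch",
    "The Jackson Laboratory", "Jackson Laboratory", "Charles River",
    "Taconic", "Envigo", "Harlan", "American Type Culture Collection",
    "American Tissue Culture Collection", "ATCC", "DSMZ", "ECACC", "JCRB",
    "RIKEN", "Addgene", "DGRC", "Bloomington Drosophila Stock Center",
    "Promega", "Qiagen", "New England Biolabs", "Roche",
    "Rainbow Transgenics", "Dharmacon", "GeneTex", "Aves Labs",
    "Synaptic Systems", "Vector Laboratories", "Abnova", "BioLegend",
    "eBioscience", "Enzo Life Sciences", "Agilent", "Takara", "Clontech"
  ],
  "software_registry": [
    "ImageJ", "ImageJ2", "Fiji", "FIJI", "NEURON", "MATLAB",
    "GraphPad Prism", "Prism", "SPSS", "CellProfiler", "FlowJo", "Imaris",
    "LabVIEW", "Photoshop", "ZEN", "NIS-Elements", "MetaMorph",
    "EthoVision", "ANY-maze", "pClamp", "Clampfit", "Igor Pro", "RStudio",
    "Bioconductor", "Cytoscape", "BLAST", "Bowtie", "Bowtie2", "BWA",
    "SAMtools", "GATK", "DESeq2", "edgeR", "limma", "Seurat", "PyMOL",
    "ChimeraX", "MaxQuant", "Trimmomatic", "FastQC", "HISAT2", "StringTie",
    "kallisto", "Huygens", "Volocity", "TensorFlow", "PyTorch",
    "scikit-learn", "Stata", "Minitab", "JMP", "OriginPro", "Gromacs"
  ],
  "cell_line_registry": [
    "HeLa", "Vero", "Jurkat", "CHO"
  ],
  "name_stopwords": [
    "the", "a", "an", "this", "that", "these", "those", "all", "each",
    "every", "any", "primary", "secondary", "following", "respective",
    "same", "appropriate", "corresponding", "specific", "of", "with",
    "using", "and", "or"
  ]
}
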
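{
  "name": "PowerPlex-16-like synthetic 15-locus STR panel",
  "loci": [
    {"locus": "D3S1358", "dye": "blue", "repeat_bp": 4, "offset_bp": 67,
     "alleles": ["12", "13", "14", "15", "16", "17", "18", "19"]},
    {"locus": "TH01", "dye": "blue", "repeat_bp": 4, "offset_bp": 156,
     "alleles": ["5", "6", "7", "8", "9", "9.3", "10"]},
    {"locus": "D21S11", "dye": "blue", "repeat_bp": 4, "offset_bp": 95,
     "alleles": ["27", "28", "29", "30", "31", "32", "33", "34"]},
    {"locus": "D18S51", "dye": "blue", "repeat_bp": 4, "offset_bp": 250,
     "alleles": ["10", "11", "12", "13", "14", "15", "16", "17", "18", "19", "20", "21", "22"]},
    {"locus": "PENTA E", "dye": "blue", "repeat_bp": 5, "offset_bp": 354,
     "alleles": ["5", "6", "7", "8", "9", "10", "11", "12", "13", "14", "15", "16", "17", "18", "19", "20", "21", "22", "23", "24"]},
    {"locus": "D5S818", "dye": "green", "repeat_bp": 4, "offset_bp": 91,
     "alleles": ["7", "8", "9", "10", "11", "12", "13", "14", "15", "16"]},
    {"locus": "D13S317", "dye": "green", "repeat_bp": 4, "offset_bp": 148,
     "alleles": ["7", "8", "9", "10", "11", "12", "13", "14", "15"]},
    {"locus": "D7S820", "dye": "green", "repeat_bp": 4, "offset_bp": 191,
     "alleles": ["6", "7", "8", "9", "10", "11", "12", "13", "14"]},
    {"locus": "D16S539", "dye": "green", "repeat_bp": 4, "offset_bp": 244,
     "alleles": ["5", "8", "9", "10", "11", "12", "13", "14", "15"]},
    {"locus": "CSF1PO", "dye": "green", "repeat_bp": 4, "offset_bp": 297,
     "alleles": ["6", "7", "8", "9", "10", "11", "12", "13", "14", "15"]},
    {"locus": "PENTA D", "dye": "green", "repeat_bp": 5, "offset_bp": 351,
     "alleles": ["5", "6", "7", "8", "9", "10", "11", "12", "13", "14", "15", "16", "17"]},
    {"locus": "VWA", "dye": "yellow", "repeat_bp": 4, "offset_bp": 79,
     "alleles": ["11", "12", "13", "14", "15", "16", "17", "18", "19", "20", "21"]},
    {"locus": "D8S1179", "dye": "yellow", "repeat_bp": 4, "offset_bp": 175,
     "alleles": ["7", "8", "9", "10", "11", "12", "13", "14", "15", "16", "17", "18"]},
    {"locus": "TPOX", "dye": "yellow", "repeat_bp": 4, "offset_bp": 238,
     "alleles": ["6", "7", "8", "9", "10", "11", "12", "13"]},
    {"locus": "FGA", "dye": "yellow", "repeat_bp": 4, "offset_bp": 250,
     "alleles": ["18", "19", "20", "21", "22", "23", "24", "25", "26", "27", "28", "29", "30"]}
  ]
}
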
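{
  "regions": {
    "1": "bankssts",
    "2": "caudalanteriorcingulate",
    "3": "caudalmiddlefrontal",
    "4": "cuneus",
    "5": "entorhinal",
    "6": "frontalpole",
    "7": "fusiform",
    "8": "inferiorparietal",
    "9": "inferiortemporal",
    "10": "insula",
    "11": "isthmuscingulate",
    "12": "lateraloccipital",
    "13": "lateralorbitofrontal",
    "14": "lingual",
    "15": "medialorbitofrontal",
    "16": "middletemporal",
    "17": "paracentral",
    "18": "parahippocampal",
    "19": "parsopercularis",
    "20": "parsorbitalis",
    "21": "parstriangularis",
    "22": "pericalcarine",
    "23": "postcentral",
    "24": "posteriorcingulate",
    "25": "precentral",
    "26": "precuneus",
    "27": "rostralanteriorcingulate",
    "28": "rostralmiddlefrontal",
    "29": "superiorfrontal",
    "30": "superiorparietal",
    "31": "superiortemporal",
    "32": "supramarginal",
    "33": "temporalpole",
    "34": "transversetemporal",
    "99": "cerebral_white_matter"
  },
  "grey_labels": [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20, 21, 22, 23, 24, 25, 26, 27, 28, 29, 30, 31, 32, 33, 34],
  "white_labels": 99
}
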
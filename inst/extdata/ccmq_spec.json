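{
  "likert": { "min": 1, "max": 5 },
  "subscales": [
    { "name": "GTC",  "items": [1, 2, 7, 8, 21, 27, 53, 54], "reverse": [2, 7, 8, 21, 27, 54], "inferred": false },
    { "name": "QDC",  "items": [2, 3, 4, 5, 6, 7, 22, 26],   "reverse": [], "inferred": false },
    { "name": "YaDC", "items": [17, 18, 19, 21, 22, 52, 55], "reverse": [], "inferred": true },
    { "name": "YiDC", "items": [16, 20, 29, 35, 38, 44, 46, 57], "reverse": [], "inferred": false },
    { "name": "PDC",  "items": [13, 15, 28, 42, 49, 50, 51, 58], "reverse": [], "inferred": false },
    { "name": "DHC",  "items": [39, 41, 48, 56, 59, 60], "reverse": [], "inferred": true },
    { "name": "BSC",  "items": [27, 33, 36, 37, 40, 43, 45], "reverse": [], "inferred": true },
    { "name": "QSC",  "items": [8, 9, 10, 11, 12, 14, 47], "reverse": [], "inferred": true },
    { "name": "SDC",  "items": [23, 24, 25, 30, 31, 32, 34], "reverse": [], "inferred": true }
  ],
  "labels": {
    "1": "energetic", "2": "tiredness", "3": "breathlessness", "5": "dizziness",
    "6": "quietude", "7": "weak voice", "8": "depression", "9": "anxiety",
    "10": "vulnerability", "14": "sighing", "15": "lethargy",
    "16": "palmar-plantar hot", "19": "cold aversion", "20": "localized hotness",
    "21": "cold intolerance", "22": "susceptibility to colds",
    "23": "frequent sneezing", "24": "chronic rhinitis", "25": "sensitivity cough",
    "26": "hyperhidrosis", "27": "forgetfulness", "28": "oily T-zone",
    "29": "reddened lips", "30": "allergies", "31": "urticaria",
    "33": "unexplained bruising", "34": "dermatographism", "35": "dryness",
    "36": "facial telangiectasia", "37": "pain", "39": "oily skin",
    "40": "hyperpigmentation", "43": "dark circles", "44": "dry eyes",
    "46": "thirstiness", "48": "bitter mouth", "49": "sticky mouth",
    "50": "flabby abdomen", "51": "excess phlegm", "52": "cold sensitivity",
    "53": "adaptability", "54": "insomnia", "55": "cold-induced diarrhea",
    "56": "sticky stools", "57": "constipation", "58": "thick tongue coating",
    "59": "urethral heat", "60": "wet scrotum / yellowing leukorrhea"
  }
}
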
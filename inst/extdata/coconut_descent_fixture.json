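{
  "name": "coconut_descent",
  "description": "Descent of a 16-chromosome coconut-like genome from 10 monocot proto-chromosomes, with a basal unduplicated outgroup (Sp), a sigma-WGT lineage sharing tau (Ac), and a eudicot-like calibrator (Vv) splitting at the root (monocot-eudicot calibration midpoint). Node ages in My; rates in synonymous substitutions per site per My.",
  "root_node": "R",
  "root": { "n_chromosomes": 10, "genes_per_chromosome": 100 },
  "ages": { "R": 173.5, "A": 150, "B": 137.5, "C": 110, "Acs": 85,
            "D": 50, "E": 50, "Cn": 0, "Sp": 0, "Ac": 0, "Vv": 0 },
  "lineages": ["Cn", "Sp", "Ac", "Vv"],
  "branches": [
    { "from": "R", "to": "Vv", "rate": 0.003, "dnds": 0.2, "events": [] },
    { "from": "R", "to": "A", "rate": 0.003, "dnds": 0.2, "events": [] },
    { "from": "A", "to": "Sp", "rate": 0.0045, "dnds": 0.2, "events": [
      { "kind": "INVERSION", "chr": "A4", "fromFrac": 0.3, "toFrac": 0.6 },
      { "kind": "INVERSION", "chr": "A9", "fromFrac": 0.2, "toFrac": 0.5 }
    ] },
    { "from": "A", "to": "B", "rate": 0.003, "dnds": 0.2, "events": [
      { "kind": "EEJ", "chr1": "A2", "chr2": "A9" },
      { "kind": "EEJ", "chr1": "A5", "chr2": "A8" },
      { "kind": "INVERSION", "chr": "A3", "fromFrac": 0.35, "toFrac": 0.65 }
    ] },
    { "from": "B", "to": "C", "rate": 0.003, "dnds": 0.2, "events": [
      { "kind": "WGD", "tag": "tau" },
      { "kind": "FRACTIONATION", "prob": 0.2 }
    ] },
    { "from": "C", "to": "Acs", "rate": 0.003, "dnds": 0.2, "events": [] },
    { "from": "Acs", "to": "Ac", "rate": 0.003, "dnds": 0.2, "events": [
      { "kind": "WGT", "tag": "sig" },
      { "kind": "FRACTIONATION", "prob": 0.35 }
    ] },
    { "from": "C", "to": "D", "rate": 0.003, "dnds": 0.2, "events": [
      { "kind": "EEJ", "chr1": "A1", "chr2": "A3" },
      { "kind": "EEJ", "chr1": "A4", "chr2": "A6" },
      { "kind": "EEJ", "chr1": "A7", "chr2": "A10" },
      { "kind": "EEJ", "chr1": "A6.tau2", "chr2": "A1.tau2" },
      { "kind": "EEJ", "chr1": "A10.tau2", "chr2": "A4.tau2" },
      { "kind": "NESTED_FUSION", "host": "A2--A9", "insert": "A7.tau2",
        "atFrac": 0.25 },
      { "kind": "NESTED_FUSION", "host": "A5--A8.tau2",
        "insert": "A3.tau2", "atFrac": 0.75 },
      { "kind": "ARM_EXCHANGE", "chr1": "A1--A3", "at1Frac": 0.7,
        "chr2": "A5--A8", "at2Frac": 0.8 },
      { "kind": "ARM_EXCHANGE", "chr1": "A6.tau2--A1.tau2",
        "at1Frac": 0.75, "chr2": "A2--A9.tau2", "at2Frac": 0.75 }
    ] },
    { "from": "D", "to": "E", "rate": 0.003, "dnds": 0.2, "events": [
      { "kind": "WGD", "tag": "om" },
      { "kind": "FRACTIONATION", "prob": 0.2 }
    ] },
    { "from": "E", "to": "Cn", "rate": 0.003, "dnds": 0.2, "events": [
      { "kind": "NESTED_FUSION", "host": "A4--A6", "insert": "A7--A10",
        "atFrac": 0.25 },
      { "kind": "NESTED_FUSION", "host": "A10.tau2--A4.tau2.om2",
        "insert": "A5--A8.om2", "atFrac": 0.25 },
      { "kind": "ARM_EXCHANGE", "chr1": "A1--A3", "at1Frac": 0.6,
        "chr2": "A6.tau2--A1.tau2", "at2Frac": 0.6 },
      { "kind": "ARM_EXCHANGE", "chr1": "A2--A9.tau2", "at1Frac": 0.55,
        "chr2": "A2--A9", "at2Frac": 0.35 },
      { "kind": "ARM_EXCHANGE", "chr1": "A5--A8.tau2", "at1Frac": 0.65,
        "chr2": "A5--A8", "at2Frac": 0.6 },
      { "kind": "ARM_EXCHANGE", "chr1": "A1--A3.om2", "at1Frac": 0.3,
        "chr2": "A2--A9.tau2.om2", "at2Frac": 0.3 },
      { "kind": "ARM_EXCHANGE", "chr1": "A10.tau2--A4.tau2",
        "at1Frac": 0.7, "chr2": "A6.tau2--A1.tau2.om2", "at2Frac": 0.3 },
      { "kind": "INVERSION", "chr": "A7--A10.om2", "fromFrac": 0.55,
        "toFrac": 0.8 }
    ] }
  ]
}
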
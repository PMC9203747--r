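{
  "provenance": "Budding yeast cell-cycle Boolean threshold network, 11 regulatory nodes plus the frozen Cell Size signal. Transcribed from Li, Long, Lu, Ouyang & Tang (2004) PNAS 101:4781-4786 (Fig. 1): activating edges +1, inhibiting edges -1, threshold 0; on a tie the five self-degrading nodes (Cln3, Cln1/2, Swi5, Cdc20&Cdc14, Mcm1/SFF) decay to 0, all other nodes retain their state. Truth tables generated by boolcontrol:::build_yeast_cellcycle().",
  "nodes": ["CellSize", "Cln3", "MBF", "SBF", "Cln12", "Cdh1", "Swi5", "Cdc2014", "Clb56", "Sic1", "Clb12", "Mcm1"],
  "rules": [
    {
      "target": "CellSize",
      "regulators": "CellSize",
      "outputs": "01"
    },
    {
      "target": "Cln3",
      "regulators": "CellSize",
      "outputs": "01"
    },
    {
      "target": "MBF",
      "regulators": ["Cln3", "MBF", "Clb12"],
      "outputs": "00101011"
    },
    {
      "target": "SBF",
      "regulators": ["Cln3", "SBF", "Clb12"],
      "outputs": "00101011"
    },
    {
      "target": "Cln12",
      "regulators": "SBF",
      "outputs": "01"
    },
    {
      "target": "Cdh1",
      "regulators": ["Cln12", "Cdh1", "Cdc2014", "Clb56", "Clb12"],
      "outputs": "00001000100011100000000000001000"
    },
    {
      "target": "Swi5",
      "regulators": ["Cdc2014", "Clb12", "Mcm1"],
      "outputs": "01001101"
    },
    {
      "target": "Cdc2014",
      "regulators": ["Clb12", "Mcm1"],
      "outputs": "0111"
    },
    {
      "target": "Clb56",
      "regulators": ["MBF", "Cdc2014", "Clb56", "Sic1"],
      "outputs": "0010000010110010"
    },
    {
      "target": "Sic1",
      "regulators": ["Cln12", "Swi5", "Cdc2014", "Clb56", "Sic1", "Clb12"],
      "outputs": "0010000010110010101100101111101100000000001000000010000010110010"
    },
    {
      "target": "Clb12",
      "regulators": ["Cdh1", "Cdc2014", "Clb56", "Sic1", "Clb12", "Mcm1"],
      "outputs": "0111000111110111000100000111000100010000011100010000000000010000"
    },
    {
      "target": "Mcm1",
      "regulators": ["Clb56", "Clb12"],
      "outputs": "0111"
    }
  ]
}
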
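{
  "provenance": "Four-cell Drosophila melanogaster parasegment segment-polarity network (4 x 15 nodes). Constructed from the single-cell Boolean rules of Albert & Othmer (2003) J. Theor. Biol. 223:1-18 with intercellular WG/hh/HH signalling between ring neighbours (periodic boundary); SLP is a frozen external input per cell. Generated by boolcontrol:::build_parasegment().",
  "nodes": ["SLP_1", "wg_1", "WG_1", "en_1", "EN_1", "hh_1", "HH_1", "ptc_1", "PTC_1", "PH_1", "SMO_1", "ci_1", "CI_1", "CIA_1", "CIR_1", "SLP_2", "wg_2", "WG_2", "en_2", "EN_2", "hh_2", "HH_2", "ptc_2", "PTC_2", "PH_2", "SMO_2", "ci_2", "CI_2", "CIA_2", "CIR_2", "SLP_3", "wg_3", "WG_3", "en_3", "EN_3", "hh_3", "HH_3", "ptc_3", "PTC_3", "PH_3", "SMO_3", "ci_3", "CI_3", "CIA_3", "CIR_3", "SLP_4", "wg_4", "WG_4", "en_4", "EN_4", "hh_4", "HH_4", "ptc_4", "PTC_4", "PH_4", "SMO_4", "ci_4", "CI_4", "CIA_4", "CIR_4"],
  "rules": [
    {
      "target": "SLP_1",
      "regulators": "SLP_1",
      "outputs": "01"
    },
    {
      "target": "wg_1",
      "regulators": ["SLP_1", "wg_1", "CIA_1", "CIR_1"],
      "outputs": "0000001000101010"
    },
    {
      "target": "WG_1",
      "regulators": "wg_1",
      "outputs": "01"
    },
    {
      "target": "en_1",
      "regulators": ["SLP_1", "WG_2", "WG_4"],
      "outputs": "01110000"
    },
    {
      "target": "EN_1",
      "regulators": "en_1",
      "outputs": "01"
    },
    {
      "target": "hh_1",
      "regulators": ["EN_1", "CIR_1"],
      "outputs": "0010"
    },
    {
      "target": "HH_1",
      "regulators": "hh_1",
      "outputs": "01"
    },
    {
      "target": "ptc_1",
      "regulators": ["EN_1", "CIA_1", "CIR_1"],
      "outputs": "00100000"
    },
    {
      "target": "PTC_1",
      "regulators": ["ptc_1", "PTC_1", "HH_2", "HH_4"],
      "outputs": "0000100011111111"
    },
    {
      "target": "PH_1",
      "regulators": ["PTC_1", "HH_2", "HH_4"],
      "outputs": "00000111"
    },
    {
      "target": "SMO_1",
      "regulators": ["PTC_1", "HH_2", "HH_4"],
      "outputs": "11110111"
    },
    {
      "target": "ci_1",
      "regulators": "EN_1",
      "outputs": "10"
    },
    {
      "target": "CI_1",
      "regulators": "ci_1",
      "outputs": "01"
    },
    {
      "target": "CIA_1",
      "regulators": ["SMO_1", "CI_1", "hh_2", "hh_4"],
      "outputs": "0000011100001111"
    },
    {
      "target": "CIR_1",
      "regulators": ["SMO_1", "CI_1", "hh_2", "hh_4"],
      "outputs": "0000100000000000"
    },
    {
      "target": "SLP_2",
      "regulators": "SLP_2",
      "outputs": "01"
    },
    {
      "target": "wg_2",
      "regulators": ["SLP_2", "wg_2", "CIA_2", "CIR_2"],
      "outputs": "0000001000101010"
    },
    {
      "target": "WG_2",
      "regulators": "wg_2",
      "outputs": "01"
    },
    {
      "target": "en_2",
      "regulators": ["WG_1", "SLP_2", "WG_3"],
      "outputs": "01001100"
    },
    {
      "target": "EN_2",
      "regulators": "en_2",
      "outputs": "01"
    },
    {
      "target": "hh_2",
      "regulators": ["EN_2", "CIR_2"],
      "outputs": "0010"
    },
    {
      "target": "HH_2",
      "regulators": "hh_2",
      "outputs": "01"
    },
    {
      "target": "ptc_2",
      "regulators": ["EN_2", "CIA_2", "CIR_2"],
      "outputs": "00100000"
    },
    {
      "target": "PTC_2",
      "regulators": ["HH_1", "ptc_2", "PTC_2", "HH_3"],
      "outputs": "0010111100001111"
    },
    {
      "target": "PH_2",
      "regulators": ["HH_1", "PTC_2", "HH_3"],
      "outputs": "00010011"
    },
    {
      "target": "SMO_2",
      "regulators": ["HH_1", "PTC_2", "HH_3"],
      "outputs": "11011111"
    },
    {
      "target": "ci_2",
      "regulators": "EN_2",
      "outputs": "10"
    },
    {
      "target": "CI_2",
      "regulators": "ci_2",
      "outputs": "01"
    },
    {
      "target": "CIA_2",
      "regulators": ["hh_1", "SMO_2", "CI_2", "hh_3"],
      "outputs": "0001001100110011"
    },
    {
      "target": "CIR_2",
      "regulators": ["hh_1", "SMO_2", "CI_2", "hh_3"],
      "outputs": "0010000000000000"
    },
    {
      "target": "SLP_3",
      "regulators": "SLP_3",
      "outputs": "01"
    },
    {
      "target": "wg_3",
      "regulators": ["SLP_3", "wg_3", "CIA_3", "CIR_3"],
      "outputs": "0000001000101010"
    },
    {
      "target": "WG_3",
      "regulators": "wg_3",
      "outputs": "01"
    },
    {
      "target": "en_3",
      "regulators": ["WG_2", "SLP_3", "WG_4"],
      "outputs": "01001100"
    },
    {
      "target": "EN_3",
      "regulators": "en_3",
      "outputs": "01"
    },
    {
      "target": "hh_3",
      "regulators": ["EN_3", "CIR_3"],
      "outputs": "0010"
    },
    {
      "target": "HH_3",
      "regulators": "hh_3",
      "outputs": "01"
    },
    {
      "target": "ptc_3",
      "regulators": ["EN_3", "CIA_3", "CIR_3"],
      "outputs": "00100000"
    },
    {
      "target": "PTC_3",
      "regulators": ["HH_2", "ptc_3", "PTC_3", "HH_4"],
      "outputs": "0010111100001111"
    },
    {
      "target": "PH_3",
      "regulators": ["HH_2", "PTC_3", "HH_4"],
      "outputs": "00010011"
    },
    {
      "target": "SMO_3",
      "regulators": ["HH_2", "PTC_3", "HH_4"],
      "outputs": "11011111"
    },
    {
      "target": "ci_3",
      "regulators": "EN_3",
      "outputs": "10"
    },
    {
      "target": "CI_3",
      "regulators": "ci_3",
      "outputs": "01"
    },
    {
      "target": "CIA_3",
      "regulators": ["hh_2", "SMO_3", "CI_3", "hh_4"],
      "outputs": "0001001100110011"
    },
    {
      "target": "CIR_3",
      "regulators": ["hh_2", "SMO_3", "CI_3", "hh_4"],
      "outputs": "0010000000000000"
    },
    {
      "target": "SLP_4",
      "regulators": "SLP_4",
      "outputs": "01"
    },
    {
      "target": "wg_4",
      "regulators": ["SLP_4", "wg_4", "CIA_4", "CIR_4"],
      "outputs": "0000001000101010"
    },
    {
      "target": "WG_4",
      "regulators": "wg_4",
      "outputs": "01"
    },
    {
      "target": "en_4",
      "regulators": ["WG_1", "WG_3", "SLP_4"],
      "outputs": "00101010"
    },
    {
      "target": "EN_4",
      "regulators": "en_4",
      "outputs": "01"
    },
    {
      "target": "hh_4",
      "regulators": ["EN_4", "CIR_4"],
      "outputs": "0010"
    },
    {
      "target": "HH_4",
      "regulators": "hh_4",
      "outputs": "01"
    },
    {
      "target": "ptc_4",
      "regulators": ["EN_4", "CIA_4", "CIR_4"],
      "outputs": "00100000"
    },
    {
      "target": "PTC_4",
      "regulators": ["HH_1", "HH_3", "ptc_4", "PTC_4"],
      "outputs": "0111001100110011"
    },
    {
      "target": "PH_4",
      "regulators": ["HH_1", "HH_3", "PTC_4"],
      "outputs": "00010101"
    },
    {
      "target": "SMO_4",
      "regulators": ["HH_1", "HH_3", "PTC_4"],
      "outputs": "10111111"
    },
    {
      "target": "ci_4",
      "regulators": "EN_4",
      "outputs": "10"
    },
    {
      "target": "CI_4",
      "regulators": "ci_4",
      "outputs": "01"
    },
    {
      "target": "CIA_4",
      "regulators": ["hh_1", "hh_3", "SMO_4", "CI_4"],
      "outputs": "0001010101010101"
    },
    {
      "target": "CIR_4",
      "regulators": ["hh_1", "hh_3", "SMO_4", "CI_4"],
      "outputs": "0100000000000000"
    }
  ]
}
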
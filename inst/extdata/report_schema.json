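{
  "title": "assemblyscope pipeline report",
  "required": ["seed", "n_samples", "n_taxa", "groups", "thresholds"],
  "stages": {
    "diversity": {
      "required": ["alpha_group_means", "permanova", "anosim"]
    },
    "niche": {
      "required": ["community_breadth_group_means", "kruskal"]
    },
    "assembly": {
      "required": ["homogeneous_selection", "heterogeneous_selection",
                   "homogenizing_dispersal", "dispersal_limitation",
                   "drift"]
    },
    "ncm": {
      "required": ["m", "Nm", "r_squared"]
    },
    "network": {
      "required": ["meta_network", "subnetworks"]
    },
    "mantel": {
      "required": ["r", "p_value"]
    }
  }
}
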
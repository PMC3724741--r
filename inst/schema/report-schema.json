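{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "cgagg pipeline report",
  "type": "object",
  "required": ["schema_version", "seed", "parameters", "trajectory",
               "clusters", "contacts", "diffusion", "sasa"],
  "properties": {
    "schema_version": {"type": "string", "const": "1.0"},
    "seed": {"type": "integer"},
    "parameters": {"type": "object"},
    "trajectory": {
      "type": "object",
      "required": ["n_frames", "t_start_ns", "t_end_ns", "n_beads"]
    },
    "clusters": {
      "type": "object",
      "required": ["initial_n_clusters", "final_n_clusters",
                   "largest_final_size", "aggregation_time_ns"]
    },
    "contacts": {
      "type": "object",
      "required": ["n_frames", "n_proteins", "n_residues",
                   "total_contacts_per_frame", "max_P", "n_high_pairs"]
    },
    "diffusion": {
      "type": "object",
      "required": ["D_1e8_cm2_s", "stderr", "fit_window_ns"]
    },
    "sasa": {
      "type": "object",
      "required": ["early_window_ns", "late_window_ns", "n_buried",
                   "max_burial_nm2"]
    },
    "domains": {
      "type": ["object", "null"],
      "required": ["ratio_dppc_dlipc", "window_ns"]
    }
  }
}
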
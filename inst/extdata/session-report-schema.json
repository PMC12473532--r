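{
  "$comment": "Field contract for mirrorvitals session reports; enforced by validate_session_report().",
  "type": "object",
  "required": ["seed", "config", "fs", "phase", "valid_seconds", "windows", "trigger_log"],
  "properties": {
    "seed": {"type": ["integer", "number", "null"]},
    "config": {
      "type": "object",
      "required": ["window_s", "stride_s", "stabilization_s", "min_valid_s",
                   "snr_gate", "face_conf_gate", "hr_band"]
    },
    "fs": {"type": "number"},
    "phase": {"enum": ["stabilizing", "estimating", "triggered", "stopped"]},
    "valid_seconds": {"type": "number", "minimum": 0},
    "windows": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["t_start", "t_end", "hr_bpm", "spo2_pct", "snr", "valid"]
      }
    },
    "trigger_log": {"type": "array"}
  }
}
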
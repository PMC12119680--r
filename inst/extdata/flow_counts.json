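{
  "extracted": 4361,
  "excluded_cause": 665,
  "excluded_no_hb": 264,
  "excluded_not_anaemic": 1245
}
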
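utils::globalVariables(c(
  "len", "aid", "ref_id", "start", "read_id", "base", "ref_base", "mismatch",
  "terminal", "roff", "read_len", "weight", "fpos", "gene", "seq",
  "terminal_excluded", "depth", "A", "C", "G", "T", "gpos", ".I", ".N", "."
))
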
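{"n_levels":15,"level1":{"lifetime_s":15,"speed_deg_s":2,"up_pct":70,"down_pct":60},"change":{"lifetime_s":-0.786,"speed_deg_s":2.36,"up_pct":1.42,"down_pct":1.42}}
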
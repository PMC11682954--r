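# Example run configuration for btrefuge::parse_run_config() / cli_main()
scenario: 2
grid: "0:1:0.01"
mode: le
previous_resistance: true
output_dir: results
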
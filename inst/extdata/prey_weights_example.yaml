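# Example prey-category weight table (mean whole-item mass, grams).
# SYNTHETIC illustrative values for documentation and tests only: real
# analyses must supply site-specific means extrapolated from weighed prey.
amphibian: 25
anthropogenic: 80
bird: 45
invertebrate: 2
mammal: 28
unclassified: 36
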
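# Warm lazily-loaded Biostrings data objects once, so timed blocks measure
# computation rather than first-touch namespace loading.
invisible(standard_genetic_code())
invisible(Biostrings::reverseComplement(Biostrings::DNAStringSet("ACGT")))
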
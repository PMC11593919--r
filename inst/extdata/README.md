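# extdata

No data files ship with the package: all test fixtures are generated in
code by the synthetic-plastome simulator.

To run the paper-scale reproduction checks in the test suite, download the
deposited chloroplast genome (GenBank accession PP979534) as a GenBank flat
file and save it here as `PP979534.gb` before installing, e.g. from
https://www.ncbi.nlm.nih.gov/nuccore/PP979534 ("Send to > File > GenBank").
The package itself never accesses the network.
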
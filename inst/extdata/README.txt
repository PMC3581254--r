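Reference crystal structures are not redistributed with the package.

To run the worked-example checks in tests/testthat/test-acceptance.R,
download the PDB entries for diaminopimelate epimerase and levansucrase and
place them here before installing:

    1BWZ.pdb   e.g. https://files.rcsb.org/download/1BWZ.pdb
    1OYG.pdb   e.g. https://files.rcsb.org/download/1OYG.pdb

Without them, those checks report a failure explaining that the structures
are unavailable; everything else runs on fixtures generated in code.
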
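# Deposited coordinate files

Checks against the deposited branch-junction and inactive-complex models
need the original coordinate files, which are far too large to ship with
the package. To enable them, download the PDB-format files for entries
**7TPT** (activated complex at a branch junction) and **4JD2** (inactive
complex bound to GMFgamma) from the Protein Data Bank and place them here
as `7TPT.pdb` and `4JD2.pdb` before installing, e.g.

    curl -o 7TPT.pdb https://files.rcsb.org/download/7TPT.pdb
    curl -o 4JD2.pdb https://files.rcsb.org/download/4JD2.pdb

The chain-to-subunit maps for both entries live in
`inst/extdata/arptraj-config.yaml` and are marked provisional: verify them
against the downloaded files (and adjust the dialect maps if the entries
use different chain lettering) before interpreting results.

Without these files the corresponding acceptance test reports a failure,
and all other tests run on synthetic data only.
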
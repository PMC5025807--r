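# External data layout

Analyses of the published Jurassic–Cretaceous tetrapod occurrence
compilation expect a PaleoDB-classic CSV at

    inst/extdata/tennant2016/occurrences.csv

with columns `occurrence_no`, `genus`, `collection_no`, `reference_no`,
`formation`, `max_ma`, `min_ma`, plus `realm` (fully pelagic taxa flagged
`marine`; semi-aquatic and coastal taxa `nonmarine`), `region` and
`group` (clade label). The compilation is not redistributable here; the
data-dependent acceptance tests report failure until it is supplied.
All other tests and scripts generate their inputs in code.
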
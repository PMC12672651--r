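# Synthetic evidence fixtures

These tables are SYNTHETIC stand-ins for a curated multi-method rRNA
modification survey of the cauliflower (Brassica oleracea) mitoribosome; the
real per-method site lists are not redistributed here.  Positions named in
the survey's main text (e.g. m62A1827/1828, m4Cm1664, m3U1807, m2G1825,
mC1671, (m)C761, Gm2560, Um2857, Gm2858, m5U2257, m2A2808, psi2188, psi2885,
and four helix-69 pseudouridines) are anchored at their published residue
numbers; the remaining rows are invented so that the aggregate structure of
the published survey is reproduced exactly:

- 39 distinct (subunit, position) entries in total;
- cryo-EM 18 sites (6 SSU / 12 LSU), nanopore 28 (8 / 20), MS 20 (7 / 13);
- 19 consensus sites supported by at least two methods (7 SSU / 12 LSU);
- 8 pseudouridines among the consensus set;
- 9 plant-specific entries;
- 9 distinct modification types among the consensus assignments.

`synthetic_homology_map.tsv` maps conserved positions to their E. coli
equivalents for type assignment by homology (E. coli coordinates are
approximate and illustrative).

Columns: `subunit` (SSU|LSU), `position` (1-based nt on 18S/26S rRNA),
`type` (modification label, empty if the method did not type the site),
`plant_specific` (curated annotation, TRUE/FALSE).
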
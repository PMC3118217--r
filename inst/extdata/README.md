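# Reference summary tables

Small plain-text summary tables for two HapMap individuals (NA12716 and
NA12760) from a targeted 454 sequence-capture experiment over the human
8p23.1 defensin region (CTRL, DEFA, DEFB targets), used by the test suite
and the acceptance script to exercise the package's arithmetic on real
published-style inputs:

- `hapmap_concordance.tsv` — genotype concordance counts of capture calls
  against HapMap genotypes in the single-copy CTRL+DEFA regions
  (truth class x called class, per sample).
- `defb_haplotype_counts.tsv` — per-locus haplotype read counts in the
  copy-number-variable DEFB cluster of NA12760 (6 copies per diploid
  genome): total spanning reads, read counts per distinct haplotype,
  haploid-multiplicity annotation for two-haplotype loci (`.` if none),
  and the reported diploid copy number.
- `snv_counts.tsv` — known and putative novel SNV counts per sample and
  target region after masking and error filtering, plus the cross-sample
  union row.
- `region_sizes.tsv` — target sizes in kb and the masked (low-copy-repeat
  overlap) span used for density denominators.
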
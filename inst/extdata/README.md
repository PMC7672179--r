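# Bundled fixtures

- `patient01_elispot.tsv` — the printed Elispot validation outcomes of the
  two top-10 lists (TruNeo / MHCflurry) of the lung-cancer case study.
- `cohort_ranks_synthetic.tsv` — SYNTHETIC stand-in for the published
  per-epitope cohort rank table, which is not redistributable here. It is
  constructed so the per-method top-5/10/20 hit counts of the 19
  immunogenic epitopes over 13 patients equal the published summary counts
  (TruNeo 6/10/13, MHCflurry 4/4/8, NetMHCpan4 4/5/10); individual ranks,
  decoy rows and TPM values are invented. Only the summary counts are
  meaningful.
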
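# pairdca

Inter-protein coevolution analysis by mean-field direct coupling analysis
(DCA), for mapping the interaction surface between two proteins — such as
a two-component signalling pair (a PhoU-like regulator and a PhoR-like
histidine kinase) — from sequence data alone.

Residues that touch across a protein–protein interface tend to co-vary
across species: a substitution on one side is compensated on the other.
`pairdca` turns that signal into ranked candidate contact pairs:

1. **Paired alignment.** Orthologous sequences of the two proteins are
   joined per species, A first, with an artificial spacer (twenty
   alanines by default) marking the boundary, aligned externally (e.g.
   MAFFT), and cleaned by removing every column where the designated
   reference sequence has a gap — so columns map 1:1 onto reference
   residue numbers of each protein.
2. **Model fit.** Sequences are reweighted (weight 1/n over clusters of
   ≥ 80 % identity, giving an effective count M_eff) and single/pair
   column frequencies f_i(a), f_ij(a,b) are estimated over the 21-state
   alphabet (20 amino acids + gap) with a pseudocount λ. For every column
   pair the package computes
   - **mutual information** MI_ij = Σ_ab f_ij(a,b) ln[ f_ij(a,b) /
     (f_i(a) f_j(b)) ] (nats), which mixes direct and transitive
     covariation, and
   - **direct information** DI_ij, the mutual information of the two-site
     distribution P_ij(a,b) ∝ exp(e_ij(a,b)) h_i(a) h_j(b) built from the
     mean-field couplings e_ij = −(C⁻¹)_ij, where C is the connected
     correlation matrix C_ij(a,b) = f_ij(a,b) − f_i(a) f_j(b), with fields
     h fixed so P_ij reproduces the single-site frequencies. DI isolates
     the coupling carried directly by the pair.
3. **Pair analysis.** The N(N−1)/2-row (i, j, MI, DI) table is filtered
   for sequence-proximal pairs (|i − j| ≤ 5 removed), restricted to
   inter-protein pairs, translated to per-protein residue numbering, and
   ranked against anchor residues (e.g. a genetically implicated residue
   vs. a kinase sensory-domain span) by MI or DI.
4. **Structure validation.** Ranked pairs are annotated with minimum
   heavy-atom (or Cα–Cα) distances measured on any complex model in PDB
   format, minimising over chains when one partner is a homodimer.

A planted-coupling synthetic generator (`synthetic_spec()` /
`sample_paired_msa()`) with closed-form oracles makes every stage
testable without external data.

## Worked example

Simulate a paired MSA of 1000 species for a 30 + 40 residue protein pair
with five planted inter-protein couplings, fit the model, and rank
inter-protein pairs:

```r
library(pairdca)

spec   <- synthetic_spec(M = 1000, seed = 11)   # 5 planted pairs, 5% gaps
rec    <- sample_paired_msa(spec)
concat <- concatenate_with_spacer(rec)          # 20-Ala spacer
seqs   <- concat$sequence; names(seqs) <- concat$species_id
aln    <- remove_insert_columns(alignment_matrix(seqs, reference = 1))
map    <- build_position_map(aln, len_a = 30, spacer_len = 20)

fit <- dca(aln, position_map = map)             # theta = 0.2, lambda = M_eff
fit
#> Mean-field direct coupling analysis
#>   alignment: 1000 sequences x 90 columns (70 analysed)
#>   M_eff = 1000.00 (theta = 0.2), lambda = 1000.00
#>   pair table: 2415 rows

inter <- restrict_inter_protein(filter_proximal_pairs(fit$pairs, 5), map)
head(inter[order(-inter$di), ], 5)
#>  protein_i res_i protein_j res_j       mi       di distance
#>          A    26         B    37 1.655930 1.669119       NA
#>          A    24         B    22 1.601419 1.636726       NA
#>          A    16         B    21 1.606121 1.633502       NA
#>          A     2         B    12 1.641533 1.597819       NA
#>          A    25         B    30 1.646416 1.597037       NA
```

The five top-DI pairs are exactly the five planted pairs (true MI of each
generating joint: 1.604 nats, computed by `true_pair_statistics(spec)`),
so `evaluate_recovery(inter, spec, k = 5, by = "di")` reports
precision@5 = 1. Anchor-style ranking, as used to compare one implicated
residue against a candidate domain:

```r
q <- anchor_query(c("A", 26), "B", c(1, 40), sort_key = "mi", top_n = 5)
rank_anchor_hits(inter, q)
#>  partner_res anchor_res        mi         di distance
#>           37         26 1.6559298 1.66911895       NA
#>           40         26 0.1918491 0.02599788       NA
#>           36         26 0.1905537 0.02715045       NA
#>           23         26 0.1888791 0.02933460       NA
#>           13         26 0.1886201 0.02711914       NA
```

The true partner (B:37) stands far above the background on both scores.
With a docking model at hand, `read_structure()` +
`annotate_pairs_with_distances()` fill the `distance` column (Å), and
`run_pipeline()` drives all stages from one config list, writing the
pair table, rankings and a JSON manifest.

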
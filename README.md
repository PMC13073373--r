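# tchur

DNA data storage promises 2 bits per nucleotide, but a sequence that merely
encodes the payload is rarely synthesizable: GC imbalance destabilizes the
duplex, homopolymer runs trigger polymerase slippage and indel errors,
extreme melting temperatures and stacking free energies complicate PCR, and
self-reverse-complementary stretches fold into hairpins. `tchur` treats
oligo design as a constrained minimization problem and solves it with the
TC-HUR tri-phase hybrid metaheuristic, for researchers designing storage
oligos and for benchmarking sequence-design optimizers.

## The model

A candidate sequence `S` of length `L` over `{A,T,C,G}` is scored by

```
Fitness(S) = w_gc·f_GC + w_hp·f_HP + w_dg·f_ΔG  +  w_tm·C_Tm + w_ham·C_Ham + w_rc·C_RC
```

with quadratic soft penalties (all zero at the ideal):

- `f_GC = (GC% − 50)²`
- `f_HP = Σ_k (h_k − 3)²` over homopolymer runs `h_k > 3`
- `f_ΔG = |Σ ΔG_step/(L−1) − ΔG_target|·100`, nearest-neighbour stacking
  energies, target −1.45 kcal/mol
- `C_Tm = (Tm − T_bound)²` outside the window [55, 65] °C, with the
  salt-corrected empirical model `Tm = 64.9 + 41·(GC% − 16.4)/100`
- `C_Ham = (d_min − min_i d(S, A_i))²` when the candidate falls closer than
  `d_min` to an archive sequence `A_i`
- `C_RC = (r − 0.15)·100` when the reverse-complement self-similarity `r`
  exceeds 15%

TC-HUR minimizes this over the continuous relaxation `[0,3]^L` in three
phases: hunger-driven global exploration (Hunger Games Search dynamics)
augmented with a heavy-tailed Cauchy jump around the incumbent best;
Runge–Kutta-style greedy refinement of the elite 30%; and adaptive targeted
mutation (rate 2%→5%) that surgically repairs homopolymer and
reverse-complement violations. Canonical PSO, GWO, HGS and RUN baselines,
a substitution/insertion/deletion channel simulator with homopolymer-aware
indel boosting, normalized edit-distance (NED) scoring, and a Friedman /
Wilcoxon benchmark harness round out the toolkit.

## Worked example

Design a 1853-nt sequence from a synthetic payload, then stress-test it
under the high-noise channel regime:

```r
library(tchur)
payload <- make_benchmark_text(1853, seed = 7)
res <- tchur_optimize(payload = text_to_dna(payload),
                      control = tchur_config(N = 30, Tmax = 60, seed = 7))
print(res$breakdown)
#> <fitness_breakdown>
#>   total 829.6857 | GC 35.46% (f_gc 211.527) | maxHP 6 (f_hp 30.000)
#>   Tm 72.71C (c_tm 59.490) | dG sum -2301.87 (f_dg 20.709)
#>   RC 9.82% (c_rc 0.000) | min Hamming NA (c_ham 0.000)

channel_report(res$best, "high", n_reads = 200, seed = 7)
#> <error_summary> 200 reads | NED 0.1211 | rates sub 0.0303 ins 0.0849 del 0.0211
#>   GC->AT 23.1% | AT->GC 43.8% | HP indel 33.0% | HP sub 18.5%
```

The breakdown shows where the remaining penalty lives: GC has been pulled
down towards the Tm window (the GC and Tm terms are in direct conflict
under this Tm model), the longest homopolymer run is 6 nt, and the
reverse-complement similarity (9.82%) is safely below the 15% hairpin-risk
threshold so its penalty is zero. Under the high-noise regime
(per-position substitution/insertion/deletion probabilities
0.03/0.08/0.02), the designed sequence reads back with a mean normalized
edit distance of 0.12; the empirical per-nt error rates echo the channel's
nominal probabilities, and a third of indels fall in homopolymer context.

`write_fasta(list(res$best), "best.fasta")` exports the design; the
`exec/tchur` script exposes the same workflow from a shell
(`tchur design`, `tchur bench`, `tchur channel`).

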
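# motiftrie

De novo DNA motif discovery for ChIP-seq peak regions, built around a
sparse k-mer trie and a fast EM refinement stage.

## The problem and who this is for

A transcription-factor ChIP-seq experiment yields thousands of peak
regions (~100–300 bp) that are enriched for a short, degenerate binding
site. Recovering that site — the *motif*, modelled as a k × 4 position
weight matrix (PWM) — requires (i) counting every k-mer in a large
sequence set quickly, (ii) deciding which k-mers are enriched over a
background model, and (iii) refining the winning k-mers into a
probabilistic model. `motiftrie` implements this two-phase design for
analysts working with peak FASTA files at the scale where naive counting
and naive EM become the bottleneck.

## Method at its core

**Counting.** All `m = t − k + 1` windows of every width-`t` sequence are
inserted into a sparse trie stored as a node table `M ∈ N^{ν×6}` (four
child pointers, a terminal count, a 2-bit numeric code). Exact lookup
(`ksearch`) walks the pointers; bounded-mismatch lookup (`kdive`)
recurses depth-first and prunes a branch as soon as the accumulated
Hamming distance exceeds the budget `d`. With per-position mismatch
probability `p` the number of symbol comparisons per fragment is
negative-binomial with mean `d/p` — about `5·4/3 ≈ 6.7` comparisons at
`d = 5`, `p = 3/4` — so approximate search costs `O(d)` per fragment,
not `O(k)`. Enrichment of each stored k-mer `w` is tested with a
one-sided binomial tail against its expected count `m·P(w|β)` under an
order-r Markov background `β` (fitted from a control set, or from a
Markov/Eulerian shuffle of the peaks), with Benjamini–Hochberg control.

**Optimization.** Each enriched seed becomes a PWM `α` refined by EM
under an occurrence model (OOPS: one site per sequence; ZOOPS: zero or
one, with prior `γ`; ANR: independent per-window occurrences). The
per-offset marginal

    P(s_i | p_u) = ∏_{j<u} P(s_ij|β) · ∏_{j=u}^{u+k−1} α_{j−u+1, s_ij} · ∏_{j≥u+k} P(s_ij|β)

is computed from a single whole-sequence background pass: the total
background log score is computed once and each offset's value is
obtained by subtracting the window's background log sum and adding its
PWM log score, entirely in log space.

**Evaluation.** Discovered PWMs are aligned to references (e.g. JASPAR
matrices) by best mean Bhattacharyya coefficient over both strands, and
scored with six per-column metrics: Euclidean, Manhattan and Hellinger
distances, Pearson correlation, Bhattacharyya coefficient, and
Sandelin–Wasserman similarity.

## Worked example

Plant a ZOOPS motif (consensus `TGACTCAGCA`, one mutated position at
most, present in 90% of sequences) into 200 synthetic 80-bp peaks, then
recover it:

```r
library(motiftrie)
pl <- generate_planted(plant_spec(n = 200, t = 80, k = 10, d = 1,
                                  model = "zoops", gamma = 0.9,
                                  consensus = "TGACTCAGCA", seed = 11))
path <- tempfile(fileext = ".fa"); write_fasta(pl$dataset, path)
reports <- run_pipeline(pipeline_config(input = path, k = 10, seed = 11))
print(reports[[1]])
#> motif_report 1: TGACTCAGCA (seed CGCCGCAGAA, count 6, loglik -21098.18, 15 iter)
compare_pwms(reports[[1]]$pwm, pwm(pl$truth$true_column_distributions))
#>    euc    man   hell    pcc    bha     sw
#> 0.0205 0.0338 0.0409 0.9998 0.9981 1.9995
```

The report's consensus equals the planted consensus; the fitted PWM puts
0.92–0.97 on each consensus base (the generator's true per-column value
is 0.95), and the six metrics against the generator's true column
distributions sit near their identity values (`bha`/`pcc` near 1, `sw`
near 2, distances near 0). The fitted occurrence prior `gamma = 0.929`
estimates the planted rate of 0.9. EM here converged in 15 iterations
under the default stop (log-likelihood increment < 0.001, cap 1000
iterations).

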
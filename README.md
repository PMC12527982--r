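# sosdep

Predict whether a prophage is induced through the bacterial SOS response,
from sequence alone.

## The problem

Temperate phages integrate into bacterial genomes as prophages. In the
classical lysogenic–lytic switch, the SOS master repressor LexA binds
operator sequences ("SOS boxes") in the prophage and keeps lytic genes
silent; DNA damage activates RecA, LexA autocleaves, and the prophage is
induced. But a substantial fraction of prophages is *SOS-independent* —
mitomycin C or UV will never induce them — and telling the two classes
apart normally requires wet-lab induction assays. `sosdep` makes that call
computationally, for microbiologists and phage ecologists who have a
genome, its CDS annotations, and prophage coordinates.

## The method

A DNA window `w` of motif length `L` (20 bp for the canonical E. coli
operator `TACTG(TA)5CAGTA`) is scored against a position count matrix
`n_i(b)` with pseudocount `p` by its **heterology index**

```
HI(w) = sum_{i=1..L} ln[ (n_i(consensus_i) + p) / (n_i(w_i) + p) ]
```

HI is 0 at the consensus and grows with divergence; low HI means strong
predicted LexA binding. The pipeline then:

1. locates the host's `lexA` gene and confirms the **canonical SOS box
   (CSB)** in its own promoter (LexA autoregulation) — hosts without both
   are not called;
2. scans the genome for **potential SOS boxes (PSBs)** — windows matching
   the invariant `CTG…CAG` core on either strand — and clusters the
   genome-wide HI distribution (1-D **mean shift**, Silverman bandwidth)
   into a low-HI (binding) and a high-HI (non-binding) component. The
   genome-specific thresholds are the cluster edges:
   `HI_C1 = max(low cluster)`, `HI_C2 = min(high cluster)`;
3. scans promoter windows (300 bp upstream + 50 bp into each CDS, both
   configurable) inside each prophage and takes the minimum HI, `HI_min`;
4. calls the prophage **SdP** (`HI_min <= HI_C1`), **SiP**
   (`HI_min >= HI_C2`), or **SuP** (in between).

Validation statistics (exact Clopper–Pearson intervals, confusion
metrics), phage-versus-host composition features (coding density, CDS
overlap, intergenic GC, codon and k-mer cosine distances), and a seeded
synthetic-genome generator with planted operators round out the package.

## Worked example

```r
library(sosdep)

# a synthetic host genome with planted lexA, operators and four prophages
fx <- generate_fixture(fixture_spec(seed = 42), tempdir())

prof <- build_host_profile(fx$genome)
prof
#> <host_profile> synfix00042: status OK
#>   lexA: lexA [550, 1159) +, score 5.01
#>   CSB: HI 0.000, 80 bp from lexA start
#>   PSBs: 35
#>   thresholds: hi_c1 9.008, hi_c2 18.924

calls <- classify_prophages(fx$genome, fx$regions, prof)
calls[, c("prophage_id", "hi_min", "class")]
#>   prophage_id    hi_min class
#> 1 prophage_01  3.076334   SdP
#> 2 prophage_02  4.007892   SdP
#> 3 prophage_03 25.131798   SiP
#> 4 prophage_04 25.938890   SiP
```

The host status `OK` says lexA and its canonical box were found and the
genome-wide PSB HI values split cleanly (35 operators, low cluster up to
9.01, high cluster from 18.92). `prophage_01`'s best operator scores
HI 3.08 — well inside the binding cluster — so LexA can repress it: SdP.
`prophage_03`'s best candidate (HI 25.1) is indistinguishable from the
non-binding background: SiP. `autoplot(prof)` draws the HI histogram with
both thresholds; `tidy(prof)` / `glance(prof)` return the hit table and
the one-row profile summary.

File-based runs produce the same thing plus TSV/JSON reports:

```r
run_single(fx$paths$genbank, "out/", prophage_path = fx$paths$bed)
```

or from a shell, `Rscript inst/cli/sosdep.R run --genome g.gbk
--prophages p.bed --out out/` (subcommands `run`, `batch`, `fixture`,
`validate`; exit codes 10/11/12 mark the reportable outcomes NO_LEXA /
NO_CSB / AMBIGUOUS_CLUSTERING).

## Scope

`sosdep` does not predict prophage boundaries (they are an input), does
not build protein-sharing networks or taxonomies, and does not model
non-LexA induction mechanisms; hosts lacking LexA or a canonical SOS box
are reported as such rather than force-called.
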
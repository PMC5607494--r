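# hmdnuc

Nucleosome organization and sequence preference in hypomethylated domains
(HMDs).

In vertebrate genomes most of the DNA is CpG-methylated, but gene promoters
sit in short hypomethylated domains. Within these domains, nucleosomes are
arranged in phased arrays whose linkers are unusually accessible to
nucleases, unusually long (~200 bp spacing vs ~180 bp in the methylated
bulk, with an extra-wide ~250 bp linker at the 5' domain edge carrying the
TSS), and — unlike the rest of the genome — predictable from DNA sequence
alone. `hmdnuc` packages that analysis as a tested pipeline for anyone
working with methylomes plus accessibility (DNase-seq/ATAC-seq) and
nucleosome (MNase-seq) data:

* **HMD calling** — maximal runs of ≥ 10 consecutive CpGs with methylation
  ratio < 0.4.
* **Accessible-linker detection** — 5'-shifted cut counts, smoothed
  coverage, and a deterministic summit caller (external narrowPeak summits
  are accepted anywhere summits are consumed).
* **Boundary metaprofiles** — anchor each HMD boundary at the in-domain
  summit nearest the boundary CpG, orient it by the direction of
  transcription of the nearest TSS (5' if transcription runs into the
  domain), and average any per-base track over the anchors.
* **Spacing estimation** — lag-by-lag Pearson autocorrelation of the dyad
  metaprofile over offsets `0..1000` (HMD side) and `-1000..-100`
  (methylated side); the spacing is the lag of the strongest ACF peak in
  `[100, 400]` bp.
* **k-mer spectrum SVMs** — the core machinery. A linear soft-margin SVM
  on (unit-normalized) k-mer count vectors, trained by deterministic dual
  coordinate descent (compiled):
  * `SVM_DNaseI`: 100-bp linker sequences (centered on in-HMD summits)
    vs nucleosome-core sequences (centered between adjacent summits more
    than 150 bp apart);
  * `SVM_hypo`: whole HMD sequences under 3 kb vs ten length-matched
    methylated copies each.
  Decision function `f(x) = w·x + b`; the per-6-mer weights `w` are the
  biological readout. HMDs are scored with 100-bp windows every 20 bp,
  averaging overlapping windows per step, and compared with the
  accessibility signal by Pearson correlation per HMD. Evaluation is ROC /
  precision-recall on a held-out chromosome.
* **Motif periodicity** — histogram of all within-HMD pairwise distances
  between occurrences of the top-10-weight 6-mers (distances < 3 bp
  excluded).
* **Hard-rod occupancy** — exact equilibrium occupancy of non-overlapping
  147-bp particles with per-start Boltzmann weights `z·exp(-E(i))`,
  computed by forward/backward partition sums in log space, with a GC
  energy model and a tabulated-parameter loader.
* **Synthetic chromatin generator** — a 5 Mb, 200-HMD world with known
  ground truth (dyad lattices at 200/180 bp, the 250-bp boundary linker,
  planted linker 6-mers such as `GCTAAC`, GC-rich linkers, TSSs, SNP
  depletion in linkers) used for parameter-recovery testing throughout.

## Worked example

```r
library(hmdnuc)
report <- run_pipeline(pipeline_config(sim = synthetic_config(seed = 1)))
print(report)
```

prints (about 70 s on one CPU):

```
<pipeline_report>
  HMDs: 210  summits: 2025  (8.2% of genome)
  spacing: HMD 201 bp / methylated 180 bp; 5' boundary gap 246 bp
  AUC: DNaseI 0.932, hypo 0.988
  periodicity mode: 198 bp; significant HMDs 53/53
```

Reading the numbers: the methylome segmentation recovers ~210 domains
covering 8.2% of the toy genome; the dyad-metaprofile autocorrelation
estimates 201 bp nucleosome spacing inside HMDs vs 180 bp in the
methylated flanks (generator truth: 200/180), with a 246 bp first linker
step at the 5' boundary (truth: 250). The linker-vs-core SVM classifies
held-out linkers with ROC-AUC 0.93 and its score tracks the accessibility
signal significantly in all 53 scored holdout HMDs; the top-weight 6-mers
recur at ~200-bp intervals (modal pair distance bin centered at 198 bp).
All five planted linker motifs rank in the top weights:

```r
head(sort(report$top_kmers, decreasing = TRUE), 5)
# GATCCG TCATGC AGGCTA GCTAAC CTAGCA
#   5.21   4.91   4.89   4.79   4.76
```

## Command line

```sh
Rscript inst/cli/hmdnuc.R simulate  --seed 1 --out sim/
Rscript inst/cli/hmdnuc.R call-hmds --meth sim/meth.tsv --out hmds.bed
Rscript inst/cli/hmdnuc.R summits   --cuts sim/dnase_cuts.bed --genome sim/genome.fa --out summits.bed
Rscript inst/cli/hmdnuc.R occupancy --genome sim/genome.fa --model gc:1.0 --out occ.bdg
Rscript inst/cli/hmdnuc.R run       --seed 1 --out out/
```

All coordinates are 0-based half-open (BED convention) throughout; I/O
formats are FASTA, BED3/6, narrowPeak, bedGraph and a 3-column methylation
TSV (chrom, pos, ratio). See `vignettes/hmd-nucleosome-organization.Rmd`
for the model, parameter and design documentation.
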
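# limnodiv

Analysis pipeline for probe-based microdiversity surveys of the freshwater
bacterial genus *Limnohabitans*.

Reverse line blot hybridization (RLBH) screens environmental 16S–23S rRNA
ITS amplicons against a membrane of group-specific oligonucleotide probes
and scores each (habitat, probe) signal ordinally — 0 none, 1 weak,
2 normal, 3 strong. Scored across a large set of standing freshwater
habitats spanning a wide pH gradient, such a panel reveals whether a
widespread genus is a collection of generalists or of ecologically
specialized genotype groups. `limnodiv` implements the full computational
side of that survey design for ecologists working with probe panels:

* **In-silico hybridization** — IUPAC-degenerate probe/primer matching
  against ITS sequences on both strands (probe degeneracy matches; target
  `N` does not), in-silico (nested) PCR, panel coverage statistics, and
  Wallace / nearest-neighbor melting temperatures. The 18-probe
  *Limnohabitans* panel and its primer pairs ship as packaged TSVs.
* **Score data model** — validated ordinal score matrices, habitat
  environment tables (pH mandatory, other covariates optional), detection
  binarization, and alignment between the two.
* **Gradient profiles** — per probe, the normalized relative-intensity
  curve along pH: scores summed in 0.2-unit classes, expressed as
  fractions of the probe's total score, rescaled so the maximal class is
  1, then smoothed with a 7-value gliding average
  (`s_k = smooth( (Σ_{h∈class k} y_h / Σ_h y_h) / max_k )`), plus an
  explicit classifier of curve shape: acidic, alkaline,
  circumneutral-narrow, broad, or bimodal (two occurrence maxima — the
  signature of hidden niche separation inside one probe-defined group).
* **Richness & niche separation** — co-occurrence histograms, richness by
  ~1-unit pH classes and the acid/alkaline contrast at pH 7, half-up
  printed percentages, pairwise overlap with complete-separation flags.
* **Spatial ordination** — community similarity (simple matching or
  Jaccard), geographic distances (haversine, or the legacy 1-D
  distance-from-equator transform), a seeded permutation Mantel test with
  the (count+1)/(N+1) estimator, exact exhaustive mode at small n,
  detection-matrix PCA with deterministic axis signs, and
  occurrence-similarity clustering of probes.
* **Synthetic surveys** — a fully seeded generator of habitats (correlated
  covariates along pH), niche-structured ordinal scores (Gaussian response
  curves, ordinal thresholds, noise, false-positive baseline) and
  ITS-like sequences with planted primer/probe sites, with exported ground
  truth so every stage is validated end to end.

## Worked example

```r
library(limnodiv)

ds <- generate_dataset(n_habitats = 161, seed = 1)  # synthetic survey
b  <- binarize(ds$scores)

richness_split(b, ds$habitats, boundary = 7.0)
#> $mean_below  4.72   (n = 83 habitats below pH 7)
#> $mean_above  8.23   (n = 78 at/above)
#> $ratio       1.74

profs <- compute_profiles(ds$scores, ds$habitats)
classify_distribution(profs[["Lim4AusCurv"]])
#> $label "bimodal"   $peaks 5.3 8.9

cs  <- community_similarity(b)
geo <- geo_distance(ds$habitats)
mantel(cs$distance, geo, 10000, tail = "one-sided-positive", seed = 1)
#> Mantel test (sampled, one-sided-positive): r = 0.1144, p = 9.999e-05

sum(pca_binary(b)$explained_fraction[1:2]) * 100
#> 68.1
```

Read: in this seeded synthetic survey, alkaline habitats host on average
1.7× more probe-defined groups than acidic ones; the Lim4AusCurv group's
occurrence curve has two maxima (near pH 5.3 and 8.9), i.e. the probe pools
ecologically distinct genotypes; community composition becomes more
dissimilar with geographic distance (positive Mantel r, spatially clustered
habitat types); and the first two PCA axes carry 68 % of the
detection-matrix variance.

The same steps run as a narrated workflow over `results/`:

```sh
Rscript analysis/01_simulate_survey.R   # synthetic survey + truth
Rscript analysis/02_probe_coverage.R    # matching, PCR, panel coverage
Rscript analysis/03_gradient_profiles.R # pH profiles + shape labels
Rscript analysis/04_richness.R          # histograms, richness, overlap
Rscript analysis/05_ordination.R        # Mantel, PCA, probe clusters
```

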
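---
title: "Ingredient-target-pathway networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ingredient-target-pathway networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itpnet)
```

## The problem

Affinity-ultrafiltration LC-MS screens of herbal extracts produce a short
list of compounds that bind a target protein — in the motivating use case,
topoisomerase I inhibitors fished out of an *Artemisiae Scopariae* Herba
extract. Understanding *how* those few compounds act requires placing them
in the web of their predicted protein targets and the biological pathways
those targets belong to. `itpnet` implements the two computational halves
of such a study:

1. **annotation and screening** — molecular-formula arithmetic, accurate-mass
   matching at a ppm tolerance, and the sample-versus-control enrichment
   test that defines a binder;
2. **network construction and statistics** — building a merged
   ingredient-pathway interaction (IPI) network and its three subnetworks
   from two annotation relations, then computing the small-world and
   centrality statistics used to nominate key ingredients and critical
   pathways.

Target prediction (e.g. similarity-ensemble approaches) and pathway
enrichment (e.g. DAVID) are *inputs*, consumed as two-column mapping
tables; the package does not re-implement them.

## Annotation model

A molecular formula is parsed into an element→count multiset
(`parse_formula()`), accepting both plain and underscore-decorated
dialects. The neutral monoisotopic mass is the sum of count ×
most-abundant-isotope mass over elements, with isotope masses fixed at
CODATA/IUPAC values to 7 decimals (`isotope_masses()`; carbon-12 exact).
The theoretical ion of positive-mode ESI annotation is the protonated
molecule, so `protonated_mz()` adds the **proton** mass 1.00727646 Da, not
the hydrogen-atom mass: protonation adds a bare proton, and this choice
reproduces published 4-decimal \[M+H\]⁺ values (electron mass is below the
4-decimal quantum and is not modelled). Mass deviation is reported as

$$\mathrm{ppm} = \frac{m_\mathrm{measured} - m_\mathrm{theoretical}}
  {m_\mathrm{theoretical}} \times 10^6,$$

and `annotate_peaks()` keeps every (peak, compound) pair inside the
tolerance window (default ±5 ppm, the usual Q/TOF accurate-mass setting).
A peak matching several library compounds is *not* resolved — all hits are
emitted with an `ambiguous` flag, because resolution in practice comes from
MS/MS fragmentation, which is out of scope. Published annotation tables
round ppm errors under conventions they rarely state; recomputed errors can
differ from printed ones by a few tenths of a ppm, and the package always
reports the directly computed value.

The ultrafiltration screen (`screen_enriched()`) is a strict ratio test:
a compound is a putative binder when its released peak area in the
protein-containing sample strictly exceeds `ratio_threshold` times the
area in the protein-free control (default threshold 1, i.e. "larger in
sample than control"). A zero control area with a positive sample area
counts as enriched; an exact tie does not.

## Network model

Two relations drive all construction: the ingredient→target map (which
proteins each screened compound is predicted to hit) and the
target→pathway map (which pathways each protein belongs to). From these,
four undirected simple graphs:

* **TTI** (`build_tti()`): ingredients; edge iff two ingredients share at
  least one target.
* **IPB** (`build_ipb()`): bipartite ingredient × pathway; edge iff some
  target of the ingredient is annotated to the pathway.
* **PPI** (`build_ppi()`): pathways; edge iff some target is annotated to
  both — equivalently the union over targets of the clique on each
  target's pathway set.
* **IPI** (`build_ipi()`): the merged multiplex on ingredients ∪ pathways
  carrying all three edge classes. Because the classes are disjoint by
  node-type signature, $|E_{IPI}| = |E_{TTI}| + |E_{IPB}| + |E_{PPI}|$
  holds identically; the test suite checks it on hundreds of random
  instances.

Edges are unweighted: multiplicity of shared targets is deliberately
discarded, as these studies analyse simple graphs. Targets that appear in
the ingredient map but lack pathway annotation contribute nothing (with a
warning). Isolated nodes are *kept* by default so that node budgets remain
auditable against the input tables; `prune_isolated()` (or
`build_ipi(..., prune = TRUE)`) applies the usual "remove isolated
elements" convention when wanted. Node identity is the raw id string —
trimming happens in the readers, never in the builders.

## Statistics suite

For each network `network_metrics()` reports (symbols as used throughout
the field):

* degree $k_i$, average degree $\langle k\rangle = \frac1N\sum_i k_i =
  2E/N$, degree distribution $P(k)$;
* density $2E/(N(N-1))$, or $E/(n_i n_p)$ in bipartite mode — the right
  normalisation for the IPB network, where same-type pairs can never link;
* average path length $L = \frac{1}{N(N-1)}\sum_{i\neq j} d_{ij}$ over
  ordered pairs and diameter $D = \max d_{ij}$, with $d_{ij}$ from
  breadth-first search. On a disconnected network $L$ averages within
  components and $D$ is the largest finite distance;
* local clustering $C_i = \frac{2e_i}{k_i(k_i-1)}$ for $k_i \ge 2$ (else
  0), the network average $C$, and the clustering spectrum $C(k)$;
* degree centrality $C_d = k_i/(N-1)$;
* betweenness centrality $C_b(i) = \sum_{j<k,\,j,k\neq i}
  g_{jk}(i)/g_{jk}$, computed with Brandes' accumulation algorithm.
  The raw pair-sum is reported alongside a normalised value (divided by
  $(N-1)(N-2)/2$) so that $C_b \in [0,1]$; published per-node values in
  this literature are on the normalised scale even when the displayed
  formula is not;
* closeness centrality $C_c = (N-1)/\sum_j d_{ij}$. On disconnected
  networks the sum runs over reachable nodes and the value is scaled by
  the reachable fraction (Wasserman–Faust correction,
  `wf_correction = TRUE` by default; the naive reachable-only formula is
  available as a flag). Isolated nodes get 0 with a warning. For a
  complete graph the analytic value 1 is reported — a printed 0 in some
  published tables for the complete-subnetwork column is a typesetting
  artifact, not a different definition.

A small-world diagnosis in this literature pairs a high $C$ with a small
$L$, and the clustering spectrum is summarised by a power-law exponent:
`powerlaw_gamma()` fits $\log C(k) \sim \log k$ by ordinary least squares
on points with $k \ge k_{min}$ and $C(k) > 0$. OLS on the log-log spectrum
is the convention these analyses print; maximum-likelihood tail estimation
is out of scope. $k_{min}$ is a parameter (the motivating study used
$k \ge 72$ on a 90-node pathway network), and at least two usable points
are required. The fit is exact on noise-free power-law input and recovers
planted exponents to ±0.05 under 5 % multiplicative noise.

Key-element ranking (`rank_key_nodes()`) orders nodes by degree, one of
the three centralities, or a composite (the mean of min-max-scaled $C_d$,
$C_b$, $C_c$); ties break lexicographically by node id so reports are
reproducible.

Brandes betweenness and the BFS machinery are validated two ways: against
a brute-force oracle (Floyd–Warshall distances plus the combinatorial
geodesic-count recursion, shared code with nothing in the package) on 200
random graphs of ≤ 12 nodes, exactly; and against igraph on a sample of
graphs. igraph is deliberately only a cross-check, never the
implementation, so the two routes stay independent.

## Synthetic data: what it emulates, and what it does not

`generate_mappings()` draws the two relations at the reference scale — 6
ingredients, 160 targets, 90 pathways — with independent Bernoulli
annotation plus three structural features real instances show:

* **hub ingredients** (`hub_fraction`, default 2/6): a subset of
  ingredients post-processed to cover all pathways, mirroring the two
  main active ingredients that dominate such screens. Planted hubs must —
  and in tests do — top the IPB degree ranking;
* **pleiotropic targets** (default: 15 % of targets annotated at
  probability 0.20 versus a 0.06 baseline): multi-pathway proteins are
  what make pathway-pathway networks dense. The effective mean annotation
  probability is ≈ 0.08;
* **hub pathways** (default: 4 pathways at probability 0.85): large
  generic pathways that collect most targets and concentrate centrality,
  the analogue of a critical pathway such as hsa05208.

The free parameters were calibrated once against the aggregate counts a
reference study of this design prints — about 480 ingredient-pathway
edges and a pathway-pathway density near 0.77 — and then frozen; over 50
seeds the generator's mean IPB edge count sits within ±15 % of 479 and
its mean PPI density within ±0.1 of 0.77. Note that a *uniform*
annotation probability of 0.08 cannot reach that density band
(it yields ≈ 0.64); the pleiotropy skew is what closes the gap, which is
itself evidence that real target→pathway tables are overdispersed.

Targets drawn with an empty pathway set are re-drawn once and then
dropped with a message; ingredients drawn with an empty target set are
kept as isolated nodes (hubs instead receive one random target so full
coverage stays possible). Identical seeds give byte-identical instances.

What the generator does **not** emulate: the exact edge counts of any real
instance (those depend on the unpublished per-ingredient target lists),
correlated target prediction across chemically similar ingredients,
pathway-size distributions from a real annotation database, and any
retention-time or fragmentation structure on the MS side. Consequently,
quantities that depend on fine structure — an exact 3593-edge count, a
clustering-spectrum exponent of −0.95, one specific pathway's centrality
triple — are *not* reproduction targets of the synthetic instance; tests
cover them through the invariants and through the calibrated aggregate
bands above, and the statistics themselves are verified on reference-count
constructions (e.g. a 96-node, 3593-edge, diameter-2 graph, for which
$L = 2 - 2E/(N(N-1)) = 1.21$ exactly).

`generate_peak_table()` likewise plants the annotation ground truth: one
\[M+H\]⁺ peak per library compound with uniform m/z noise of ±`noise_ppm`,
and exactly `n_enriched` compounds given a sample/control ratio above 1
(drawn in \[1.5, 4\], the rest in \[0.3, 0.9\]). The built-in composition
set keeps all pairwise \[M+H\]⁺ gaps above 10 ppm so the planted structure
round-trips unambiguously through a 5 ppm annotation.

## Numerical and design choices

* Formula parsing strips underscores, whitespace and dots; a dotted
  solvate/adduct written out in full is summed element-wise, but textual
  adduct annotations in compound *names* are never interpreted — callers
  supply the effective formula.
* Printed reference masses occasionally truncate rather than round the
  4th decimal; recomputation is therefore asserted to one unit in the 4th
  decimal place rather than to exact rounded equality.
* Edge canonicalisation (lexicographic endpoint order, sorted tables) and
  lexicographic tie-breaks make every output, including file exports,
  byte-reproducible for a given seed.
* Pajek export encodes node type as vertex shape (`ellipse` = ingredient,
  `box` = pathway) — the format has no general attributes — and GraphML
  carries an explicit `node_type` key; both round-trip losslessly through
  the package's own readers, and the files parse in igraph.
* Degenerate inputs: an edgeless network has no finite distances and
  `distance_metrics()` refuses it; betweenness needs ≥ 3 nodes; density
  needs ≥ 2; the power-law fit needs ≥ 2 usable points. Each failure is an
  informative error rather than an NA cascade.
* The problem sizes used throughout the tests — graphs of ≤ 12 nodes for
  exhaustive oracles, 50-seed Monte-Carlo bands, the 96-node reference
  constructions — were chosen so the whole suite characterises the
  implementation precisely at the scale of the motivating study.

## Limitations

* The shared-target construction rule is implemented exactly as stated in
  the source methodology; whether an ingredient-pathway edge should
  additionally require per-ingredient enrichment significance is a
  modelling question the input tables must settle upstream.
* Betweenness is exact but $O(NE)$; the package targets the
  hundreds-of-nodes scale of pathway networks, not genome-scale graphs.
* OLS power-law fitting is descriptive, not inferential: no standard
  errors or goodness-of-fit tests are attached, and exponents from short
  degree ranges (a 72–90 window has 19 possible abscissae) are sensitive
  to $k_{min}$.
* Enrichment screening is a point estimate per compound; replicate-aware
  testing is out of scope.

## A worked synthetic run

```{r, eval = FALSE}
cfg <- pipeline_config(generator = generator_config(seed = 1L),
                       k_min = 72, out_dir = "itpnet_out", seed = 1L)
res <- run_pipeline(cfg)
res$summary
head(res$key_ingredients)
head(res$key_pathways)
```

The run annotates 34 synthetic peaks, screens 6 as enriched, builds the
four networks (96 nodes; the merged edge count decomposes exactly over the
three classes), writes Pajek/GraphML/CSV outputs, and ranks the two
planted hub ingredients first with IPB degree 90.
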
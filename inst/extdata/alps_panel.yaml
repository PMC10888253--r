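# Default 3-tube, 10-color ALPS panel description.
#
# Markers are matched by normalized name (case/punctuation-insensitive with
# aliases), so the fluorochrome and detector columns are informative only.
# Reference ranges other than CD45RA+ T cells (30-60% of T) and switched
# memory B cells (>5% of B) are illustrative defaults, not clinical values.
version: "1.0"
tubes:
  - name: ALPS-T
    scatter_channels: {fsc_a: FSC-A, fsc_h: FSC-H, ssc_a: SSC-A}
    time_channel: TIME
    channels:
      - {detector: FL1,  fluorochrome: FITC,     marker: TCR gd}
      - {detector: FL2,  fluorochrome: PE,       marker: TCR ab}
      - {detector: FL3,  fluorochrome: ECD,      marker: CD19}
      - {detector: FL4,  fluorochrome: PC5.5,    marker: CD25}
      - {detector: FL5,  fluorochrome: PC7,      marker: CD4}
      - {detector: FL6,  fluorochrome: APC,      marker: CD127}
      - {detector: FL7,  fluorochrome: APC-A700, marker: CD3}
      - {detector: FL8,  fluorochrome: APC-A750, marker: CD8}
      - {detector: FL9,  fluorochrome: KrO,      marker: CD45}
  - name: ACT-T
    scatter_channels: {fsc_a: FSC-A, fsc_h: FSC-H, ssc_a: SSC-A}
    time_channel: TIME
    channels:
      - {detector: FL1,  fluorochrome: FITC,     marker: CD45RA}
      - {detector: FL2,  fluorochrome: PE,       marker: CD69}
      - {detector: FL3,  fluorochrome: ECD,      marker: CD45RO}
      - {detector: FL4,  fluorochrome: PC5.5,    marker: CD279 (PD1)}
      - {detector: FL5,  fluorochrome: PC7,      marker: CD4}
      - {detector: FL6,  fluorochrome: APC,      marker: HLA-DR}
      - {detector: FL7,  fluorochrome: APC-A700, marker: CD3}
      - {detector: FL8,  fluorochrome: APC-A750, marker: CD8}
      - {detector: FL9,  fluorochrome: KrO,      marker: CD45}
  - name: ALPS-B
    scatter_channels: {fsc_a: FSC-A, fsc_h: FSC-H, ssc_a: SSC-A}
    time_channel: TIME
    channels:
      - {detector: FL1,  fluorochrome: FITC,     marker: kappa}
      - {detector: FL2,  fluorochrome: PE,       marker: lambda}
      - {detector: FL3,  fluorochrome: ECD,      marker: IgD}
      - {detector: FL4,  fluorochrome: PC5.5,    marker: CD27}
      - {detector: FL5,  fluorochrome: PC7,      marker: CD19}
      - {detector: FL6,  fluorochrome: APC,      marker: CD5}
      - {detector: FL7,  fluorochrome: APC-A700, marker: CD3}
      - {detector: FL8,  fluorochrome: APC-A750, marker: CD56}
      - {detector: FL9,  fluorochrome: KrO,      marker: CD45}
# Subset taxonomy: one tree per tube rooted at "lymphocytes".  Children of
# the root are the lineages assigned by the cluster classifier; deeper nodes
# are assigned by the marker-level predicates below (evaluated on cluster
# phenotype codes; min/max are inclusive five-level bounds).  Within a
# parent, primary children are evaluated in listed order and the first match
# wins; nodes marked secondary are counted but do not participate in the
# event partition (their marker axis crosses the primary partition, e.g.
# light chains across memory B subsets).
taxonomy:
  - {name: lymphocytes, parent: null, tube: ALPS-T}
  - {name: T cells, parent: lymphocytes, tube: ALPS-T}
  - {name: B cells, parent: lymphocytes, tube: ALPS-T}
  - {name: NK cells, parent: lymphocytes, tube: ALPS-T}
  - name: gd T cells
    parent: T cells
    tube: ALPS-T
    predicates: [{marker: TCR gd, min: positive}]
  - name: CD4 T cells
    parent: T cells
    tube: ALPS-T
    predicates: [{marker: CD4, min: positive}, {marker: CD8, max: dim}]
  - name: CD8 T cells
    parent: T cells
    tube: ALPS-T
    predicates: [{marker: CD8, min: positive}, {marker: CD4, max: dim}]
  - name: DNT
    parent: T cells
    tube: ALPS-T
    predicates: [{marker: CD4, max: dim}, {marker: CD8, max: dim}]
  - name: TCRab+ DNT
    parent: DNT
    tube: ALPS-T
    predicates: [{marker: TCR ab, min: positive}]
  - name: Treg-like
    parent: CD4 T cells
    tube: ALPS-T
    predicates: [{marker: CD25, min: positive}, {marker: CD127, max: dim}]
  - {name: lymphocytes, parent: null, tube: ACT-T}
  - {name: T cells, parent: lymphocytes, tube: ACT-T}
  - {name: non-T lymphocytes, parent: lymphocytes, tube: ACT-T}
  - name: CD4 T cells
    parent: T cells
    tube: ACT-T
    predicates: [{marker: CD4, min: positive}, {marker: CD8, max: dim}]
  - name: CD8 T cells
    parent: T cells
    tube: ACT-T
    predicates: [{marker: CD8, min: positive}, {marker: CD4, max: dim}]
  - name: CD45RA+ T cells
    parent: T cells
    tube: ACT-T
    secondary: true
    predicates: [{marker: CD45RA, min: positive}]
  - name: CD45RO+ T cells
    parent: T cells
    tube: ACT-T
    secondary: true
    predicates: [{marker: CD45RO, min: positive}]
  - name: activated T cells
    parent: T cells
    tube: ACT-T
    secondary: true
    predicates: [{marker: CD69, min: positive}, {marker: HLA-DR, min: positive}]
  - {name: lymphocytes, parent: null, tube: ALPS-B}
  - {name: T cells, parent: lymphocytes, tube: ALPS-B}
  - {name: B cells, parent: lymphocytes, tube: ALPS-B}
  - {name: NK cells, parent: lymphocytes, tube: ALPS-B}
  - name: naive B cells
    parent: B cells
    tube: ALPS-B
    predicates: [{marker: CD27, max: dim}, {marker: IgD, min: positive}]
  - name: switched memory B cells
    parent: B cells
    tube: ALPS-B
    predicates: [{marker: CD27, min: positive}, {marker: IgD, max: dim}]
  - name: non-switched memory B cells
    parent: B cells
    tube: ALPS-B
    predicates: [{marker: CD27, min: positive}, {marker: IgD, min: positive}]
  - name: kappa+ B cells
    parent: B cells
    tube: ALPS-B
    secondary: true
    predicates: [{marker: kappa, min: positive}]
  - name: lambda+ B cells
    parent: B cells
    tube: ALPS-B
    secondary: true
    predicates: [{marker: lambda, min: positive}]
# Cluster-classifier labels that are valid but fall outside the lymphocyte
# tree (excluded from every lymphocyte denominator).
non_lymphocyte_labels: [Monocytes]
reference_ranges:
  - {subset: CD45RA+ T cells, tube: ACT-T, low: 30, high: 60, denominator: T cells}
  - {subset: CD45RO+ T cells, tube: ACT-T, low: null, high: 60, denominator: T cells}
  - {subset: switched memory B cells, tube: ALPS-B, low: 5, high: null, denominator: B cells}
alps_criteria:
  dnt_pct_of_lymphs: 1.5
  dnt_pct_of_cd3: 2.5
  dnt_subset: TCRab+ DNT
  t_subset: T cells
  tube: ALPS-T
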
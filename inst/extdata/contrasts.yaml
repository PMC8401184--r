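# Cross-study contrast catalogue: 24 named contrasts in three groups.
# Each contrast intersects the listed layers after filtering each layer to
# the given direction ("any" = no direction filter).
#   Layers: wgbs_dm   - gene-level WGBS differential methylation (hyper/hypo)
#           array_de  - cell-line expression-array DE, R vs S (up/down)
#           cohort_de - cohort tumor-vs-control DE (up/down)
#           k450_dm   - 450K-array patient differential methylation
#           rnaseq_de - cohort RNA-seq DE, resistant vs sensitive (up/down)
# Group 1 combines WGBS + expression array + cohort; group 2 combines 450K +
# RNA-seq + cohort; group 3 crosses all methylation and expression layers.
contrasts:
  - {name: g1_hyper_inhibited,            group: group1, layers: {wgbs_dm: hyper, array_de: down}}
  - {name: g1_hyper_inhibited_cohort,     group: group1, layers: {wgbs_dm: hyper, array_de: down, cohort_de: down}}
  - {name: g1_hypo_overexpressed,         group: group1, layers: {wgbs_dm: hypo, array_de: up}}
  - {name: g1_hypo_overexpressed_cohort,  group: group1, layers: {wgbs_dm: hypo, array_de: up, cohort_de: up}}
  - {name: g1_hyper_cohort_down,          group: group1, layers: {wgbs_dm: hyper, cohort_de: down}}
  - {name: g1_hypo_cohort_up,             group: group1, layers: {wgbs_dm: hypo, cohort_de: up}}
  - {name: g1_dm_any_inhibited,           group: group1, layers: {wgbs_dm: any, array_de: down, cohort_de: down}}
  - {name: g1_dm_any_overexpressed,       group: group1, layers: {wgbs_dm: any, array_de: up, cohort_de: up}}
  - {name: g2_hyper_inhibited,            group: group2, layers: {k450_dm: hyper, rnaseq_de: down}}
  - {name: g2_hyper_inhibited_cohort,     group: group2, layers: {k450_dm: hyper, rnaseq_de: down, cohort_de: down}}
  - {name: g2_hypo_overexpressed,         group: group2, layers: {k450_dm: hypo, rnaseq_de: up}}
  - {name: g2_hypo_overexpressed_cohort,  group: group2, layers: {k450_dm: hypo, rnaseq_de: up, cohort_de: up}}
  - {name: g2_hyper_cohort_down,          group: group2, layers: {k450_dm: hyper, cohort_de: down}}
  - {name: g2_hypo_cohort_up,             group: group2, layers: {k450_dm: hypo, cohort_de: up}}
  - {name: g2_dm_any_inhibited,           group: group2, layers: {k450_dm: any, rnaseq_de: down, cohort_de: down}}
  - {name: g2_dm_any_overexpressed,       group: group2, layers: {k450_dm: any, rnaseq_de: up, cohort_de: up}}
  - {name: g3_hyper_both_inhibited_both,  group: group3, layers: {wgbs_dm: hyper, k450_dm: hyper, array_de: down, rnaseq_de: down}}
  - {name: g3_hyper_both_inhibited_array, group: group3, layers: {wgbs_dm: hyper, k450_dm: hyper, array_de: down}}
  - {name: g3_hyper_both_inhibited_rnaseq, group: group3, layers: {wgbs_dm: hyper, k450_dm: hyper, rnaseq_de: down}}
  - {name: g3_hyper_wgbs_inhibited_both,  group: group3, layers: {wgbs_dm: hyper, array_de: down, rnaseq_de: down}}
  - {name: g3_hyper_k450_inhibited_both,  group: group3, layers: {k450_dm: hyper, array_de: down, rnaseq_de: down}}
  - {name: g3_hypo_both_overexpressed_both, group: group3, layers: {wgbs_dm: hypo, k450_dm: hypo, array_de: up, rnaseq_de: up}}
  - {name: g3_dm_both_any_inhibited_both, group: group3, layers: {wgbs_dm: any, k450_dm: any, array_de: down, rnaseq_de: down}}
  - {name: g3_dm_both_any_overexpressed_both, group: group3, layers: {wgbs_dm: any, k450_dm: any, array_de: up, rnaseq_de: up}}
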
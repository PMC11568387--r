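{
  "config": {
    "seed": 20,
    "peak_q": 0.05,
    "peak_min_fold": 2,
    "peak_window": 500,
    "min_support": 2,
    "max_length": 10000,
    "presence_min_replicates": 1,
    "diff_q": 0.05,
    "overlap_n_perm": 50,
    "assoc_q": 0.05,
    "maf_min": 0.05,
    "max_missing": 0.25,
    "qual_min": 30,
    "motif_sig": 0.0001,
    "motif_ratio": 1.5,
    "pbs_quantile": 0.95,
    "stages": {
      "differential": true,
      "overlap": true,
      "association": true,
      "pbs": true,
      "motifs": true
    }
  },
  "sim": {
    "n_truth_enhancers": 24,
    "n_genes": 20,
    "n_snps": 72
  },
  "peaks": {
    "n_per_replicate": [12, 12, 12, 12, 12, 12, 13, 13, 13, 9, 9, 9, 12, 12, 12, 11, 11, 11]
  },
  "consensus": {
    "n": 24,
    "mean_width": 1670.8333333333,
    "recall": 1,
    "precision": 1
  },
  "presence": {
    "frac_conserved": 0.083333333333,
    "frac_single": 0.375
  },
  "genes": {
    "n_with_enhancer": 16,
    "multi_enhancer_trend": [
      {
        "max_specificity": 1,
        "n_genes": 2,
        "frac_multi_enhancer": 0
      },
      {
        "max_specificity": 2,
        "n_genes": 4,
        "frac_multi_enhancer": 0.25
      },
      {
        "max_specificity": 3,
        "n_genes": 1,
        "frac_multi_enhancer": 1
      },
      {
        "max_specificity": 4,
        "n_genes": 3,
        "frac_multi_enhancer": 0.66666666667
      },
      {
        "max_specificity": 5,
        "n_genes": 4,
        "frac_multi_enhancer": 0.25
      },
      {
        "max_specificity": 6,
        "n_genes": 2,
        "frac_multi_enhancer": 1
      }
    ],
    "n_social_only": 2,
    "n_solitary_only": 0,
    "mechanism_table": [
      [0, 0, 11],
      [0, 0, 3],
      [1, 1, 0]
    ]
  },
  "differential": {
    "n_tested": 24,
    "n_significant": 1,
    "n_social_biased": 1,
    "n_solitary_biased": 0,
    "power": null,
    "fdr": 0
  },
  "overlap": {
    "observed_overlap": 24,
    "perm_mean": 16.24,
    "perm_sd": 2.2457215558,
    "perm_min": 10,
    "perm_max": 22,
    "z_score": 3.4554595515,
    "empirical_p": 0.019607843137,
    "representation_factor": 1.4778325123,
    "n_permutations": 50,
    "representation_factor_2dp": 1.48
  },
  "association": {
    "n_filtered_snps": 65,
    "n_tested": 65,
    "n_significant": 14,
    "power": 0.86666666667,
    "fdr": 0.071428571429,
    "polarization_rate": 1
  },
  "pbs": {
    "n_sites": 72,
    "mean_pbs_social": 0.017917949016,
    "mean_pbs_solitary": 0.0092355088268,
    "n_outlier_social": 4,
    "selected_site_enrichment": 12
  },
  "motifs": {
    "n_snps": 20,
    "n_with_effect": 11,
    "effect_recall": 1
  },
  "direction_tests": {
    "table": [
      {
        "increase": 9,
        "decrease": 5,
        "_row": "non-DAE"
      }
    ],
    "chisq": {},
    "binomial": {
      "non-DAE": {
        "n": 14,
        "frac_increase": 0.64285714286,
        "p_value": 0.42395019531
      }
    },
    "kruskal": {
      "pbs_social:non-DAE": {
        "pbs": "pbs_social",
        "class": "non-DAE",
        "statistic": 0.04,
        "p_value": 0.84148058112
      },
      "pbs_solitary:non-DAE": {
        "pbs": "pbs_solitary",
        "class": "non-DAE",
        "statistic": 0.04,
        "p_value": 0.84148058112
      }
    }
  }
}
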
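{
  "schema_version": "1.0",
  "stats_file": "species_profiles.csv",
  "taxa": {
    "A. palmi": {
      "full_name": "Allopodocotyle palmi",
      "host": "Epinephelus coioides",
      "locality": "Bali, Indonesia",
      "source": "present material (22 gravid whole-mount worms)",
      "categoricals": {
        "testes_arrangement": "diagonal",
        "body_shape": "elongate",
        "uterus_half": "anterior",
        "gonads_third": "middle",
        "ovary_half": "mainly_posterior",
        "anterior_testis_half": "completely_posterior",
        "uterine_coils_eighths": [4],
        "cirrus_sac_vitellarium_relation": "separated",
        "cirrus_sac_ventral_sucker_relation": "well_posterior"
      },
      "notes": "vitelline follicles usually well separated from the posterior border of the cirrus-sac; ovary in about mid-body"
    },
    "A. epinepheli": {
      "full_name": "Allopodocotyle epinepheli",
      "host": "Epinephelus quoyanus",
      "locality": "Heron Island, Australia",
      "source": "literature",
      "categoricals": {
        "testes_arrangement": "diagonal",
        "body_shape": "elongate",
        "uterus_half": "anterior",
        "gonads_third": "middle",
        "cirrus_sac_ventral_sucker_relation": "well_posterior"
      },
      "notes": "testes almost contiguous, also almost contiguous to ovary; morphological group A"
    },
    "A. epinepheli sensu Rueckert": {
      "full_name": "Allopodocotyle epinepheli sensu Rueckert 2006",
      "host": "Epinephelus coioides, E. fuscoguttatus",
      "locality": "Bali, Indonesia",
      "source": "literature (single drawing)",
      "categoricals": {
        "ovary_eighths": [4],
        "anterior_testis_eighths": [5],
        "posterior_testis_eighths": [6]
      },
      "notes": "tandem-vs-diagonal wording ambiguous in the source; testes arrangement deliberately left unknown and the taxon is not encoded in the key"
    },
    "A. heronensis": {
      "full_name": "Allopodocotyle heronensis",
      "host": "Cromileptes altivelis, Epinephelus fuscoguttatus",
      "locality": "Heron Island, Australia",
      "source": "literature",
      "categoricals": {
        "testes_arrangement": "tandem",
        "body_shape": "elongate"
      },
      "notes": "testes very well separated, also from ovary; morphological group C; cirrus-sac length drawing-derived (510 um) conflicts with the printed key bound < 0.5 mm"
    },
    "A. manteri": {
      "full_name": "Allopodocotyle manteri",
      "host": "Epinephelus summana",
      "locality": "Red Sea, Egypt",
      "source": "literature",
      "categoricals": {
        "testes_arrangement": "diagonal",
        "body_shape": "squat",
        "uterus_half": "posterior",
        "gonads_third": "posterior",
        "cirrus_sac_ventral_sucker_relation": "well_posterior"
      },
      "caveat": "published body sizes (<= 1.75 mm) are smaller than as calculated from the associated original figure and scale bar (> 2 mm)",
      "notes": "squat, pyriform body; uterine coils and vitelline follicles entirely in the second body half; morphological group A"
    },
    "A. mecopera": {
      "full_name": "Allopodocotyle mecopera",
      "host": "spotted grouper",
      "locality": "James Island, Galapagos",
      "source": "literature",
      "categoricals": {
        "testes_arrangement": "tandem"
      },
      "notes": "testes just slightly separated, each half as wide as body; morphological group C"
    },
    "A. plectropomi": {
      "full_name": "Allopodocotyle plectropomi",
      "host": "Plectropomus maculatus",
      "locality": "Suva, Fiji",
      "source": "literature",
      "categoricals": {
        "testes_arrangement": "diagonal",
        "body_shape": "elongate",
        "uterus_half": "anterior",
        "gonads_third": "middle",
        "ovary_half": "anterior",
        "anterior_testis_half": "anterior",
        "uterine_coils_eighths": [3],
        "cirrus_sac_ventral_sucker_relation": "well_posterior"
      },
      "notes": "ovary and anterior testis in first half of body; morphological group A"
    },
    "A. serrani": {
      "full_name": "Allopodocotyle serrani",
      "host": "Serranus sp. (probably an Epinephelus sp.)",
      "locality": "Makassar, Indonesia",
      "source": "literature",
      "categoricals": {
        "testes_arrangement": "diagonal",
        "body_shape": "elongate",
        "uterus_half": "anterior",
        "gonads_third": "middle",
        "ovary_half": "mainly_posterior",
        "anterior_testis_half": "completely_posterior",
        "uterine_coils_eighths": [4],
        "cirrus_sac_vitellarium_relation": "overlapping",
        "cirrus_sac_ventral_sucker_relation": "well_posterior"
      },
      "notes": "cirrus-sac long, distinctly overlapping the anterior region of the vitellarium; morphological group A"
    },
    "P. maternus": {
      "full_name": "Prosorhynchus maternus",
      "host": "Epinephelus coioides (additional), E. malabaricus (type)",
      "locality": "Indonesia (new record); type locality New Caledonia",
      "source": "present material (5 gravid whole-mount worms)",
      "categoricals": {},
      "notes": "bucephalid; not part of the Allopodocotyle key"
    }
  }
}
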
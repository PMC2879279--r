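# MLPA preset: segmental call at >= 2 consecutive loci deviating >= 0.25 from
# 1, or > 75% of a region's probes deviating >= 0.15 in the same direction;
# whole-chromosome and MYCN clauses as in the MAQ preset except that only 2
# MYCN probes are required.
name: MLPA
segmental_delta: 0.25
segmental_min_consecutive: 2
fraction_rule_enabled: yes
fraction_rule_fraction: 0.75
fraction_rule_delta: 0.15
numerical_arm_fraction: 0.75
numerical_majority_delta: 0.1
numerical_majority_fraction: 0.5
mycn_delta: 3.0
mycn_required_loci: 2
mycn_absolute: no
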
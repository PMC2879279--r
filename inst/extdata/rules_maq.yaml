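# MAQ preset: segmental call at >= 2 consecutive loci deviating >= 0.2 from 1;
# whole-chromosome call at >= 75% of both arms off 1 and > 50% of loci
# deviating >= 0.1; MYCN amplified when all 3 MYCN loci increase by >= 3.
name: MAQ
segmental_delta: 0.2
segmental_min_consecutive: 2
fraction_rule_enabled: no
fraction_rule_fraction: 0.75
fraction_rule_delta: 0.15
numerical_arm_fraction: 0.75
numerical_majority_delta: 0.1
numerical_majority_fraction: 0.5
mycn_delta: 3.0
mycn_required_loci: 3
mycn_absolute: no
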